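#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members.  Used for the signal-transduction pathway profiling of a called
#' network.
#'
#' @param path GMT file path.
#' @param source_tag label recorded on the collection (default the file name).
#' @return named list of gene-symbol character vectors, class
#'   `gene_set_collection`, with attributes `description` and `source`.
#' @export
read_gene_sets <- function(path, source_tag = basename(path)) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[[`, "", 1L)
  dup <- unique(nm[duplicated(nm)])
  if (length(dup)) stop("duplicated gene-set name(s): ", paste(dup, collapse = ", "))
  desc <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else "", "")
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  empty <- nm[vapply(sets, length, 0L) == 0L]
  if (length(empty)) stop("empty gene set(s): ", paste(empty, collapse = ", "))
  names(sets) <- nm
  structure(sets, description = stats::setNames(desc, nm), source = source_tag,
            class = "gene_set_collection")
}

#' Packaged default pathway collection
#'
#' Thirteen cancer-related signal-transduction / machinery gene sets
#' (ribosome, VEGF, cell cycle, ERBB2, PDGFRB, and eight further standard
#' pathways) with representative member symbols, shipped for pathway
#' profiling of called networks.
#' @return a `gene_set_collection` of 13 sets.
#' @export
default_pathways <- function() {
  path <- system.file("extdata", "pathways13.gmt", package = "cidnet",
                      mustWork = TRUE)
  read_gene_sets(path, source_tag = "packaged_13_pathways")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection (%s): %d sets\n",
              attr(x, "source"), length(x)))
  for (nm in names(x)) cat(sprintf("  %-22s %d genes\n", nm, length(x[[nm]])))
  invisible(x)
}

#' Load a packaged signature table
#'
#' The two signature tables shipped with the package:
#' \describe{
#'   \item{`"type2_nr5a2"`}{the 16-probe feature-type-II pool of the NR5A2
#'     network (consensus poor-prognosis signature candidates; removing the
#'     driving TF's own probe, feature 16670, leaves the 15 scored probes).}
#'   \item{`"type4_nr5a1"`}{the 8 transcription factors with antagonistic
#'     NR5A1/NR5A2 regulation in feature type IV (favorable signature).}
#' }
#' Columns: `feature_number`, `gene_symbol`, `direction` (prognosis when the
#' probe is elevated: `poor`/`good`), `literature_annotation` (free text,
#' `Undefined` where none), `regulation_by_tf` (`Up`/`Down`/`unknown`).
#'
#' @param name one of `"type2_nr5a2"`, `"type4_nr5a1"`.
#' @return data.frame, class `signature_table`.
#' @export
load_packaged_signature <- function(name) {
  files <- c(type2_nr5a2 = "signature_type2_nr5a2.tsv",
             type4_nr5a1 = "signature_type4_nr5a1.tsv")
  if (!name %in% names(files))
    stop("unknown signature '", name, "'; available: ",
         paste(names(files), collapse = ", "))
  path <- system.file("extdata", files[[name]], package = "cidnet", mustWork = TRUE)
  tab <- utils::read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  tab$feature_number <- as.character(tab$feature_number)
  stopifnot(!anyDuplicated(tab$feature_number),
            all(tab$direction %in% c("poor", "good")))
  class(tab) <- c("signature_table", class(tab))
  tab
}
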