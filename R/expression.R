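#' Construct a probe-by-sample expression matrix
#'
#' The substrate of every statistic in the package: a numeric matrix of
#' log2-ratio expression values with probes in rows (identified by array
#' feature numbers) and samples in columns, plus an optional probe-to-gene
#' symbol annotation.  Missing values are stored as `NA`, never imputed;
#' every downstream statistic drops samples pairwise-complete.
#'
#' @param values numeric matrix (probes x samples) of log2 ratios.
#' @param probe_ids character vector of unique probe identifiers (array
#'   feature numbers such as `"16670"`); defaults to `rownames(values)`.
#' @param sample_ids character vector of unique sample identifiers;
#'   defaults to `colnames(values)`.
#' @param gene_symbols optional character vector of gene symbols parallel to
#'   `probe_ids` (`NA` where unknown).
#' @return An object of class `expr_matrix`: the values matrix with
#'   `probe_ids`/`sample_ids` as dimnames and a `gene_symbols` attribute.
#' @export
expr_matrix <- function(values, probe_ids = rownames(values),
                        sample_ids = colnames(values), gene_symbols = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(probe_ids) || is.null(sample_ids))
    stop("probe_ids and sample_ids are required (or set as dimnames)")
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(probe_ids) || ncol(values) != length(sample_ids))
    stop("dimension mismatch between values and identifiers")
  dup <- unique(probe_ids[duplicated(probe_ids)])
  if (length(dup))
    stop("duplicate probe ids: ", paste(dup, collapse = ", "))
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop("duplicate sample ids: ", paste(dup, collapse = ", "))
  if (nrow(values) < 1L || ncol(values) < 2L)
    stop("need at least 1 probe and 2 samples")
  bad <- is.infinite(values)
  if (any(bad))
    stop("non-finite expression values at ", sum(bad), " cells; use NA for missing")
  dimnames(values) <- list(probe_ids, sample_ids)
  if (is.null(gene_symbols)) {
    gene_symbols <- rep(NA_character_, length(probe_ids))
  } else {
    gene_symbols <- as.character(gene_symbols)
    if (length(gene_symbols) != length(probe_ids))
      stop("gene_symbols must be parallel to probe_ids")
  }
  names(gene_symbols) <- probe_ids
  structure(values, gene_symbols = gene_symbols, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d probes x %d samples (%.1f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  sym <- gene_symbols(x)
  cat(sprintf("  gene symbols annotated for %d probes\n", sum(!is.na(sym))))
  invisible(x)
}

#' Gene-symbol annotation of an expression matrix
#' @param x an `expr_matrix`.
#' @return named character vector, probe id -> symbol (`NA` if unknown).
#' @export
gene_symbols <- function(x) attr(x, "gene_symbols")

# subsetting keeps class and annotation aligned
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  sym <- attr(x, "gene_symbols")
  y <- NextMethod(drop = drop)
  if (is.matrix(y)) {
    attr(y, "gene_symbols") <- sym[rownames(y)]
    class(y) <- c("expr_matrix", "matrix", "array")
  }
  y
}

#' Read a probe-by-sample expression table
#'
#' Tab-separated, UTF-8, `.` decimal; first column probe ids, header row of
#' sample ids; an optional gene-symbol column (named by `symbol_col`) is
#' carried as annotation.  Cells matching `na_tokens` become missing values.
#'
#' @param path file path.
#' @param symbol_col name of the gene-symbol column, if present
#'   (default `"gene_symbol"`).
#' @param na_tokens strings read as missing (default `""`, `"NA"`, `"NaN"`).
#' @return an [expr_matrix()].
#' @export
read_expression_matrix <- function(path, symbol_col = "gene_symbol",
                                   na_tokens = c("", "NA", "NaN")) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", check.names = FALSE,
                           fileEncoding = "UTF-8")
  if (ncol(tab) < 2L) stop("expression table needs a probe column plus samples")
  probe_ids <- tab[[1L]]
  dup <- unique(probe_ids[duplicated(probe_ids)])
  if (length(dup))
    stop("duplicate probe ids in ", path, ": ", paste(dup, collapse = ", "))
  tab <- tab[, -1L, drop = FALSE]
  gene_symbols <- NULL
  if (symbol_col %in% names(tab)) {
    gene_symbols <- tab[[symbol_col]]
    gene_symbols[is.na(gene_symbols) | gene_symbols %in% na_tokens] <- NA_character_
    tab <- tab[, names(tab) != symbol_col, drop = FALSE]
  }
  vals <- matrix(NA_real_, nrow(tab), ncol(tab),
                 dimnames = list(probe_ids, names(tab)))
  for (j in seq_len(ncol(tab))) {
    cell <- tab[[j]]
    miss <- is.na(cell) | cell %in% na_tokens
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & !miss)
    if (length(bad))
      stop(sprintf("non-numeric cell at row %d (probe %s), column '%s': '%s'",
                   bad[1L], probe_ids[bad[1L]], names(tab)[j], cell[bad[1L]]))
    num[miss] <- NA_real_
    vals[, j] <- num
  }
  expr_matrix(vals, gene_symbols = gene_symbols)
}

#' Write an expression matrix as a tab-separated table
#'
#' Inverse of [read_expression_matrix()]: write-then-read reproduces the
#' object (ids bit-exact, values to full precision via \code{format(digits=17)}).
#'
#' @param x an `expr_matrix`.
#' @param path output path.
#' @export
write_expression_matrix <- function(x, path) {
  sym <- gene_symbols(x)
  vals <- apply(unclass(x), 2L, function(col) {
    out <- vapply(col, function(v) if (is.na(v)) "NA" else format(v, digits = 17), "")
    out
  })
  df <- data.frame(probe_id = rownames(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (any(!is.na(sym))) df$gene_symbol <- ifelse(is.na(sym), "NA", sym)
  df <- cbind(df, as.data.frame(vals, stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
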