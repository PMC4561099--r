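#' Validate a per-sample clinical table
#'
#' The clinical table is a plain `data.frame` with one row per sample and the
#' columns used by the cohort definitions and the survival machinery:
#' \describe{
#'   \item{sample_id}{unique sample identifier}
#'   \item{er_status, pr_status, her_status}{tri-state receptor calls:
#'     `"+"`, `"-"` or `NA` (unknown)}
#'   \item{grade, nuclear_pleomorphism, mitotic_count, tubule_formation,
#'     stage}{ordinal categories (integer-coded, level order ascending)}
#'   \item{lvi, lym}{binary 0/1 (lymphovascular invasion, nodal metastasis
#'     status)}
#'   \item{lnm}{count of lymph-node metastases}
#'   \item{age}{years}
#'   \item{tumor_size}{cm}
#'   \item{surv_time}{follow-up time, months, >= 0}
#'   \item{event}{1 = event (death/relapse, endpoint labelled by the run
#'     configuration), 0 = censored}
#' }
#'
#' @param clinical data.frame as above.
#' @return the validated data.frame, invisibly classed `clinical_table`.
#' @export
clinical_table <- function(clinical) {
  need <- c("sample_id", "er_status", "surv_time", "event")
  miss <- setdiff(need, names(clinical))
  if (length(miss)) stop("clinical table missing columns: ", paste(miss, collapse = ", "))
  clinical$sample_id <- as.character(clinical$sample_id)
  dup <- unique(clinical$sample_id[duplicated(clinical$sample_id)])
  if (length(dup)) stop("duplicate sample ids: ", paste(dup, collapse = ", "))
  if (any(clinical$surv_time < 0, na.rm = TRUE)) stop("surv_time must be >= 0")
  if (!all(clinical$event %in% c(0, 1, NA))) stop("event must be 0/1")
  for (st in intersect(c("er_status", "pr_status", "her_status"), names(clinical))) {
    v <- as.character(clinical[[st]])
    if (!all(v %in% c("+", "-", NA_character_)))
      stop(st, " must be '+', '-' or NA")
    clinical[[st]] <- v
  }
  class(clinical) <- unique(c("clinical_table", class(clinical)))
  clinical
}

#' Read / write a clinical table (tab-separated, UTF-8)
#' @param path file path.
#' @param na_tokens strings read as missing.
#' @return [clinical_table()] data.frame.
#' @export
read_clinical_table <- function(path, na_tokens = c("", "NA", "NaN")) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           na.strings = na_tokens, check.names = FALSE,
                           fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  clinical_table(tab)
}

#' @rdname read_clinical_table
#' @param clinical a clinical table.
#' @export
write_clinical_table <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Default clinical-relevance parameter panel
#'
#' The ten clinicopathological parameters screened against a TF's expression
#' (ANOVA pools) and carried through the clinically-significant-cluster
#' intersection.
#' @return character vector of 10 clinical column names.
#' @export
default_clinical_panel <- function() {
  c("pr_status", "her_status", "lvi", "lym", "lnm",
    "age", "tumor_size", "grade", "nuclear_pleomorphism", "mitotic_count")
}

#' Partition samples into receptor-defined cohorts
#'
#' Derives the named analysis cohorts from receptor status: `"90A"` = ER(+),
#' `"91A"` = ER(-), `"181A"` = all samples, plus the molecular subtype
#' subsets (`IE` ER+PR+, `IIE` ER+PR-, `TN` ER-PR-HER-, `ERBB2` ER-PR-HER+,
#' `ERnPRpHERn`, `ERnPRpHERp`, `ERnHERu` for the remaining ER(-) subgroups).
#' Cohort names follow the study-design convention regardless of actual
#' sizes.  Samples with unknown ER status fall only in `"181A"`, with a
#' warning.
#'
#' @param clinical a [clinical_table()].
#' @return named list of sample-id character vectors, class `cohort_set`.
#' @export
define_cohorts <- function(clinical) {
  clinical <- clinical_table(clinical)
  id <- clinical$sample_id
  er <- clinical$er_status
  pr <- if ("pr_status" %in% names(clinical)) clinical$pr_status else rep(NA_character_, length(id))
  her <- if ("her_status" %in% names(clinical)) clinical$her_status else rep(NA_character_, length(id))
  if (anyNA(er))
    warning(sum(is.na(er)), " sample(s) with unknown ER status placed in 181A only")
  erp <- !is.na(er) & er == "+"
  ern <- !is.na(er) & er == "-"
  eq <- function(v, s) !is.na(v) & v == s
  cs <- list(
    "181A" = id,
    "90A"  = id[erp],
    "91A"  = id[ern],
    "IE"   = id[erp & eq(pr, "+")],
    "IIE"  = id[erp & eq(pr, "-")],
    "TN"   = id[ern & eq(pr, "-") & eq(her, "-")],
    "ERBB2" = id[ern & eq(pr, "-") & eq(her, "+")],
    "ERnPRpHERn" = id[ern & eq(pr, "+") & eq(her, "-")],
    "ERnPRpHERp" = id[ern & eq(pr, "+") & eq(her, "+")],
    "ERnHERu" = id[ern & is.na(her)]
  )
  if (!length(cs[["91A"]])) warning("ER(-) cohort (91A) is empty")
  if (!length(cs[["90A"]])) warning("ER(+) cohort (90A) is empty")
  structure(cs, class = "cohort_set")
}

#' @export
print.cohort_set <- function(x, ...) {
  cat("cohort_set:\n")
  for (nm in names(x)) cat(sprintf("  %-12s %d samples\n", nm, length(x[[nm]])))
  invisible(x)
}
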