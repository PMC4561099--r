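## Four-way prognostic typing across the ER-status cohorts, and the feature
## types obtained by intersecting the typed pools with a called network.

#' Classify probes into prognostic types 1-4 across the three cohorts
#'
#' Given per-probe log-rank p-values in the ER(+) (`90A`), ER(-) (`91A`) and
#' combined (`181A`) cohorts, a probe is significant in a cohort when
#' `p <= alpha`, and:
#' \describe{
#'   \item{type 1}{significant in all three cohorts}
#'   \item{type 2}{significant in 91A and 181A but not 90A}
#'   \item{type 3}{significant in 90A and 181A but not 91A}
#'   \item{type 4}{significant in 181A only}
#'   \item{none}{any other pattern}
#' }
#' The four types partition the probes significant in 181A.
#'
#' @param p90,p91,p181 named numeric vectors of log-rank p-values (names =
#'   probe ids); probes missing from any cohort are skipped with a warning.
#' @param alpha significance level (default 0.05).
#' @return data.frame of class `type_assignment`: `probe`, `p90`, `p91`,
#'   `p181`, `type` (`"1"`..`"4"` or `"none"`).
#' @export
classify_types <- function(p90, p91, p181, alpha = 0.05) {
  probes <- intersect(intersect(names(p90), names(p91)), names(p181))
  skipped <- setdiff(unique(c(names(p90), names(p91), names(p181))), probes)
  if (length(skipped))
    warning(length(skipped), " probe(s) missing a cohort call were skipped")
  if (!length(probes)) stop("no probe has calls in all three cohorts")
  s90 <- p90[probes] <= alpha
  s91 <- p91[probes] <= alpha
  s181 <- p181[probes] <= alpha
  type <- rep("none", length(probes))
  type[s90 & s91 & s181] <- "1"
  type[!s90 & s91 & s181] <- "2"
  type[s90 & !s91 & s181] <- "3"
  type[!s90 & !s91 & s181] <- "4"
  out <- data.frame(probe = probes, p90 = unname(p90[probes]),
                    p91 = unname(p91[probes]), p181 = unname(p181[probes]),
                    type = type, stringsAsFactors = FALSE)
  class(out) <- c("type_assignment", class(out))
  out
}

#' Feature types: typed probes inside a called network
#'
#' Feature type X (I-IV) is the set of type-x probes that are also called
#' targets of the network; probes outside the network (or typed `none`)
#' receive feature type `none`.  The pie distribution reports counts and
#' percentages of I-IV among the feature-typed probes.
#'
#' @param assignment a [classify_types()] result.
#' @param net a [tf_network()].
#' @return object of class `feature_type_assignment`: list with
#'   `assignment` (the input data.frame plus a `feature_type` column),
#'   `pie` (data.frame `feature_type`, `count`, `percent`), and `status`
#'   (`"ok"` or `"empty network"` / `"no feature-typed probes"`).
#' @export
feature_types <- function(assignment, net) {
  called <- called_probes(net)
  df <- assignment
  roman <- c("1" = "I", "2" = "II", "3" = "III", "4" = "IV")
  ft <- rep("none", nrow(df))
  in_net <- df$probe %in% called
  has_type <- df$type != "none"
  ft[in_net & has_type] <- roman[df$type[in_net & has_type]]
  df$feature_type <- ft
  status <- if (!length(called)) "empty network"
  else if (!any(ft != "none")) "no feature-typed probes"
  else "ok"
  cnt <- table(factor(ft[ft != "none"], levels = c("I", "II", "III", "IV")))
  tot <- sum(cnt)
  pie <- data.frame(feature_type = names(cnt), count = as.integer(cnt),
                    percent = if (tot > 0) round(100 * as.integer(cnt) / tot, 1)
                    else rep(0, 4),
                    stringsAsFactors = FALSE)
  structure(list(assignment = df, pie = pie, status = status,
                 tf = net$tf, cohort_name = net$cohort_name),
            class = "feature_type_assignment")
}

#' Probes of one feature type, as a gene pool
#' @param ft a [feature_types()] result.
#' @param type `"I"`, `"II"`, `"III"` or `"IV"`.
#' @return a [gene_pool()] whose provenance records TF, cohort and type.
#' @export
feature_type_pool <- function(ft, type = c("II", "I", "III", "IV")) {
  type <- match.arg(type)
  probes <- ft$assignment$probe[ft$assignment$feature_type == type]
  gene_pool(probes, sprintf("feature_type_%s", type),
            sprintf("feature type %s of TF %s network in cohort %s",
                    type, ft$tf, ft$cohort_name))
}

#' @export
print.feature_type_assignment <- function(x, ...) {
  cat(sprintf("feature_type_assignment (TF %s, cohort %s): %s\n",
              x$tf, x$cohort_name, x$status))
  print(x$pie, row.names = FALSE)
  invisible(x)
}

#' @export
plot.feature_type_assignment <- function(x, ...) {
  cnt <- x$pie$count
  if (sum(cnt) == 0) {
    graphics::plot.new(); graphics::title("no feature-typed probes")
    return(invisible(x))
  }
  graphics::pie(cnt[cnt > 0],
                labels = sprintf("%s (%d, %.0f%%)", x$pie$feature_type[cnt > 0],
                                 cnt[cnt > 0], x$pie$percent[cnt > 0]),
                main = sprintf("feature types, TF %s / %s", x$tf, x$cohort_name),
                ...)
  invisible(x)
}
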