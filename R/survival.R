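## Percentile-stratified Kaplan-Meier / log-rank machinery.  The two-group
## log-rank test and the product-limit curves are computed in the
## discrete-time formulation (exact tie handling) and vectorised across
## probes for the genome-wide typing scans.

#' Split samples at an upper percentile of a value vector
#'
#' The high group is the `round(fraction * n)` samples with the largest
#' values (ties broken by stable input order, so the split is invariant
#' under strictly monotone transforms); everyone else is low.
#'
#' @param values per-sample numeric vector (named by sample id if available).
#' @param fraction upper tail fraction in `(0, 0.5]` (default 0.10, the
#'   90th-percentile rule).
#' @return factor of levels `c("low", "high")`, same length/names as
#'   `values`.
#' @export
percentile_split <- function(values, fraction = 0.10) {
  n <- length(values)
  if (n < 10) stop("need at least 10 samples to split")
  if (fraction <= 0 || fraction > 0.5) stop("fraction must be in (0, 0.5]")
  if (length(unique(values)) == 1L) stop("degenerate split: all values identical")
  k <- round(fraction * n)
  if (k < 1) k <- 1L
  ord <- order(values, decreasing = TRUE)   # stable: ties keep input order
  g <- rep("low", n)
  g[ord[seq_len(k)]] <- "high"
  out <- factor(g, levels = c("low", "high"))
  names(out) <- names(values)
  out
}

# discrete-time two-group log-rank ingredients at the distinct event times
.logrank_tables <- function(time, event) {
  et <- sort(unique(time[event == 1]))
  n_t <- vapply(et, function(t) sum(time >= t), 0)
  d_t <- vapply(et, function(t) sum(time == t & event == 1), 0)
  list(event_times = et, n = n_t, d = d_t)
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival curves per group and the standard two-group
#' log-rank chi-square (discrete-time formulation, exact tie handling).
#' Direction is `high_poor` when the high group's curve lies below the low
#' group's at the last time both groups are still at risk, falling back to
#' the sign of (observed - expected) events in the high group when the
#' curves are equal there.
#'
#' @param time follow-up times (months), `>= 0`.
#' @param event 0/1 event indicators (at least one event overall).
#' @param group factor with levels `c("low", "high")` (see
#'   [percentile_split()]); both groups non-empty.
#' @return object of class `prognostic_call`: list with `chi2`, `p`,
#'   `direction` (`"high_poor"`/`"high_good"`), `observed`, `expected` (high
#'   group), `sizes`, and `curves` (per group a data.frame `time`, `surv`,
#'   `n_risk`, `n_event`).
#' @export
km_logrank <- function(time, event, group) {
  group <- factor(group, levels = c("low", "high"))
  ok <- !is.na(time) & !is.na(event) & !is.na(group)
  time <- time[ok]; event <- event[ok]; group <- group[ok]
  if (sum(event) < 1) stop("no events")
  if (any(table(group) == 0)) stop("one group is empty")
  tab <- .logrank_tables(time, event)
  hi <- group == "high"
  n1 <- vapply(tab$event_times, function(t) sum(time >= t & hi), 0)
  O <- sum(event == 1 & hi)
  E <- sum(n1 * tab$d / tab$n)
  vterm <- ifelse(tab$n > 1,
                  tab$d * (tab$n - tab$d) / (tab$n - 1) *
                    n1 * (tab$n - n1) / tab$n^2, 0)
  V <- sum(vterm)
  chi2 <- if (V > 0) (O - E)^2 / V else 0
  p <- if (V > 0) stats::pchisq(chi2, df = 1, lower.tail = FALSE) else 1

  curves <- lapply(levels(group), function(g) .km_curve(time[group == g],
                                                        event[group == g]))
  names(curves) <- levels(group)
  s_hi <- .km_eval(curves$high, min(max(time[hi]), max(time[!hi])))
  s_lo <- .km_eval(curves$low, min(max(time[hi]), max(time[!hi])))
  direction <- if (s_hi < s_lo) "high_poor"
  else if (s_hi > s_lo) "high_good"
  else if (O >= E) "high_poor" else "high_good"
  structure(list(chi2 = chi2, p = p, direction = direction,
                 observed = O, expected = E, variance = V,
                 sizes = table(group), curves = curves),
            class = "prognostic_call")
}

# product-limit estimate over one group's own event times
.km_curve <- function(time, event) {
  et <- sort(unique(time[event == 1]))
  if (!length(et))
    return(data.frame(time = numeric(0), surv = numeric(0),
                      n_risk = numeric(0), n_event = numeric(0)))
  n_t <- vapply(et, function(t) sum(time >= t), 0)
  d_t <- vapply(et, function(t) sum(time == t & event == 1), 0)
  data.frame(time = et, surv = cumprod(1 - d_t / n_t),
             n_risk = n_t, n_event = d_t)
}

# step-function evaluation of a KM curve at time t (1 before first event)
.km_eval <- function(curve, t) {
  if (!nrow(curve)) return(1)
  idx <- findInterval(t, curve$time)
  if (idx == 0) 1 else curve$surv[idx]
}

#' @export
print.prognostic_call <- function(x, ...) {
  cat(sprintf("prognostic_call: log-rank chi2 = %.4g, p = %.4g, %s (high %d vs low %d)\n",
              x$chi2, x$p, x$direction, x$sizes[["high"]], x$sizes[["low"]]))
  invisible(x)
}

#' @export
plot.prognostic_call <- function(x, ...) {
  graphics::plot(NA, xlim = c(0, max(1, unlist(lapply(x$curves, function(cv) cv$time)))),
                 ylim = c(0, 1), xlab = "time (months)", ylab = "survival",
                 main = sprintf("log-rank p = %.3g (%s)", x$p, x$direction), ...)
  cols <- c(low = "navy", high = "firebrick")
  for (g in names(x$curves)) {
    cv <- x$curves[[g]]
    graphics::lines(stats::stepfun(cv$time, c(1, cv$surv)), do.points = FALSE,
                    col = cols[[g]], lwd = 2)
  }
  graphics::legend("bottomleft", legend = names(x$curves), col = cols, lwd = 2,
                   bty = "n")
  invisible(x)
}

#' Genome-wide percentile-split log-rank scan
#'
#' For every probe: split the cohort at the upper `fraction` of that probe's
#' expression and log-rank test high vs low.  The discrete-time log-rank
#' ingredients that do not depend on the split (at-risk sets, event counts)
#' are computed once and shared, so the scan is a few matrix products.
#'
#' @param expr an [expr_matrix()].
#' @param clinical a [clinical_table()] covering the cohort.
#' @param cohort sample ids.
#' @param fraction upper-tail split fraction (default 0.10).
#' @return data.frame, one row per probe: `probe`, `chi2`, `p`, `direction`,
#'   `high_n`.
#' @export
prognostic_scan <- function(expr, clinical, cohort = colnames(expr),
                            fraction = 0.10) {
  keep <- match(cohort, clinical$sample_id)
  if (anyNA(keep)) stop("cohort samples missing from clinical table")
  time <- clinical$surv_time[keep]
  event <- clinical$event[keep]
  if (sum(event, na.rm = TRUE) < 1) stop("no events in cohort")
  sub <- unclass(expr)[, cohort, drop = FALSE]
  n <- length(cohort)
  k <- max(1L, round(fraction * n))
  tab <- .logrank_tables(time, event)
  m <- length(tab$event_times)
  # at-risk indicator matrix (samples x event times), fixed for the cohort
  R <- outer(time, tab$event_times, `>=`) * 1
  # high-group membership per probe (probes x samples)
  H <- t(apply(sub, 1L, function(y) {
    h <- numeric(n)
    h[order(y, decreasing = TRUE)[seq_len(k)]] <- 1
    h
  }))
  N1 <- H %*% R                                   # probes x event times
  O <- as.numeric(H %*% (event == 1))
  E <- as.numeric(N1 %*% (tab$d / tab$n))
  w <- ifelse(tab$n > 1, tab$d * (tab$n - tab$d) / ((tab$n - 1) * tab$n^2), 0)
  V <- as.numeric((N1 * sweep(-N1, 2L, tab$n, `+`)) %*% w)
  chi2 <- ifelse(V > 0, (O - E)^2 / V, 0)
  p <- ifelse(V > 0, stats::pchisq(chi2, df = 1, lower.tail = FALSE), 1)
  data.frame(probe = rownames(sub), chi2 = chi2, p = p,
             direction = ifelse(O >= E, "high_poor", "high_good"),
             high_n = k, stringsAsFactors = FALSE, row.names = NULL)
}
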