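## Signature extraction: the consensus (feature-type-II) poor-prognosis
## signature, the antagonistic (feature-type-IV) favorable signature,
## sample scoring, subcohort discovery, and K-M / Cox evaluation.

#' Construct a gene signature
#'
#' @param probes character vector of probe ids (unique, non-empty).
#' @param modes regulatory modes parallel to `probes` (`"up"`/`"down"`).
#' @param name signature name.
#' @param direction prognostic direction of a high score (`"poor"`/`"good"`).
#' @param provenance free text describing which overlap produced it.
#' @param tf_probe the driving TF's own probe id, if it is a member; kept
#'   but flagged so scoring can exclude it.
#' @return object of class `signature`: data.frame `probe`, `mode`,
#'   `is_tf`, with attributes `name`, `direction`, `provenance`, `status`.
#' @export
signature <- function(probes, modes, name, direction = "poor",
                      provenance = "manual", tf_probe = NULL) {
  probes <- as.character(probes)
  if (anyDuplicated(probes)) stop("signature probes must be unique")
  if (length(probes) && !all(modes %in% c("up", "down")))
    stop("modes must be 'up' or 'down'")
  df <- data.frame(probe = probes,
                   mode = if (length(probes)) modes else character(0),
                   is_tf = probes %in% (tf_probe %||% character(0)),
                   stringsAsFactors = FALSE)
  structure(df, name = name, direction = direction, provenance = provenance,
            status = if (nrow(df)) "ok" else "empty",
            class = c("signature", class(df)))
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("signature '%s' (%s prognosis when high): %d probes (%d scored)\n",
              attr(x, "name"), attr(x, "direction"), nrow(x), sum(!x$is_tf)))
  if (attr(x, "status") == "empty") cat("  status: empty\n")
  invisible(x)
}

#' Convert a packaged signature table to a scorable signature
#'
#' Turns a [load_packaged_signature()] table into a [signature()]: probes
#' are the feature numbers, modes default to `"up"` (elevated expression
#' tracks the tabulated prognosis direction), and the driving TF's own
#' probe, when present, is flagged so scoring excludes it.
#'
#' @param tab a `signature_table`.
#' @param tf_probe the driving TF's feature number (e.g. `"16670"`).
#' @param name signature name (default from the table's majority direction).
#' @return a [signature()].
#' @export
as_signature <- function(tab, tf_probe = NULL, name = "packaged") {
  dir <- names(which.max(table(tab$direction)))
  signature(tab$feature_number, rep("up", nrow(tab)), name,
            direction = dir, provenance = "packaged signature table",
            tf_probe = tf_probe)
}

#' Consensus signature from two feature-type pools
#'
#' Intersects a TF's feature-type-II pools from two cohorts (typically the
#' ER(-) and combined cohorts); modes are taken from the larger cohort's
#' network.  The driving TF's own probe, if present, is retained but
#' flagged for exclusion from scoring.  Symmetric in its two pool
#' arguments; an empty intersection yields an empty signature with status,
#' not an error.
#'
#' @param poolA,poolB [gene_pool()]s (feature-type-II pools of the same TF
#'   in two cohorts).
#' @param netA,netB the [tf_network()]s the pools derive from (modes and
#'   cohort sizes are read from them).
#' @param name signature name.
#' @return a [signature()].
#' @export
consensus_signature <- function(poolA, poolB, netA, netB,
                                name = "consensus") {
  inter <- intersect(poolA$probes, poolB$probes)
  bigger <- if (length(netB$cohort) > length(netA$cohort)) netB else netA
  modes <- bigger$records$mode[match(inter, bigger$records$target)]
  modes[is.na(modes)] <- "up"
  tf <- netA$tf
  probes <- inter
  if (tf %in% c(poolA$probes, poolB$probes) && !tf %in% probes) {
    # the TF's own probe never appears in its own scan records; if both
    # pools were built around it, carry it flagged
    probes <- c(tf, probes); modes <- c("up", modes)
  }
  signature(probes, modes, name, direction = "poor",
            provenance = sprintf("intersection of %s and %s", poolA$provenance,
                                 poolB$provenance),
            tf_probe = tf)
}

#' Antagonistic signature: shared targets with opposite regulatory modes
#'
#' Among a candidate pool of targets called in both networks, keeps the
#' probes whose regulatory mode differs between the two TFs (the
#' antagonistic regulation pattern); optionally restricted to probes
#' annotated as transcription factors.
#'
#' @param netA,netB two [tf_network()]s over the same probe universe.
#' @param candidates a [gene_pool()] (or character vector) of candidate
#'   probes; candidates not called in both networks are dropped with a
#'   warning.
#' @param tf_only restrict to probes in `tf_annotation`.
#' @param tf_annotation character vector of probe ids annotated as TFs
#'   (required when `tf_only`).
#' @param name signature name.
#' @return a [signature()] with modes taken from `netA` and direction
#'   `"good"` (the favorable signature convention).
#' @export
antagonistic_signature <- function(netA, netB, candidates, tf_only = FALSE,
                                   tf_annotation = NULL,
                                   name = "antagonistic") {
  cand <- if (inherits(candidates, "gene_pool")) candidates$probes
  else as.character(candidates)
  inA <- cand %in% called_probes(netA)
  inB <- cand %in% called_probes(netB)
  drop <- cand[!(inA & inB)]
  if (length(drop))
    warning(length(drop), " candidate(s) not called in both networks were dropped")
  cand <- cand[inA & inB]
  mA <- netA$records$mode[match(cand, netA$records$target)]
  mB <- netB$records$mode[match(cand, netB$records$target)]
  keep <- mA != mB
  probes <- cand[keep]
  modes <- mA[keep]
  if (tf_only) {
    if (is.null(tf_annotation)) stop("tf_only requires a tf_annotation list")
    sel <- probes %in% tf_annotation
    probes <- probes[sel]; modes <- modes[sel]
  }
  signature(probes, modes, name, direction = "good",
            provenance = sprintf("opposite modes of TFs %s and %s among %d shared candidates",
                                 netA$tf, netB$tf, length(cand)))
}

#' Score samples against a signature
#'
#' Mode-aligned mean z-score: each scored probe is z-standardised within the
#' cohort, down-mode probes are negated, and the per-sample score is the
#' mean across probes.  The driving TF's flagged probe is excluded unless
#' `include_tf`.
#'
#' @param expr an [expr_matrix()].
#' @param sig a [signature()].
#' @param cohort sample ids (default all).
#' @param include_tf include the flagged TF probe in the score.
#' @return named numeric vector of per-sample scores; probes absent from
#'   the matrix are dropped with a warning.
#' @export
signature_score <- function(expr, sig, cohort = colnames(expr),
                            include_tf = FALSE) {
  use <- sig[!sig$is_tf | include_tf, , drop = FALSE]
  present <- use$probe %in% rownames(expr)
  if (any(!present))
    warning(sum(!present), " signature probe(s) absent from matrix: ",
            paste(use$probe[!present], collapse = ", "))
  use <- use[present, , drop = FALSE]
  if (!nrow(use)) stop("no signature probe overlaps the expression matrix")
  sub <- unclass(expr)[use$probe, cohort, drop = FALSE]
  z <- t(scale(t(sub)))
  z[use$mode == "down", ] <- -z[use$mode == "down", , drop = FALSE]
  score <- colMeans(z, na.rm = TRUE)
  names(score) <- cohort
  score
}

#' Discover signature-defined subcohorts
#'
#' The subcohort is the top `round(fraction * n)` scores; the control group
#' is either everyone else (`"complement"`) or the equal-size lowest-score
#' group (`"matched_size"`, mirroring equal-size subcohort pairs; remaining
#' samples are `NA`).
#'
#' @param score per-sample signature scores.
#' @param fraction upper-tail fraction (default 0.10).
#' @param control_rule `"complement"` or `"matched_size"`.
#' @return factor with levels `c("control", "subcohort")` (NA outside the
#'   matched groups under `"matched_size"`).
#' @export
discover_subcohorts <- function(score, fraction = 0.10,
                                control_rule = c("complement", "matched_size")) {
  control_rule <- match.arg(control_rule)
  n <- length(score)
  if (n < 10) stop("need at least 10 samples")
  if (fraction <= 0 || fraction > 0.5) stop("fraction must be in (0, 0.5]")
  if (length(unique(score)) == 1L) stop("degenerate split: all scores identical")
  k <- max(1L, round(fraction * n))
  ord_hi <- order(score, decreasing = TRUE)
  g <- rep(NA_character_, n)
  g[ord_hi[seq_len(k)]] <- "subcohort"
  if (control_rule == "complement") {
    g[is.na(g)] <- "control"
  } else {
    ord_lo <- order(score)
    lo <- setdiff(ord_lo, ord_hi[seq_len(k)])[seq_len(k)]
    g[lo] <- "control"
  }
  out <- factor(g, levels = c("control", "subcohort"))
  names(out) <- names(score)
  out
}

#' Evaluate grouped samples with K-M/log-rank and Cox models
#'
#' Kaplan-Meier curves with the two-group log-rank test on the grouping,
#' a univariate Cox proportional-hazards fit on the group indicator, and a
#' multivariate Cox fit adding the configured clinical covariates
#' (`survival::coxph`, Efron ties).  Hazard ratios are reported with 95%
#' Wald confidence intervals; non-convergence is reported as a status, never
#' a silent zero.
#'
#' @param clinical a [clinical_table()].
#' @param groups named factor (names = sample ids) with two levels, the
#'   second level being the tested group.
#' @param covariates clinical column names for the multivariate model
#'   (default `c("grade", "tumor_size", "lnm")`; ignored if absent).
#' @return object of class `signature_evaluation`: list with `logrank`
#'   (a [km_logrank()] call), `cox_uni`, `cox_multi` (data.frames `term`,
#'   `hr`, `lo95`, `hi95`, `p`), `status`, `n`, `n_events`.
#' @export
evaluate_signature <- function(clinical, groups,
                               covariates = c("grade", "tumor_size", "lnm")) {
  ids <- names(groups)
  if (is.null(ids)) stop("groups must be named by sample id")
  keep <- !is.na(groups)
  ids <- ids[keep]; groups <- droplevels(factor(groups[keep]))
  idx <- match(ids, clinical$sample_id)
  if (anyNA(idx)) stop("group samples missing from clinical table")
  time <- clinical$surv_time[idx]; event <- clinical$event[idx]
  if (sum(event) < 1) stop("no events")
  lr_groups <- factor(ifelse(groups == levels(groups)[2L], "high", "low"),
                      levels = c("low", "high"))
  lr <- km_logrank(time, event, lr_groups)

  covariates <- intersect(covariates, names(clinical))
  df <- data.frame(time = time, event = event, group = lr_groups)
  for (cv in covariates) df[[cv]] <- clinical[[cv]][idx]

  fit_cox <- function(formula) {
    out <- tryCatch({
      fit <- withCallingHandlers(
        survival::coxph(formula, data = df, ties = "efron"),
        warning = function(w) {
          if (grepl("converge|infinite|Loglik", conditionMessage(w)))
            stop(conditionMessage(w), call. = FALSE)
          invokeRestart("muffleWarning")
        })
      s <- summary(fit)
      data.frame(term = rownames(s$coefficients),
                 loghr = s$coefficients[, "coef"],
                 se = s$coefficients[, "se(coef)"],
                 hr = s$conf.int[, "exp(coef)"],
                 lo95 = s$conf.int[, "lower .95"],
                 hi95 = s$conf.int[, "upper .95"],
                 p = s$coefficients[, "Pr(>|z|)"],
                 stringsAsFactors = FALSE, row.names = NULL)
    }, error = function(e) structure(list(message = conditionMessage(e)),
                                     class = "cox_failure"))
    out
  }
  uni <- fit_cox(survival::Surv(time, event) ~ group)
  multi <- if (length(covariates))
    fit_cox(stats::as.formula(paste("survival::Surv(time, event) ~ group +",
                                    paste(covariates, collapse = " + "))))
  else NULL
  status <- if (inherits(uni, "cox_failure")) paste("univariate Cox did not converge:", uni$message)
  else if (inherits(multi, "cox_failure")) paste("multivariate Cox did not converge:", multi$message)
  else "ok"
  structure(list(logrank = lr, cox_uni = uni, cox_multi = multi,
                 status = status, n = length(ids), n_events = sum(event)),
            class = "signature_evaluation")
}

#' @export
print.signature_evaluation <- function(x, ...) {
  cat(sprintf("signature_evaluation: n = %d (%d events), status: %s\n",
              x$n, x$n_events, x$status))
  print(x$logrank)
  if (!inherits(x$cox_uni, "cox_failure")) {
    cat("univariate Cox:\n"); print(x$cox_uni, row.names = FALSE)
  }
  if (!is.null(x$cox_multi) && !inherits(x$cox_multi, "cox_failure")) {
    cat("multivariate Cox:\n"); print(x$cox_multi, row.names = FALSE)
  }
  invisible(x)
}
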