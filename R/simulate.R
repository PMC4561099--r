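#' Simulation configuration for a synthetic breast-tumor cohort
#'
#' Defines the generative conditions the pipeline is validated under,
#' emulating the 181-sample study design: seven receptor-defined subtype
#' blocks (ER(+): IE 61, IIE 29; ER(-): TN 48, ERBB2 29, plus the three
#' small ER(-) PR/HER subgroups 5/6/3), a driver TF (`"A"`) with linear,
#' threshold and quadratic targets, an antagonistic second TF (`"B"`)
#' sharing a subset of the linear targets with opposite sign, ordinal
#' histology covariates monotonically linked to the driver TF, and
#' exponential survival tied to a planted 16-probe signature.
#'
#' Planted edge classes (all with coefficient `beta` and noise `noise_sd`):
#' \describe{
#'   \item{linear}{`beta * TF_A + e` — detectable by GPCC and CID.}
#'   \item{threshold}{`beta * 1[TF_A > its 75th percentile] + e` — the
#'     nonlinear dose-response class CID exists to catch.}
#'   \item{quadratic}{`beta * (TF_A - mean)^2 + e` — zero-correlation
#'     nonlinear class.}
#'   \item{shared (antagonistic)}{`beta * TF_A - beta * TF_B + e`, counted
#'     as one edge of each TF.}
#' }
#' Defaults give 40 TF-A edges (20 linear / 10 threshold / 10 quadratic)
#' plus 10 TF-B edges on shared linear targets: 50 edges in total.
#'
#' The true prognostic signature is a 15-probe module: the 10 exclusive
#' linear and first 5 threshold targets of TF A additionally load (with
#' coefficient `latent_coef`) on a latent per-sample prognostic factor
#' `u ~ N(0,1)` that is independent of both TFs.  The true signature score
#' (the observable quantity a recovered signature should reproduce) is the
#' module's mode-aligned mean z-score; survival is exponential with hazard
#' `lambda0 * exp(hazard_coef * u)` — the latent program of which the
#' module score is the expression proxy — applied in ER(-) samples only when
#' `er_specific` (the planted effect is cohort-specific, which is what
#' makes the signature feature-type II rather than type 1).  Tying the
#' hazard to the latent factor rather than to the TF itself makes the
#' signature module the only genuinely prognostic part of the network, so
#' recovery is well defined.  Censoring is an independent exponential
#' giving a baseline censoring probability `censoring_rate`.
#'
#' @param blocks named integer vector of subtype block sizes.
#' @param n_probes total number of probes (default 2000; set 22000 for
#'   study-scale realism).
#' @param n_linear,n_threshold,n_quadratic planted TF-A target counts.
#' @param n_shared how many linear targets are antagonistically shared with
#'   TF B (must be <= `n_linear`).
#' @param beta planted effect size (default 1).
#' @param noise_sd residual standard deviation of target probes (default 1).
#' @param grade_link_sd noise of the latent monotone link from TF A to the
#'   grade/nuclear-pleomorphism/mitotic-count ordinals (default 1).
#' @param latent_coef loading of the signature probes on the latent
#'   prognostic factor (default 1.2, so the prognostic program dominates
#'   the TF link within the module and the module score is recoverable).
#' @param er_shift elevation (log2 units) of the signature probes in ER(-)
#'   samples (default 0.8): the signature module is enriched in the ER(-)
#'   subtype, so the combined-cohort upper decile of a signature probe is
#'   predominantly ER(-) — the property that makes the module prognostic in
#'   the combined cohort as well as the ER(-) one.
#' @param lambda0 baseline hazard per month (default 0.01).
#' @param hazard_coef log-hazard per unit of the latent factor
#'   (default 2.5, a pronounced planted effect).
#' @param censoring_rate baseline probability of censoring before the event,
#'   in `[0, 1)` (default 0.4).
#' @param er_specific logical; hazard acts in ER(-) samples only
#'   (default TRUE).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(blocks = c(IE = 61L, IIE = 29L, TN = 48L, ERBB2 = 29L,
                                  ERnPRpHERn = 5L, ERnPRpHERp = 6L, ERnHERu = 3L),
                       n_probes = 2000L,
                       n_linear = 20L, n_threshold = 10L, n_quadratic = 10L,
                       n_shared = 10L,
                       beta = 1, noise_sd = 1, grade_link_sd = 1,
                       latent_coef = 1.2, er_shift = 0.8,
                       lambda0 = 0.01, hazard_coef = 2.5,
                       censoring_rate = 0.4, er_specific = TRUE) {
  if (any(blocks < 0)) stop("block sizes must be >= 0")
  if (sum(blocks) == 0) stop("block sizes sum to 0")
  if (n_shared > n_linear) stop("n_shared must be <= n_linear")
  if (!is.finite(beta) || !is.finite(noise_sd)) stop("effect sizes must be finite")
  if (censoring_rate < 0 || censoring_rate >= 1) stop("censoring_rate must be in [0,1)")
  n_targets <- n_linear + n_threshold + n_quadratic
  if (n_probes < n_targets + 2L) stop("n_probes too small for the planted design")
  structure(list(blocks = blocks, n_probes = as.integer(n_probes),
                 n_linear = as.integer(n_linear),
                 n_threshold = as.integer(n_threshold),
                 n_quadratic = as.integer(n_quadratic),
                 n_shared = as.integer(n_shared),
                 beta = beta, noise_sd = noise_sd,
                 grade_link_sd = grade_link_sd, latent_coef = latent_coef,
                 er_shift = er_shift,
                 lambda0 = lambda0, hazard_coef = hazard_coef,
                 censoring_rate = censoring_rate, er_specific = er_specific),
            class = "sim_config")
}

# ordinal from a latent monotone link to the driver TF: latent = z(tf)+noise,
# cut at fixed quantiles -> levels 1..3
.ordinal_link <- function(tf, sd, probs = c(0.3, 0.7)) {
  latent <- as.numeric(scale(tf)) + stats::rnorm(length(tf), 0, sd)
  cuts <- stats::quantile(latent, probs = probs, names = FALSE)
  findInterval(latent, cuts) + 1L
}

#' Generate a synthetic expression + clinical + survival cohort
#'
#' Draws a cohort under a [sim_config()]: the driver TF and antagonist are
#' standard Gaussian, planted targets follow their edge forms, all other
#' probes are independent noise; histology ordinals carry a monotone link to
#' the driver TF; survival is exponential with the planted signature hazard.
#' Fully reproducible from `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `expr` ([expr_matrix()]), `clinical`
#'   ([clinical_table()]), and `truth` (list: `edges` data.frame
#'   (tf/target/form/beta), `signature` data.frame (probe/mode/direction),
#'   `score` named per-sample true module score, `latent` the latent
#'   hazard-driving factor, `tf_a`, `tf_b` probe ids).
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  n <- sum(config$blocks)
  p <- config$n_probes
  sample_ids <- sprintf("S%03d", seq_len(n))
  probe_ids <- as.character(seq_len(p))
  block <- rep(names(config$blocks), config$blocks)

  tf_a <- stats::rnorm(n)
  tf_b <- stats::rnorm(n)
  u <- stats::rnorm(n)      # latent prognostic factor, independent of both TFs
  nl <- config$n_linear; nt <- config$n_threshold; nq <- config$n_quadratic
  ns <- config$n_shared
  # probe layout: 1 = TF A, 2 = TF B, then linear (shared first), threshold,
  # quadratic targets, then noise
  id_a <- probe_ids[1L]; id_b <- probe_ids[2L]
  lin_ids <- probe_ids[2L + seq_len(nl)]
  shared_ids <- lin_ids[seq_len(ns)]
  thr_ids <- probe_ids[2L + nl + seq_len(nt)]
  quad_ids <- probe_ids[2L + nl + nt + seq_len(nq)]
  beta <- config$beta; nsd <- config$noise_sd

  vals <- matrix(stats::rnorm(p * n), nrow = p, ncol = n,
                 dimnames = list(probe_ids, sample_ids))
  vals[id_a, ] <- tf_a
  vals[id_b, ] <- tf_b
  thr_ind <- as.numeric(tf_a > stats::quantile(tf_a, 0.75, names = FALSE))
  excl_lin <- setdiff(lin_ids, shared_ids)
  sig_probes <- c(excl_lin[seq_len(min(10L, length(excl_lin)))],
                  thr_ids[seq_len(min(5L, nt))])
  gam <- config$latent_coef
  for (pr in lin_ids) {
    sh <- pr %in% shared_ids
    vals[pr, ] <- beta * tf_a - (if (sh) beta * tf_b else 0) +
      (if (pr %in% sig_probes) gam * u else 0) + stats::rnorm(n, 0, nsd)
  }
  for (pr in thr_ids) vals[pr, ] <- beta * thr_ind +
    (if (pr %in% sig_probes) gam * u else 0) + stats::rnorm(n, 0, nsd)
  for (pr in quad_ids) vals[pr, ] <- beta * (tf_a - mean(tf_a))^2 +
    stats::rnorm(n, 0, nsd)

  gene_symbols <- sprintf("G%04d", seq_len(p))
  gene_symbols[1:2] <- c("TFA", "TFB")

  edges <- rbind(
    data.frame(tf = id_a, target = lin_ids, form = "linear", beta = beta,
               stringsAsFactors = FALSE),
    data.frame(tf = id_a, target = thr_ids, form = "threshold", beta = beta,
               stringsAsFactors = FALSE),
    data.frame(tf = id_a, target = quad_ids, form = "quadratic", beta = beta,
               stringsAsFactors = FALSE),
    data.frame(tf = id_b, target = shared_ids, form = "linear", beta = -beta,
               stringsAsFactors = FALSE)
  )

  signature <- data.frame(probe = sig_probes, mode = "up", direction = "poor",
                          stringsAsFactors = FALSE)

  er <- ifelse(block %in% c("IE", "IIE"), "+", "-")
  # subtype enrichment of the signature module in ER(-) tumors
  if (config$er_shift != 0)
    vals[sig_probes, ] <- sweep(vals[sig_probes, , drop = FALSE], 2L,
                                config$er_shift * (er == "-"), `+`)
  expr <- expr_matrix(vals, gene_symbols = gene_symbols)
  # observable score of the true module: mode-aligned mean z (all up-mode)
  score <- colMeans(t(scale(t(vals[sig_probes, , drop = FALSE]))))
  pr_st <- ifelse(block %in% c("IE", "ERnPRpHERn", "ERnPRpHERp"), "+", "-")
  her <- rep("-", n)
  her[block %in% c("ERBB2", "ERnPRpHERp")] <- "+"
  her[block == "ERnHERu"] <- NA_character_

  grade <- .ordinal_link(tf_a, config$grade_link_sd)
  np <- .ordinal_link(tf_a, config$grade_link_sd)
  mc <- .ordinal_link(tf_a, config$grade_link_sd)
  tub <- sample(1:3, n, replace = TRUE)
  lvi <- stats::rbinom(n, 1, 0.4)
  lym <- stats::rbinom(n, 1, 0.5)
  lnm <- stats::rpois(n, 2)
  age <- round(pmin(pmax(stats::rnorm(n, 53, 11), 25), 90))
  size <- round(stats::rlnorm(n, log(2.5), 0.4), 1)
  stage <- sample(1:3, n, replace = TRUE, prob = c(0.3, 0.5, 0.2))

  at_risk <- if (config$er_specific) as.numeric(er == "-") else rep(1, n)
  hz <- config$lambda0 * exp(config$hazard_coef * u * at_risk)
  t_event <- stats::rexp(n, hz)
  cr <- config$censoring_rate
  t_cens <- if (cr > 0) stats::rexp(n, config$lambda0 * cr / (1 - cr)) else rep(Inf, n)
  surv_time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  # break potential ties before downstream rank operations
  surv_time <- surv_time + stats::runif(n) * 1e-9

  clinical <- clinical_table(data.frame(
    sample_id = sample_ids, block = block,
    er_status = er, pr_status = pr_st, her_status = her,
    grade = grade, nuclear_pleomorphism = np, mitotic_count = mc,
    tubule_formation = tub, lvi = lvi, lym = lym, lnm = lnm,
    age = age, tumor_size = size, stage = stage,
    surv_time = surv_time, event = event,
    stringsAsFactors = FALSE))

  list(expr = expr, clinical = clinical,
       truth = list(edges = edges, signature = signature,
                    score = stats::setNames(score, sample_ids),
                    latent = stats::setNames(u, sample_ids),
                    tf_a = id_a, tf_b = id_b))
}

#' Generate an i.i.d. standard Gaussian expression matrix
#'
#' Null calibration harness: no structure at all.
#'
#' @param n_probes,n_samples dimensions (each >= 2).
#' @param seed integer seed.
#' @return an [expr_matrix()].
#' @export
simulate_null_matrix <- function(n_probes, n_samples, seed = 1) {
  if (n_probes < 2 || n_samples < 2) stop("need n_probes, n_samples >= 2")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  vals <- matrix(stats::rnorm(n_probes * n_samples), nrow = n_probes,
                 dimnames = list(as.character(seq_len(n_probes)),
                                 sprintf("S%03d", seq_len(n_samples))))
  expr_matrix(vals)
}
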