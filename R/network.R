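## Supervised TF network: scan every probe against a driver TF with CID
## (permutation-calibrated) and GPCC, call edges by the union rule
## (CIDUGPCC), and assign regulatory modes.

# pooled permutation null for the CID over a probe scan: for tie-free y the
# CID is a rank statistic, so its permutation distribution depends only on
# (n, bin sizes); one set of B draws serves every tie-free probe with the
# same n.  Probes whose values contain ties fall back to per-probe
# permutations.
.cid_null_draws <- function(n, K, B, seed) {
  st <- .cid_structure(seq_len(n))
  b <- .rank_bins(seq_len(n), K)
  smax <- sum(.cid_addends(st, .max_sep_labels(st, b$sizes), b$sizes))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  draws <- numeric(B)
  for (i in seq_len(B))
    draws[i] <- sum(.cid_addends(st, sample(b$g), b$sizes)) / smax
  sort(draws)
}

# p = (1 + #{null >= obs}) / (B + 1), with the null draws pre-sorted
.p_from_null <- function(obs, sorted_null) {
  B <- length(sorted_null)
  ge <- B - findInterval(obs, sorted_null, left.open = TRUE)
  (1 + ge) / (B + 1)
}

# mode cascade for a called edge: GPCC sign when informative, else Spearman
# sign, else sign of (mean of top x-bin - mean of bottom x-bin)
.edge_mode <- function(y, x, r, K, informative = 0.1) {
  if (is.finite(r) && abs(r) >= informative) return(if (r > 0) "up" else "down")
  rho <- suppressWarnings(stats::cor(y, x, method = "spearman",
                                     use = "pairwise.complete.obs"))
  if (is.finite(rho) && abs(rho) >= informative) return(if (rho > 0) "up" else "down")
  b <- .rank_bins(x, K)
  d <- mean(y[b$g == K], na.rm = TRUE) - mean(y[b$g == 1L], na.rm = TRUE)
  if (isTRUE(d < 0)) "down" else "up"
}

#' Fit a supervised TF transcriptional regulatory network
#'
#' For every probe other than the driver TF, computes the CID (with
#' permutation p-value) and the GPCC (with t-reference p-value) against the
#' TF's expression over the chosen cohort, adjusts both p-value columns for
#' multiple testing, and calls an edge when either adjusted p-value passes
#' `alpha` (the CIDUGPCC union rule).  Called edges receive a regulatory
#' mode (`up`/`down`) via a cascade: GPCC sign if `|r| >= 0.1`, else
#' Spearman sign, else the top-minus-bottom conditioning-bin mean difference.
#'
#' @param expr an [expr_matrix()].
#' @param tf probe id of the driver TF.
#' @param cohort character vector of sample ids (default: all samples).
#' @param cohort_name label stored on the fit.
#' @param K conditioning bins for the CID (default 5).
#' @param B permutation count (default 4999 for scans).  With `m` probes
#'   and BH control at level `alpha`, adjusted p-values near the calling
#'   boundary are of order `alpha * k / m` (`k` = discovery count), so the
#'   permutation floor `1/(B+1)` must lie well below that; for a
#'   2000-probe scan expecting tens of discoveries, `B = 1000` sits exactly
#'   at the boundary and `B = 4999` gives headroom.  The pooled null makes
#'   large `B` cheap.
#' @param alpha edge-calling significance level on adjusted p (default 0.05).
#' @param mtc multiple-testing procedure: `"BH"` (default), `"bonferroni"`,
#'   or `"none"`.
#' @param seed master seed; per-probe permutation streams (used when a probe
#'   needs its own permutations) are derived from it per probe id, so results
#'   are independent of scan order.
#' @param null `"pooled"` (default) shares one permutation null across
#'   tie-free probes with equal n; `"per_probe"` forces per-probe
#'   permutations everywhere.
#' @return object of class `tf_network`: list with `tf`, `cohort_name`,
#'   `params`, and `records` (one row per scanned probe: `target`,
#'   `gene_symbol`, `cid`, `p_cid`, `q_cid`, `gpcc`, `p_gpcc`, `q_gpcc`,
#'   `n_used`, `called`, `mode`).
#' @export
tf_network <- function(expr, tf, cohort = colnames(expr),
                       cohort_name = "all", K = 5, B = 4999, alpha = 0.05,
                       mtc = c("BH", "bonferroni", "none"), seed = 1,
                       null = c("pooled", "per_probe")) {
  mtc <- match.arg(mtc)
  null <- match.arg(null)
  if (!tf %in% rownames(expr)) stop("tf probe '", tf, "' not in expression matrix")
  miss <- setdiff(cohort, colnames(expr))
  if (length(miss)) stop("cohort samples not in matrix: ", paste(miss, collapse = ", "))
  if (length(cohort) < 2 * K) stop("cohort smaller than 2*K samples")
  sub <- unclass(expr)[, cohort, drop = FALSE]
  x <- sub[tf, ]
  targets <- setdiff(rownames(sub), tf)
  syms <- gene_symbols(expr)[targets]

  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  # child seeds keyed to sorted probe ids, so per-probe permutation streams
  # do not depend on the scan (row) order of the matrix
  probe_seeds <- stats::setNames(sample.int(.Machine$integer.max, length(targets)),
                                 sort(targets))
  null_cache <- new.env(parent = emptyenv())
  np <- length(targets)
  cid_v <- p_cid <- r_v <- p_r <- rep(NA_real_, np)
  n_used <- integer(np)

  for (i in seq_len(np)) {
    y <- sub[targets[i], ]
    pc <- .pairwise_complete(y, x)
    n_used[i] <- pc$n
    if (pc$n < max(2 * K, 3)) next
    if (length(unique(pc$x)) == 1L) { cid_v[i] <- 0; p_cid[i] <- 1 } else {
      ties <- anyDuplicated(pc$y) > 0L
      if (null == "per_probe" || ties) {
        pt <- cid_perm_test(pc$y, pc$x, K = K, B = B,
                            seed = probe_seeds[[targets[i]]])
        cid_v[i] <- as.numeric(pt$cid); p_cid[i] <- pt$p_value
      } else {
        key <- as.character(pc$n)
        if (is.null(null_cache[[key]]))
          null_cache[[key]] <- .cid_null_draws(pc$n, K, B, seed)
        cid_v[i] <- as.numeric(cid(pc$y, pc$x, K = K))
        p_cid[i] <- .p_from_null(cid_v[i], null_cache[[key]])
      }
    }
    # GPCC: vector form of the cor.test t reference
    sdy <- stats::sd(pc$y); sdx <- stats::sd(pc$x)
    if (sdy == 0 || sdx == 0) { r_v[i] <- 0; p_r[i] <- NA_real_ } else {
      r <- stats::cor(pc$y, pc$x)
      tt <- r * sqrt((pc$n - 2) / max(1 - r^2, .Machine$double.eps))
      r_v[i] <- r
      p_r[i] <- 2 * stats::pt(-abs(tt), df = pc$n - 2)
    }
  }

  q_cid <- stats::p.adjust(p_cid, method = if (mtc == "none") "none" else mtc)
  q_r <- stats::p.adjust(p_r, method = if (mtc == "none") "none" else mtc)
  called <- (!is.na(q_cid) & q_cid <= alpha) | (!is.na(q_r) & q_r <= alpha)
  mode <- rep(NA_character_, np)
  for (i in which(called))
    mode[i] <- .edge_mode(sub[targets[i], ], x, r_v[i], K)

  records <- data.frame(target = targets, gene_symbol = unname(syms),
                        cid = cid_v, p_cid = p_cid, q_cid = q_cid,
                        gpcc = r_v, p_gpcc = p_r, q_gpcc = q_r,
                        n_used = n_used, called = called, mode = mode,
                        stringsAsFactors = FALSE)
  structure(list(tf = tf, tf_symbol = unname(gene_symbols(expr)[tf]),
                 cohort_name = cohort_name, cohort = cohort,
                 params = list(K = K, B = B, alpha = alpha, mtc = mtc,
                               seed = seed, null = null),
                 records = records),
            class = "tf_network")
}

#' Called probes of a TF network
#' @param net a `tf_network`.
#' @param mode optionally restrict to `"up"` or `"down"` edges.
#' @return character vector of called target probe ids.
#' @export
called_probes <- function(net, mode = NULL) {
  rec <- net$records[net$records$called, , drop = FALSE]
  if (!is.null(mode)) rec <- rec[rec$mode == mode, , drop = FALSE]
  rec$target
}

#' @export
print.tf_network <- function(x, ...) {
  rec <- x$records
  cat(sprintf("tf_network: TF %s (%s), cohort %s (%d samples)\n",
              x$tf, x$tf_symbol %||% "?", x$cohort_name, length(x$cohort)))
  cat(sprintf("  %d probes scanned, %d called (%d/%d up/down)  [K=%d, B=%d, %s q<=%.3g]\n",
              nrow(rec), sum(rec$called),
              sum(rec$mode == "up", na.rm = TRUE),
              sum(rec$mode == "down", na.rm = TRUE),
              x$params$K, x$params$B, x$params$mtc, x$params$alpha))
  invisible(x)
}

#' @export
summary.tf_network <- function(object, n_top = 10, ...) {
  rec <- object$records[order(object$records$p_cid), ]
  print(object)
  cat("top associations by CID p-value:\n")
  print(utils::head(rec[, c("target", "gene_symbol", "cid", "q_cid",
                            "gpcc", "q_gpcc", "called", "mode")], n_top),
        row.names = FALSE)
  invisible(object)
}

#' @export
plot.tf_network <- function(x, ...) {
  rec <- x$records
  col <- ifelse(!rec$called, "grey60", ifelse(rec$mode == "up", "firebrick", "navy"))
  graphics::plot(rec$gpcc, rec$cid, col = col, pch = 16, cex = 0.6,
                 xlab = "GPCC (Pearson r)", ylab = "CID",
                 main = sprintf("%s network, cohort %s", x$tf, x$cohort_name), ...)
  graphics::legend("topleft", pch = 16, col = c("firebrick", "navy", "grey60"),
                   legend = c("called, up", "called, down", "not called"),
                   bty = "n", cex = 0.8)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a

## ---- clinical-relevance pools ---------------------------------------------

#' Per-probe one-way ANOVA pool for a clinical parameter
#'
#' Screens every probe for differential expression across the levels of an
#' ordinal/categorical clinical parameter within a cohort (classical one-way
#' ANOVA via `stats::oneway.test`; Welch correction by `welch = TRUE`),
#' returning the pool of probes passing the adjusted-p threshold.
#'
#' @param expr an [expr_matrix()].
#' @param clinical a [clinical_table()].
#' @param param clinical column name to test.
#' @param cohort sample ids (default all).
#' @param alpha significance level on adjusted p (default 0.05).
#' @param mtc `"BH"`, `"bonferroni"` or `"none"`.
#' @param welch use the Welch (unequal-variance) statistic.
#' @return object of class `gene_pool`: list with `label`, `probes`,
#'   `provenance`, `p_values`.
#' @export
anova_pool <- function(expr, clinical, param, cohort = colnames(expr),
                       alpha = 0.05, mtc = c("BH", "bonferroni", "none"),
                       welch = FALSE) {
  mtc <- match.arg(mtc)
  if (!param %in% names(clinical)) stop("unknown clinical parameter: ", param)
  keep <- match(cohort, clinical$sample_id)
  if (anyNA(keep)) stop("cohort samples missing from clinical table")
  fac <- clinical[[param]][keep]
  ok <- !is.na(fac)
  fac <- factor(fac[ok])
  cohort_ok <- cohort[ok]
  tabf <- table(fac)
  drop_lv <- names(tabf)[tabf < 2]
  if (length(drop_lv)) {
    warning("dropping level(s) with < 2 samples for '", param, "': ",
            paste(drop_lv, collapse = ", "))
    keep2 <- !(fac %in% drop_lv)
    fac <- droplevels(fac[keep2]); cohort_ok <- cohort_ok[keep2]
  }
  if (nlevels(fac) < 2) stop("fewer than 2 usable levels for '", param, "'")
  sub <- unclass(expr)[, cohort_ok, drop = FALSE]
  pv <- apply(sub, 1L, function(y) {
    if (sum(!is.na(y)) < nlevels(fac) + 1 || stats::sd(y, na.rm = TRUE) == 0)
      return(NA_real_)
    tryCatch(stats::oneway.test(y ~ fac, var.equal = !welch)$p.value,
             error = function(e) NA_real_)
  })
  q <- stats::p.adjust(pv, method = if (mtc == "none") "none" else mtc)
  pool <- rownames(sub)[!is.na(q) & q <= alpha]
  structure(list(label = param, probes = pool,
                 provenance = sprintf("anova_pool(param=%s, cohort_n=%d, alpha=%g, mtc=%s, welch=%s)",
                                      param, length(cohort_ok), alpha, mtc, welch),
                 p_values = q),
            class = "gene_pool")
}

#' Construct a gene pool by hand
#' @param probes character vector of probe ids.
#' @param label pool label.
#' @param provenance free-text provenance (required, non-empty).
#' @return a `gene_pool`.
#' @export
gene_pool <- function(probes, label, provenance) {
  if (!nzchar(provenance)) stop("provenance must be non-empty")
  structure(list(label = label, probes = unique(as.character(probes)),
                 provenance = provenance),
            class = "gene_pool")
}

#' @export
print.gene_pool <- function(x, ...) {
  cat(sprintf("gene_pool '%s': %d probes [%s]\n", x$label,
              length(x$probes), x$provenance))
  invisible(x)
}

#' Clinically significant cluster of a TF
#'
#' Restricts a list of clinical-parameter gene pools to those containing the
#' TF's own probe (the parameters for which the TF is itself a clinically
#' relevant determinant) and intersects them; the TF probe is reported
#' separately, not inside the cluster.
#'
#' @param tf TF probe id.
#' @param pools list of `gene_pool` objects.
#' @return a `gene_pool` labelled `"clinically_significant_cluster"` with
#'   attribute `status` (`"ok"` or `"tf not clinically relevant"`) and
#'   attribute `parameters` naming the contributing pools.
#' @export
clinically_significant_cluster <- function(tf, pools) {
  has_tf <- vapply(pools, function(p) tf %in% p$probes, TRUE)
  if (!any(has_tf)) {
    out <- gene_pool(character(0), "clinically_significant_cluster",
                     sprintf("intersection of 0 pools containing TF %s", tf))
    attr(out, "status") <- "tf not clinically relevant"
    attr(out, "parameters") <- character(0)
    return(out)
  }
  rel <- pools[has_tf]
  inter <- Reduce(intersect, lapply(rel, `[[`, "probes"))
  inter <- setdiff(inter, tf)
  out <- gene_pool(inter, "clinically_significant_cluster",
                   sprintf("intersection of pools {%s} containing TF %s",
                           paste(vapply(rel, `[[`, "", "label"), collapse = ", "), tf))
  attr(out, "status") <- "ok"
  attr(out, "parameters") <- vapply(rel, `[[`, "", "label")
  out
}

#' Venn decomposition of 2-4 gene pools
#'
#' Enumerates every Venn region (each non-empty membership pattern over the
#' pools) with exact probe membership; region sizes sum to the union size.
#'
#' @param pools list of 2-4 `gene_pool` objects (or plain character vectors).
#' @return object of class `venn_result`: list with `regions` (named list of
#'   probe vectors, names like `"A&B"`), `sizes`, and `pool_names`.
#' @export
venn_pools <- function(pools) {
  if (length(pools) < 2 || length(pools) > 4)
    stop("venn_pools renders 2-4 pools; intersect repeatedly for more")
  sets <- lapply(pools, function(p) if (inherits(p, "gene_pool")) p$probes else as.character(p))
  nms <- names(pools)
  if (is.null(nms) || any(!nzchar(nms)))
    nms <- vapply(seq_along(pools), function(i) {
      if (inherits(pools[[i]], "gene_pool")) pools[[i]]$label else LETTERS[i]
    }, "")
  universe <- unique(unlist(sets))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) memb <- matrix(memb, nrow = 1L)
  pat <- apply(memb, 1L, function(r) paste(nms[r], collapse = "&"))
  regions <- split(universe, pat)
  # include empty regions so every membership pattern is reported
  all_pat <- unlist(lapply(seq_along(sets), function(k) {
    utils::combn(nms, k, paste, collapse = "&", simplify = TRUE)
  }))
  missing <- setdiff(all_pat, names(regions))
  for (m in missing) regions[[m]] <- character(0)
  regions <- regions[all_pat]
  structure(list(regions = regions,
                 sizes = vapply(regions, length, 0L),
                 pool_names = nms),
            class = "venn_result")
}

#' @export
print.venn_result <- function(x, ...) {
  cat("venn_result over pools:", paste(x$pool_names, collapse = ", "), "\n")
  for (nm in names(x$regions))
    cat(sprintf("  only[%s]: %d\n", nm, x$sizes[[nm]]))
  cat(sprintf("  union: %d\n", sum(x$sizes)))
  invisible(x)
}

#' Pathway profile of a called network
#'
#' Overlaps the called targets of a network (by gene symbol) with each set
#' of a gene-set collection, counting up- and down-mode targets per set; a
#' set is flagged preferentially suppressed when down-mode targets
#' outnumber up-mode ones.  Sets are ranked by overlap fraction
#' (overlap / set size).
#'
#' @param net a [tf_network()].
#' @param gene_sets a `gene_set_collection`.
#' @return data.frame of class `pathway_profile`, one row per set:
#'   `set`, `set_size`, `overlap`, `down`, `up`, `fraction`, `suppressed`,
#'   ordered by decreasing fraction.
#' @export
pathway_profile <- function(net, gene_sets) {
  rec <- net$records[net$records$called, , drop = FALSE]
  syms <- rec$gene_symbol
  if (nrow(rec) > 0 && all(is.na(syms)))
    stop("no gene-symbol annotation on called targets")
  out <- do.call(rbind, lapply(names(gene_sets), function(nm) {
    members <- gene_sets[[nm]]
    hit <- !is.na(syms) & syms %in% members
    data.frame(set = nm, set_size = length(members),
               overlap = sum(hit),
               down = sum(hit & rec$mode == "down"),
               up = sum(hit & rec$mode == "up"),
               fraction = sum(hit) / length(members),
               stringsAsFactors = FALSE)
  }))
  out$suppressed <- out$down > out$up
  out <- out[order(-out$fraction, out$set), ]
  rownames(out) <- NULL
  class(out) <- c("pathway_profile", class(out))
  out
}
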