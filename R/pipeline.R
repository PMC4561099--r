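## Orchestration and visual outputs: median-centered clustered heatmaps and
## the end-to-end pipeline (simulate -> networks -> ANOVA pools -> typing ->
## signatures -> held-out evaluation).

#' Median-centered hierarchical clustering for heatmap display
#'
#' Each probe (row) is centered by subtracting its median across samples;
#' rows and columns are then clustered hierarchically (default distance
#' `1 - Pearson`, average linkage) and the leaf orders returned so a plot is
#' exactly reproducible.  Constant rows, whose correlation distance is
#' undefined, are dropped with a warning.
#'
#' @param values numeric matrix (probes x samples), >= 2 rows and columns.
#' @param distance `"pearson"` (1 - correlation) or `"euclidean"`.
#' @param linkage agglomeration method for `stats::hclust`
#'   (default `"average"`).
#' @return object of class `clustered_heatmap`: list with `values` (the
#'   centered matrix), `row_order`, `col_order` (leaf orders as indices into
#'   `values`), `row_hclust`, `col_hclust`.
#' @export
clustered_heatmap <- function(values, distance = c("pearson", "euclidean"),
                              linkage = "average") {
  distance <- match.arg(distance)
  values <- as.matrix(values)
  if (nrow(values) < 2 || ncol(values) < 2) stop("need >= 2 rows and columns")
  centered <- sweep(values, 1L, apply(values, 1L, stats::median, na.rm = TRUE))
  if (distance == "pearson") {
    const <- apply(centered, 1L, function(r) stats::sd(r, na.rm = TRUE) == 0)
    if (any(const)) {
      warning("dropping ", sum(const), " constant row(s): correlation distance undefined")
      centered <- centered[!const, , drop = FALSE]
      if (nrow(centered) < 2) stop("fewer than 2 usable rows")
    }
    dr <- stats::as.dist(1 - stats::cor(t(centered), use = "pairwise.complete.obs"))
    dc <- stats::as.dist(1 - stats::cor(centered, use = "pairwise.complete.obs"))
  } else {
    dr <- stats::dist(centered)
    dc <- stats::dist(t(centered))
  }
  hr <- stats::hclust(dr, method = linkage)
  hc <- stats::hclust(dc, method = linkage)
  structure(list(values = centered, row_order = hr$order, col_order = hc$order,
                 row_hclust = hr, col_hclust = hc),
            class = "clustered_heatmap")
}

#' @export
plot.clustered_heatmap <- function(x, col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                                   ...) {
  m <- x$values[x$row_order, x$col_order, drop = FALSE]
  graphics::image(t(m)[, rev(seq_len(nrow(m))), drop = FALSE], col = col,
                  axes = FALSE, ...)
  invisible(x)
}

#' @export
print.clustered_heatmap <- function(x, ...) {
  cat(sprintf("clustered_heatmap: %d x %d (median-centered)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Run the full supervised-network prognosis pipeline on a synthetic cohort
#'
#' End to end: simulate (or accept) a cohort, fit the driver TF's networks
#' in the ER(-) and combined cohorts and the antagonist TF's network in the
#' combined cohort, screen the histology ANOVA pools and intersect the
#' clinically significant cluster, run the genome-wide percentile log-rank
#' typing in all three cohorts, classify types 1-4 and feature types I-IV,
#' extract the consensus (feature-type-II) signature and the antagonistic
#' signature, and evaluate the consensus signature by K-M/log-rank and Cox
#' on an evaluation cohort.
#'
#' By default the evaluation cohort is a fresh draw from the same generative
#' truth (`heldout = TRUE`): selecting subcohorts with the same survival
#' data that evaluates them inflates significance, so held-out evaluation is
#' the honest default; `heldout = FALSE` evaluates in-sample.
#'
#' @param config a [sim_config()].
#' @param seed master seed for the run (the held-out cohort uses
#'   `seed + 10000`).
#' @param alpha significance level used throughout (default 0.05).
#' @param K,B CID parameters for the network scans.
#' @param fraction percentile-split fraction (default 0.10).
#' @param heldout evaluate on a fresh simulated cohort (default TRUE).
#' @param antagonist also fit the antagonist TF's network and extract the
#'   antagonistic signature (default TRUE; skipping saves a genome scan
#'   when only the consensus route is of interest).
#' @param data optional pre-generated `simulate_cohort()` output to analyse
#'   instead of drawing one.
#' @param outdir optional directory: tab-separated stage artifacts and the
#'   run configuration are written there.
#' @return object of class `pipeline_run`: list with the stage artifacts
#'   (`data`, `cohorts`, `net91`, `net181`, `netB181`, `pools`, `cluster`,
#'   `typing`, `ft91`, `ft181`, `consensus`, `antagonistic`, `evaluation`,
#'   `counts`, `config`, `seed`).
#' @export
run_pipeline <- function(config = sim_config(), seed = 1, alpha = 0.05,
                         K = 5, B = 4999, fraction = 0.10, heldout = TRUE,
                         antagonist = TRUE, data = NULL, outdir = NULL) {
  log_counts <- list()
  stage <- function(nm, expr_) {
    tryCatch(expr_, error = function(e)
      stop("pipeline stage '", nm, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dat <- stage("synthetic_cohort",
               if (is.null(data)) simulate_cohort(config, seed = seed) else data)
  cohorts <- stage("cohort_io", define_cohorts(dat$clinical))
  tfa <- dat$truth$tf_a; tfb <- dat$truth$tf_b
  log_counts$samples <- length(cohorts[["181A"]])

  net91 <- stage("network_91A",
                 tf_network(dat$expr, tfa, cohorts[["91A"]], "91A",
                            K = K, B = B, alpha = alpha, seed = seed))
  net181 <- stage("network_181A",
                  tf_network(dat$expr, tfa, cohorts[["181A"]], "181A",
                             K = K, B = B, alpha = alpha, seed = seed))
  netB181 <- if (antagonist)
    stage("network_B_181A",
          tf_network(dat$expr, tfb, cohorts[["181A"]], "181A",
                     K = K, B = B, alpha = alpha, seed = seed))
  else NULL
  log_counts$called_91 <- sum(net91$records$called)
  log_counts$called_181 <- sum(net181$records$called)

  pools <- stage("anova_pools", lapply(
    c("grade", "nuclear_pleomorphism", "mitotic_count"),
    function(p) anova_pool(dat$expr, dat$clinical, p,
                           cohort = cohorts[["181A"]], alpha = alpha)))
  cluster <- stage("clinical_cluster",
                   clinically_significant_cluster(tfa, pools))
  log_counts$cluster <- length(cluster$probes)

  scans <- stage("prognostic_typing", lapply(
    c("90A", "91A", "181A"),
    function(cn) {
      sc <- prognostic_scan(dat$expr, dat$clinical, cohorts[[cn]],
                            fraction = fraction)
      stats::setNames(sc$p, sc$probe)
    }))
  typing <- stage("classify_types",
                  classify_types(scans[[1]], scans[[2]], scans[[3]],
                                 alpha = alpha))
  ft91 <- stage("feature_types_91A", feature_types(typing, net91))
  ft181 <- stage("feature_types_181A", feature_types(typing, net181))
  log_counts$typed_181 <- sum(typing$type != "none")

  consensus <- stage("consensus_signature", consensus_signature(
    feature_type_pool(ft91, "II"), feature_type_pool(ft181, "II"),
    net91, net181, name = "consensus_type2"))
  antagonistic <- if (antagonist) {
    shared4 <- stage("shared_type4_pool", {
      p4 <- feature_type_pool(ft181, "IV")
      gene_pool(intersect(p4$probes, called_probes(netB181)),
                "shared_type4", "type-IV probes called in both TF networks")
    })
    if (length(shared4$probes))
      stage("antagonistic_signature", suppressWarnings(
        antagonistic_signature(netB181, net181, shared4,
                               name = "antagonistic_type4")))
    else signature(character(0), character(0), "antagonistic_type4",
                   direction = "good", provenance = "no shared type-IV probes")
  } else NULL
  log_counts$consensus <- nrow(consensus)
  log_counts$antagonistic <- if (is.null(antagonistic)) NA_integer_
  else nrow(antagonistic)

  evaluation <- stage("evaluation", {
    if (nrow(consensus[!consensus$is_tf, ]) == 0) {
      structure(list(status = "empty signature: nothing to evaluate",
                     logrank = NULL), class = "signature_evaluation")
    } else {
      if (heldout) {
        ev <- simulate_cohort(config, seed = seed + 10000L)
        ecoh <- define_cohorts(ev$clinical)
        sc <- signature_score(ev$expr, consensus, ecoh[["181A"]])
        grp <- discover_subcohorts(sc, fraction = fraction)
        evaluate_signature(ev$clinical, grp)
      } else {
        sc <- signature_score(dat$expr, consensus, cohorts[["181A"]])
        grp <- discover_subcohorts(sc, fraction = fraction)
        evaluate_signature(dat$clinical, grp)
      }
    }
  })

  run <- structure(list(data = dat, cohorts = cohorts, net91 = net91,
                        net181 = net181, netB181 = netB181, pools = pools,
                        cluster = cluster, typing = typing, ft91 = ft91,
                        ft181 = ft181, consensus = consensus,
                        antagonistic = antagonistic, evaluation = evaluation,
                        counts = log_counts, config = config, seed = seed,
                        params = list(alpha = alpha, K = K, B = B,
                                      fraction = fraction, heldout = heldout)),
                   class = "pipeline_run")
  if (!is.null(outdir)) write_pipeline_run(run, outdir)
  run
}

#' Write the tab-separated artifacts of a pipeline run
#'
#' Every figure-feeding table plus the run configuration (seed, parameters)
#' lands next to the outputs, so a run is reproducible from its directory.
#'
#' @param run a [run_pipeline()] result.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_pipeline_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, nm) utils::write.table(df, file.path(outdir, nm),
                                           sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  w(run$net91$records, "network_91A.tsv")
  w(run$net181$records, "network_181A.tsv")
  if (!is.null(run$netB181)) w(run$netB181$records, "network_B_181A.tsv")
  w(run$typing, "typing.tsv")
  w(run$ft91$assignment, "feature_types_91A.tsv")
  w(run$ft181$assignment, "feature_types_181A.tsv")
  w(run$ft91$pie, "pie_91A.tsv")
  w(run$ft181$pie, "pie_181A.tsv")
  w(as.data.frame(run$consensus), "signature_consensus.tsv")
  if (!is.null(run$antagonistic))
    w(as.data.frame(run$antagonistic), "signature_antagonistic.tsv")
  w(data.frame(probe = run$cluster$probes), "clinical_cluster.tsv")
  cfg <- c(list(seed = run$seed), run$params,
           run$config[setdiff(names(run$config), "blocks")],
           as.list(stats::setNames(run$config$blocks,
                                   paste0("block_", names(run$config$blocks)))))
  w(data.frame(key = names(cfg), value = vapply(cfg, function(v)
    paste(format(v), collapse = ","), "")), "run_config.tsv")
  invisible(outdir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run (seed", x$seed, ")\n")
  cat(sprintf("  samples: %d | network called 91A/181A: %d/%d | cluster: %d\n",
              x$counts$samples, x$counts$called_91, x$counts$called_181,
              x$counts$cluster))
  cat(sprintf("  typed probes (181A significant): %d | consensus: %d probes | antagonistic: %s probes\n",
              x$counts$typed_181, x$counts$consensus,
              ifelse(is.na(x$counts$antagonistic), "-", x$counts$antagonistic)))
  if (!is.null(x$evaluation$logrank))
    cat(sprintf("  held-out evaluation log-rank p = %.4g (%s)\n",
                x$evaluation$logrank$p, x$evaluation$logrank$direction))
  else cat("  evaluation:", x$evaluation$status, "\n")
  invisible(x)
}
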