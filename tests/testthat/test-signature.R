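mk_pool <- function(probes, lab = "p") gene_pool(probes, lab, "test pool")

mk_net <- function(targets, modes, tf = "tfX", cohort = paste0("S", 1:50),
                   cohort_name = "test") {
  structure(list(tf = tf, cohort = cohort, cohort_name = cohort_name,
                 records = data.frame(target = targets, called = TRUE,
                                      mode = modes, stringsAsFactors = FALSE)),
            class = "tf_network")
}

test_that("consensus signature is the symmetric pool intersection", {
  nA <- mk_net(c("1", "2", "3"), c("up", "up", "down"), cohort = paste0("S", 1:40))
  nB <- mk_net(c("2", "3", "4"), c("up", "down", "up"), cohort = paste0("S", 1:90))
  ab <- consensus_signature(mk_pool(c("1", "2", "3")), mk_pool(c("2", "3", "4")),
                            nA, nB)
  ba <- consensus_signature(mk_pool(c("2", "3", "4")), mk_pool(c("1", "2", "3")),
                            nA, nB)
  expect_setequal(ab$probe, c("2", "3"))
  expect_setequal(ab$probe, ba$probe)
  # modes from the larger cohort's network (nB)
  expect_identical(ab$mode[ab$probe == "3"], "down")
  empty <- consensus_signature(mk_pool("1"), mk_pool("9"), nA, nB)
  expect_equal(nrow(empty), 0)
  expect_identical(attr(empty, "status"), "empty")
})

test_that("the packaged 16-probe pool scores 15 probes once the TF is flagged", {
  sig <- as_signature(load_packaged_signature("type2_nr5a2"), tf_probe = "16670")
  expect_equal(nrow(sig), 16)
  expect_equal(sum(!sig$is_tf), 15)
  expect_identical(attr(sig, "direction"), "poor")
})

test_that("antagonistic signature keeps only mode-discordant shared targets", {
  nA <- mk_net(c("g1", "g2"), c("up", "down"))
  nB <- mk_net(c("g1", "g2"), c("down", "down"))
  s <- antagonistic_signature(nA, nB, mk_pool(c("g1", "g2")))
  expect_setequal(s$probe, "g1")
  same <- antagonistic_signature(nA, nA, mk_pool(c("g1", "g2")))
  expect_equal(nrow(same), 0)
  expect_warning(antagonistic_signature(nA, nB, mk_pool(c("g1", "zzz"))),
                 "dropped")
  tf_only <- antagonistic_signature(nA, nB, mk_pool(c("g1", "g2")),
                                    tf_only = TRUE, tf_annotation = "g2")
  expect_equal(nrow(tf_only), 0)
})

test_that("signature scoring is a mode-aligned mean z-score", {
  set.seed(2)
  vals <- matrix(rnorm(100), 5, 20,
                 dimnames = list(letters[1:5], paste0("S", 1:20)))
  em <- expr_matrix(vals)
  one <- signature(probes = "b", modes = "up", name = "one")
  sc <- signature_score(em, one)
  expect_equal(unname(sc), as.numeric(scale(vals["b", ])), tolerance = 1e-12)

  dn <- signature(letters[1:3], rep("down", 3), "dn")
  up <- signature(letters[1:3], rep("up", 3), "up")
  em_neg <- expr_matrix(-vals)
  expect_equal(signature_score(em_neg, dn), signature_score(em, up),
               tolerance = 1e-12)
  expect_warning(
    sc2 <- signature_score(em, signature(c("a", "q"), c("up", "up"), "x")),
    "absent")
  suppressWarnings(expect_error(signature_score(em, signature("q", "up", "x")),
                                "no signature probe"))
})

test_that("subcohort discovery honors both control rules", {
  set.seed(3)
  score <- stats::setNames(rnorm(181), paste0("S", 1:181))
  comp <- discover_subcohorts(score, control_rule = "complement")
  expect_equal(as.vector(table(comp)), c(163, 18))
  mat <- discover_subcohorts(score, control_rule = "matched_size")
  expect_equal(sum(mat == "subcohort", na.rm = TRUE), 18)
  expect_equal(sum(mat == "control", na.rm = TRUE), 18)
  expect_equal(sum(is.na(mat)), 181 - 36)
  small <- discover_subcohorts(stats::setNames(rnorm(20), paste0("T", 1:20)),
                               control_rule = "matched_size")
  expect_equal(as.vector(table(small)), c(2, 2))
})

test_that("signature evaluation reports HRs and survives degenerate groups", {
  dat <- simulate_cohort(sim_config(), seed = 4)
  grp <- discover_subcohorts(dat$truth$score)
  ev <- evaluate_signature(dat$clinical, grp)
  expect_identical(ev$status, "ok")
  expect_true(all(ev$cox_uni$hr > 0))
  expect_true(ev$cox_uni$lo95 <= ev$cox_uni$hr & ev$cox_uni$hr <= ev$cox_uni$hi95)
  expect_equal(nrow(ev$cox_multi), 4)   # group + grade + tumor_size + lnm
  expect_true(any(grepl("grade", ev$cox_multi$term)))

  # single-sample group: the non-convergence path must be a status, not a crash
  g2 <- factor(c("subcohort", rep("control", nrow(dat$clinical) - 1)),
               levels = c("control", "subcohort"))
  names(g2) <- dat$clinical$sample_id
  cl2 <- dat$clinical
  cl2$event[1] <- 0   # the lone subcohort sample never has an event
  cl2$surv_time[1] <- max(cl2$surv_time) + 1
  ev2 <- evaluate_signature(cl2, g2, covariates = character(0))
  expect_true(is.list(ev2))
  expect_true(ev2$status == "ok" ||
                grepl("converge", ev2$status))
})

test_that("null groupings give calibrated univariate Cox coverage", {
  set.seed(5)
  cover <- replicate(60, {
    n <- 120
    cl <- clinical_table(data.frame(
      sample_id = paste0("S", 1:n), er_status = "-",
      surv_time = rexp(n, 0.05), event = rbinom(n, 1, 0.6)))
    grp <- factor(sample(rep(c("control", "subcohort"), c(n - 20, 20))),
                  levels = c("control", "subcohort"))
    names(grp) <- cl$sample_id
    ev <- evaluate_signature(cl, grp, covariates = character(0))
    if (!is.data.frame(ev$cox_uni)) return(NA)
    ev$cox_uni$lo95[1] <= 1 && 1 <= ev$cox_uni$hi95[1]
  })
  expect_gte(mean(cover, na.rm = TRUE), 0.9)
})

test_that("planted cohorts yield a consensus signature dominated by true probes", {
  hits <- vapply(1:5, function(sd) {
    run <- run_pipeline(seed = sd, B = 1999, antagonist = FALSE)
    cons <- run$consensus$probe[!run$consensus$is_tf]
    length(cons) > 0 &&
      mean(cons %in% run$data$truth$signature$probe) >= 0.6
  }, TRUE)
  expect_gte(sum(hits), 3)
})
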