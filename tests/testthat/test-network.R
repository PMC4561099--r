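# small planted cohort shared by the network tests
small_sim <- function(seed = 1, ...)
  simulate_cohort(sim_config(n_probes = 300L, ...), seed = seed)

test_that("the union call is a superset of each single-statistic call", {
  dat <- small_sim()
  cs <- define_cohorts(dat$clinical)
  net <- tf_network(dat$expr, dat$truth$tf_a, cs[["181A"]], "181A",
                    B = 999, seed = 1)
  rec <- net$records
  cid_only <- !is.na(rec$q_cid) & rec$q_cid <= net$params$alpha
  gpcc_only <- !is.na(rec$q_gpcc) & rec$q_gpcc <= net$params$alpha
  expect_true(all(rec$called[cid_only]))
  expect_true(all(rec$called[gpcc_only]))
  expect_setequal(which(rec$called), which(cid_only | gpcc_only))
  # every called record carries a mode
  expect_false(anyNA(rec$mode[rec$called]))
  expect_true(all(is.na(rec$mode[!rec$called])))
})

test_that("modes track the planted regulation signs", {
  dat <- small_sim()
  cs <- define_cohorts(dat$clinical)
  netA <- tf_network(dat$expr, dat$truth$tf_a, cs[["181A"]], "181A",
                     B = 999, seed = 1)
  netB <- tf_network(dat$expr, dat$truth$tf_b, cs[["181A"]], "181A",
                     B = 999, seed = 1)
  lin <- dat$truth$edges$target[dat$truth$edges$tf == dat$truth$tf_a &
                                  dat$truth$edges$form == "linear"]
  mA <- netA$records$mode[match(lin, netA$records$target)]
  expect_true(all(mA[!is.na(mA)] == "up"))
  shared <- dat$truth$edges$target[dat$truth$edges$tf == dat$truth$tf_b]
  mB <- netB$records$mode[match(shared, netB$records$target)]
  expect_true(all(mB[!is.na(mB)] == "down"))
})

test_that("lowering alpha never grows the called set", {
  dat <- small_sim()
  cs <- define_cohorts(dat$clinical)
  loose <- tf_network(dat$expr, dat$truth$tf_a, cs[["181A"]], "181A",
                      B = 999, alpha = 0.05, seed = 1)
  strict <- tf_network(dat$expr, dat$truth$tf_a, cs[["181A"]], "181A",
                       B = 999, alpha = 0.01, seed = 1)
  expect_true(all(called_probes(strict) %in% called_probes(loose)))
})

test_that("network fits are deterministic and order-independent given the master seed", {
  dat <- small_sim()
  cs <- define_cohorts(dat$clinical)
  a <- tf_network(dat$expr, dat$truth$tf_a, cs[["91A"]], "91A", B = 499, seed = 9)
  b <- tf_network(dat$expr, dat$truth$tf_a, cs[["91A"]], "91A", B = 499, seed = 9)
  expect_identical(a$records, b$records)
  # per-probe permutation route: shuffling probe order must not change results
  shuf <- sample(rownames(dat$expr))
  ex2 <- dat$expr[shuf, ]
  c2 <- tf_network(ex2, dat$truth$tf_a, cs[["91A"]], "91A", B = 499, seed = 9,
                   null = "per_probe")
  d2 <- tf_network(dat$expr, dat$truth$tf_a, cs[["91A"]], "91A", B = 499,
                   seed = 9, null = "per_probe")
  m <- match(d2$records$target, c2$records$target)
  expect_equal(d2$records$p_cid, c2$records$p_cid[m])
})

test_that("null matrices produce alpha-consistent call counts", {
  calls <- vapply(1:5, function(sd) {
    m <- simulate_null_matrix(200, 80, seed = sd)
    net <- tf_network(m, "1", B = 999, seed = sd, cohort_name = "null")
    sum(net$records$called)
  }, 0)
  # BH at q<=0.05 on null data: expected discoveries ~ 0
  expect_lte(mean(calls), 2)
})

test_that("scan GPCC p-values equal cor.test on sampled probes", {
  dat <- small_sim()
  cs <- define_cohorts(dat$clinical)
  net <- tf_network(dat$expr, dat$truth$tf_a, cs[["90A"]], "90A", B = 499, seed = 2)
  x <- unclass(dat$expr)[dat$truth$tf_a, cs[["90A"]]]
  for (pr in sample(net$records$target, 10)) {
    ref <- gpcc(unclass(dat$expr)[pr, cs[["90A"]]], x)
    row <- net$records[net$records$target == pr, ]
    expect_equal(row$gpcc, ref$r, tolerance = 1e-12)
    expect_equal(row$p_gpcc, ref$p_value, tolerance = 1e-12)
  }
})

test_that("anova pools catch the planted grade link and reject degenerate factors", {
  dat <- small_sim()
  cs <- define_cohorts(dat$clinical)
  pool <- anova_pool(dat$expr, dat$clinical, "grade", cs[["181A"]])
  expect_true(dat$truth$tf_a %in% pool$probes)
  expect_match(pool$provenance, "grade")
  cl <- dat$clinical
  cl$flat <- 1
  expect_error(anova_pool(dat$expr, cl, "flat", cs[["181A"]]), "2 usable levels")
  cl$lop <- c(2, rep(1, nrow(cl) - 1))
  expect_warning(
    expect_error(anova_pool(dat$expr, cl, "lop", cs[["181A"]]), "2 usable levels"),
    "dropping")
})

test_that("permuted factor labels give uniform anova p-values for one probe", {
  dat <- small_sim()
  y <- unclass(dat$expr)[5, ]
  set.seed(4)
  ps <- replicate(300, {
    fac <- factor(sample(dat$clinical$grade))
    stats::oneway.test(y ~ fac, var.equal = TRUE)$p.value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the clinically significant cluster is the intersection of TF-containing pools", {
  mk <- function(probes, lab) gene_pool(probes, lab, "test")
  pools <- list(mk(c("tf", "g1", "g2"), "A"), mk(c("tf", "g2", "g3"), "B"),
                mk("g1", "C"))
  cl <- clinically_significant_cluster("tf", pools)
  expect_setequal(cl$probes, "g2")
  expect_identical(attr(cl, "status"), "ok")
  expect_setequal(attr(cl, "parameters"), c("A", "B"))
  none <- clinically_significant_cluster("absent", pools)
  expect_length(none$probes, 0)
  expect_identical(attr(none, "status"), "tf not clinically relevant")
})

test_that("the planted cohort's histology cluster contains a grade-linked target", {
  hits <- vapply(1:5, function(sd) {
    dat <- small_sim(seed = sd)
    cs <- define_cohorts(dat$clinical)
    pools <- lapply(c("grade", "nuclear_pleomorphism", "mitotic_count"),
                    function(p) anova_pool(dat$expr, dat$clinical, p, cs[["181A"]]))
    cl <- clinically_significant_cluster(dat$truth$tf_a, pools)
    targetsA <- dat$truth$edges$target[dat$truth$edges$tf == dat$truth$tf_a]
    length(intersect(cl$probes, targetsA)) >= 1
  }, TRUE)
  expect_gte(sum(hits), 3)
})

test_that("venn regions are exact against brute-force enumeration", {
  v <- venn_pools(list(A = c("1", "2", "3"), B = c("2", "3", "4")))
  expect_equal(unname(v$sizes[c("A", "B", "A&B")]), c(1L, 1L, 2L))
  d <- venn_pools(list(A = c("a", "b"), B = c("c")))
  expect_equal(unname(d$sizes[["A&B"]]), 0L)

  set.seed(13)
  sets <- lapply(1:3, function(i) as.character(sample(1:30, 15)))
  names(sets) <- c("X", "Y", "Z")
  v3 <- venn_pools(sets)
  expect_equal(sum(v3$sizes), length(unique(unlist(sets))))
  for (pat in names(v3$regions)) {
    inn <- strsplit(pat, "&", fixed = TRUE)[[1]]
    out <- setdiff(names(sets), inn)
    brute <- Reduce(intersect, sets[inn])
    for (o in out) brute <- setdiff(brute, sets[[o]])
    expect_setequal(v3$regions[[pat]], brute)
  }
  expect_error(venn_pools(rep(sets, 2)), "2-4")
})

test_that("pathway profiles count modes and flag suppression", {
  dat <- small_sim()
  cs <- define_cohorts(dat$clinical)
  netB <- tf_network(dat$expr, dat$truth$tf_b, cs[["181A"]], "181A",
                     B = 999, seed = 1)
  shared <- dat$truth$edges$target[dat$truth$edges$tf == dat$truth$tf_b]
  down_syms <- gene_symbols(dat$expr)[shared]
  gs <- structure(list(planted = unname(down_syms),
                       noise = sprintf("G%04d", 250:280)),
                  source = "test", class = "gene_set_collection")
  prof <- pathway_profile(netB, gs)
  expect_equal(prof$set[1], "planted")
  expect_true(prof$suppressed[prof$set == "planted"])
  expect_gt(prof$fraction[prof$set == "planted"],
            prof$fraction[prof$set == "noise"])
  expect_equal(prof$down + prof$up, prof$overlap)
  # empty network: all overlaps zero
  m <- simulate_null_matrix(50, 40, seed = 2)
  net0 <- tf_network(m, "1", B = 499, seed = 1)
  prof0 <- pathway_profile(net0, gs)
  expect_true(all(prof0$overlap == 0))
})
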