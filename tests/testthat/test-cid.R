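test_that("cid handles the degenerate and perfectly separated extremes", {
  set.seed(1)
  v <- cid(rnorm(30), rep(2, 30), K = 3)
  expect_equal(as.numeric(v), 0)
  expect_true(attr(v, "degenerate"))

  # two x-groups occupying disjoint sorted blocks of y: maximal separation
  expect_equal(as.numeric(cid(1:8, rep(1:2, each = 4), K = 2)), 1)
  expect_equal(as.numeric(cid(c(5, 7, 6, 8, 1, 4, 2, 3),
                              rep(c(10, -1), each = 4), K = 2)), 1)
  expect_error(cid(1:5, 1:5, K = 3), "2\\*K")
})

test_that("cid equals the naive double-loop EDF oracle on random instances", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(20:100, 1)
    K <- sample(2:5, 1)
    y <- switch(sample(3, 1),
                rnorm(n),
                rpois(n, 3),          # heavy ties
                rt(n, df = 2))
    x <- switch(sample(3, 1),
                rnorm(n),
                y + rnorm(n),
                round(rnorm(n), 1))   # ties in x
    expect_equal(as.numeric(cid(y, x, K)), oracle_cid(y, x, K),
                 tolerance = 1e-12)
  }
})

test_that("cid is exactly invariant under strictly monotone transforms", {
  set.seed(7)
  y <- rnorm(60); x <- rnorm(60)
  base <- cid(y, x, K = 5)
  expect_identical(as.numeric(cid(exp(y), x, K = 5)), as.numeric(base))
  expect_identical(as.numeric(cid(y, x^3 + 2 * x, K = 5)), as.numeric(base))
  expect_identical(as.numeric(cid(rank(y) * 10 - 3, x, K = 5)), as.numeric(base))
})

test_that("cid stays in [0,1] over adversarial random inputs", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(12:80, 1)
    K <- sample(2:4, 1)
    y <- sample(c(rnorm(n), rpois(n, 1)), n)
    x <- sample(c(rnorm(n), rep(0, n)), n)
    if (length(unique(x)) == 1) next
    v <- as.numeric(cid(y, x, K))
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
})

test_that("sub_cid addends are non-negative and sum to the raw statistic", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(20:60, 1); K <- sample(2:5, 1)
    y <- rnorm(n); x <- rnorm(n)
    contrib <- sub_cid(y, x, K)
    expect_length(contrib, K)
    expect_true(all(contrib >= 0))
    expect_equal(sum(contrib), attr(contrib, "S"), tolerance = 1e-15)
    expect_equal(as.numeric(contrib), oracle_addends(y, oracle_bins(x, K)$g, K),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  dg <- sub_cid(rnorm(20), rep(1, 20), K = 2)
  expect_equal(as.numeric(dg), 0)
  # perfect separation: every group contributes positively, matching oracle
  y <- 1:8; x <- rep(1:2, each = 4)
  contrib <- sub_cid(y, x, K = 2)
  expect_true(all(contrib > 0))
  expect_equal(as.numeric(contrib), oracle_addends(y, oracle_bins(x, 2)$g, 2),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("permutation p-values behave at the extremes and under transforms", {
  # maximal separation at n = 40: no permutation can reach the observed
  # statistic (the probability of redrawing the exact split is ~2/C(40,20))
  pt <- cid_perm_test(1:40, rep(1:2, each = 20), K = 2, B = 99, seed = 4)
  expect_equal(pt$p_value, 1 / 100)

  set.seed(2)
  y <- rnorm(50); x <- y + rnorm(50)
  a <- cid_perm_test(y, x, K = 5, B = 99, seed = 10)
  b <- cid_perm_test(exp(y), x, K = 5, B = 99, seed = 10)
  expect_identical(a$cid, b$cid)
  expect_identical(a$p_value, b$p_value)
  expect_gte(a$p_value, 1 / 100)
  expect_lte(a$p_value, 1)
})

test_that("gpcc recovers exact linear relationships and their p-values", {
  x <- seq(-3, 3, length.out = 20)
  expect_equal(gpcc(2 * x + 1, x)$r, 1)
  expect_equal(gpcc(-x, x)$r, -1)
  dg <- gpcc(rep(1, 10), rnorm(10))
  expect_true(dg$degenerate)
  expect_equal(dg$r, 0)
})

test_that("a symmetric quadratic response is invisible to GPCC but not CID", {
  set.seed(3)
  x <- rnorm(200)
  y <- (x - mean(x))^2
  g <- gpcc(y, x)
  expect_lt(abs(g$r), 0.1)
  pt <- cid_perm_test(y, x, K = 5, B = 199, seed = 1)
  expect_lt(pt$p_value, 0.01)
  expect_gt(pt$cid, 0.3)
})

test_that("multivariate cid reduces to univariate on a duplicated axis", {
  set.seed(5)
  y <- rnorm(80); x <- rnorm(80)
  expect_equal(as.numeric(cid_multi(y, cbind(x, x), K = 5)),
               as.numeric(cid(y, x, K = 2)), tolerance = 1e-12)
})

test_that("multivariate cid sees joint structure neither axis shows alone", {
  set.seed(11)
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- x1 + x2 + rnorm(n, 0, 0.3)
  mv <- as.numeric(cid_multi(y, cbind(x1, x2), K = 5))
  uni <- max(as.numeric(cid(y, x1, K = 2)), as.numeric(cid(y, x2, K = 2)))
  expect_gt(mv, uni)
  expect_error(cid_multi(y, cbind(x1, x2, x1, x2, x1), K = 600),
               "joint cells|fewer bins|complete")
})

test_that("permutation p for the multivariate statistic is valid under independence", {
  set.seed(21)
  p <- replicate(60, {
    y <- rnorm(60)
    X <- cbind(rnorm(60), rnorm(60))
    cid_perm_test(y, X, K = 5, B = 39, seed = sample.int(1e6, 1))$p_value
  })
  # a valid permutation p: P(p <= 0.05) near or below nominal
  expect_lte(mean(p <= 0.05), 0.15)
  expect_gt(mean(p), 0.3)
})
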