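## Coefficient of intrinsic dependence (CID): an empirical-distribution-
## function statistic in [0,1] measuring how strongly the conditional
## distribution of a response y changes across rank-bins of a conditioning
## variable x.  It detects nonlinear and nonmonotone dependence that the
## Pearson correlation (GPCC) misses.
##
## Definition used here (a reconstruction; the normalisation guarantees the
## [0,1] contract):
##   groups    = K near-equal-size rank bins of x (remainder spread to the
##               lowest bins; ties in x broken by stable input order)
##   S         = sum_k (n_k/n) * (1/n) * sum_i [F_k(y_i) - F(y_i)]^2
##               with F the pooled EDF and F_k the EDF of group k, the inner
##               sum running over all n observations
##   S_max     = the S obtained by reassigning the sorted y values to the
##               groups as contiguous blocks of the same sizes (maximal
##               separation of the conditional distributions)
##   CID       = S / S_max   (0 when S_max = 0, i.e. degenerate y)

# pairwise-complete filter shared by the association statistics
# (x may be a matrix of conditioning variables)
.pairwise_complete <- function(y, x) {
  if (is.matrix(x)) {
    ok <- !is.na(y) & stats::complete.cases(x)
    return(list(y = y[ok], x = x[ok, , drop = FALSE], n = sum(ok)))
  }
  ok <- !is.na(y) & !is.na(x)
  list(y = y[ok], x = x[ok], n = sum(ok))
}

# precompute the sorted-order structure of y: stable order, tie-block last
# positions, and the pooled EDF evaluated at each sorted observation
.cid_structure <- function(y) {
  n <- length(y)
  ord <- order(y)                      # stable: ties keep input order
  ys <- y[ord]
  lob <- rank(ys, ties.method = "max") # last index of each tie block
  list(ord = ord, lob = lob, F = lob / n, n = n)
}

# per-group addends c_k = (n_k/n)(1/n) sum_i [F_k(y_i)-F(y_i)]^2, given the
# group label of each observation (original order); sum(c_k) = S
.cid_addends <- function(st, g, sizes) {
  gs <- g[st$ord]
  K <- length(sizes)
  contrib <- numeric(K)
  for (k in seq_len(K)) {
    Fk <- cumsum(gs == k)[st$lob] / sizes[k]
    contrib[k] <- (sizes[k] / st$n) * mean((Fk - st$F)^2)
  }
  contrib
}

# K near-equal rank bins of x; remainder spread to the lowest bins; stable
# tie-break so results are deterministic across platforms
.rank_bins <- function(x, K) {
  n <- length(x)
  sizes <- rep.int(n %/% K, K)
  r <- n %% K
  if (r > 0L) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  g <- integer(n)
  g[order(x)] <- rep.int(seq_len(K), sizes)
  list(g = g, sizes = sizes)
}

# maximal-separation labels: sorted y assigned to groups as contiguous blocks
.max_sep_labels <- function(st, sizes) {
  g <- integer(st$n)
  g[st$ord] <- rep.int(seq_along(sizes), sizes)
  g
}

.cid_from_groups <- function(st, g, sizes) {
  S <- sum(.cid_addends(st, g, sizes))
  Smax <- sum(.cid_addends(st, .max_sep_labels(st, sizes), sizes))
  if (Smax <= 0) return(structure(0, degenerate = TRUE))   # constant y
  val <- S / Smax
  if (val > 1 && val < 1 + 1e-9) val <- 1                  # tie round-off
  val
}

#' Coefficient of intrinsic dependence
#'
#' EDF-based nonlinear association between a response `y` and a conditioning
#' variable `x`, in `[0, 1]`.  `x` is cut into `K` near-equal rank bins; the
#' statistic compares each bin's empirical distribution of `y` with the
#' pooled one and normalises by the maximal-separation configuration, so 0
#' means identical conditional distributions and 1 means the bins occupy
#' disjoint sorted blocks of `y`.  Exactly invariant under strictly monotone
#' transforms of `y` and of `x`.
#'
#' @param y,x numeric vectors of equal length; incomplete pairs are dropped.
#' @param K number of conditioning rank bins (default 5).
#' @return CID value in `[0,1]`.  A constant `x` (or constant `y`) after
#'   filtering returns 0 with attribute `degenerate = TRUE`.
#' @seealso [sub_cid()] for the per-bin addends, [cid_perm_test()] for
#'   permutation significance, [cid_multi()] for several conditioning
#'   variables.
#' @export
cid <- function(y, x, K = 5) {
  if (K < 2) stop("K must be >= 2")
  pc <- .pairwise_complete(y, x)
  if (pc$n < 2 * K) stop("need at least 2*K complete pairs (have ", pc$n, ")")
  if (length(unique(pc$x)) == 1L) return(structure(0, degenerate = TRUE))
  st <- .cid_structure(pc$y)
  b <- .rank_bins(pc$x, K)
  .cid_from_groups(st, b$g, b$sizes)
}

#' Per-bin contributions of the CID sum
#'
#' The `K` unnormalised addends `c_k = (n_k/n)(1/n) sum_i [F_k(y_i)-F(y_i)]^2`
#' whose sum is the raw separation `S`; ranking them locates which
#' conditioning subgroup drives an association (sub-CID values).
#'
#' @inheritParams cid
#' @return numeric vector of length `K` (a single 0 for a degenerate
#'   constant `x`), with attribute `S` holding the total.
#' @export
sub_cid <- function(y, x, K = 5) {
  if (K < 2) stop("K must be >= 2")
  pc <- .pairwise_complete(y, x)
  if (pc$n < 2 * K) stop("need at least 2*K complete pairs (have ", pc$n, ")")
  if (length(unique(pc$x)) == 1L)
    return(structure(0, S = 0, degenerate = TRUE))
  st <- .cid_structure(pc$y)
  b <- .rank_bins(pc$x, K)
  contrib <- .cid_addends(st, b$g, b$sizes)
  structure(contrib, S = sum(contrib))
}

#' Permutation test for the CID
#'
#' Monte-Carlo significance: `x` is permuted `B` times and
#' `p = (1 + #\{b : CID_b >= CID_obs\}) / (B + 1)`, so `p` is bounded below
#' by `1/(B+1)`.  Because the statistic depends on `x` only through its rank
#' bins, permuting `x` is realised as permuting the bin labels.
#'
#' @inheritParams cid
#' @param B number of permutations (default 1000, minimum 19).
#' @param seed integer seed driving the permutation stream.
#' @return list with `cid`, `p_value`, `B`, `n_used`.
#' @export
cid_perm_test <- function(y, x, K = 5, B = 1000, seed = 1) {
  if (B < 19) stop("B must be >= 19")
  pc <- .pairwise_complete(y, x)
  if (pc$n < 2 * K) stop("need at least 2*K complete pairs (have ", pc$n, ")")
  if (is.matrix(x)) return(.cid_multi_perm(pc, K, B, seed))
  if (length(unique(pc$x)) == 1L)
    return(list(cid = structure(0, degenerate = TRUE), p_value = 1,
                B = B, n_used = pc$n))
  st <- .cid_structure(pc$y)
  b <- .rank_bins(pc$x, K)
  s_obs <- sum(.cid_addends(st, b$g, b$sizes))
  smax <- sum(.cid_addends(st, .max_sep_labels(st, b$sizes), b$sizes))
  obs <- if (smax <= 0) 0 else min(s_obs / smax, 1)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  ge <- 0L
  for (bb in seq_len(B)) {
    sp <- sum(.cid_addends(st, sample(b$g), b$sizes))
    if (sp >= s_obs) ge <- ge + 1L
  }
  list(cid = obs, p_value = (1 + ge) / (B + 1), B = B, n_used = pc$n)
}

#' Pearson correlation with t-reference significance (GPCC)
#'
#' The linear-association counterpart of [cid()]: the ordinary sample
#' Pearson correlation with its two-sided p-value from the t distribution
#' with `n - 2` degrees of freedom.
#'
#' @inheritParams cid
#' @return list with `r`, `p_value`, `n_used`, and `degenerate = TRUE`
#'   (with `r = 0`, `p_value = NA`) when either vector has zero variance.
#' @export
gpcc <- function(y, x) {
  pc <- .pairwise_complete(y, x)
  if (pc$n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(pc$x) == 0 || stats::sd(pc$y) == 0)
    return(list(r = 0, p_value = NA_real_, n_used = pc$n, degenerate = TRUE))
  ct <- stats::cor.test(pc$y, pc$x, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n_used = pc$n,
       degenerate = FALSE)
}

## ---- multivariate CID ------------------------------------------------------

# joint rank-bin grouping for a matrix of conditioning variables: per-axis
# bins (round(K^(1/d)), at least 2), crossed; empty cells dropped; cells
# smaller than min_cell merged into the smallest grid-adjacent cell
.joint_bins <- function(X, K, min_cell = 2L) {
  n <- nrow(X); d <- ncol(X)
  ka <- max(2L, as.integer(round(K^(1 / d))))
  if (ka^d > n / 4) stop("too many joint cells (", ka^d,
                         ") for n = ", n, "; use fewer bins")
  ax <- vapply(seq_len(d), function(j) .rank_bins(X[, j], ka)$g, integer(n))
  cell <- as.integer(factor(apply(ax, 1L, paste, collapse = ".")))
  coords <- unique(cbind(cell, ax))
  coords <- coords[order(coords[, 1L]), , drop = FALSE]
  repeat {
    sizes <- tabulate(cell)
    live <- which(sizes > 0L)
    if (length(live) < 2L)
      stop("degenerate joint grouping (fewer than 2 non-empty cells); use fewer bins")
    small <- live[sizes[live] < min_cell]
    if (!length(small)) break
    s <- small[which.min(sizes[small])]
    cs <- coords[coords[, 1L] == s, -1L, drop = FALSE][1L, ]
    cand <- live[live != s]
    dist <- vapply(cand, function(cc) {
      co <- coords[coords[, 1L] == cc, -1L, drop = FALSE][1L, ]
      sum(abs(co - cs))
    }, 0)
    adj <- cand[dist == min(dist)]
    tgt <- adj[which.min(sizes[adj])]
    cell[cell == s] <- tgt
  }
  g <- as.integer(factor(cell))
  list(g = g, sizes = tabulate(g))
}

#' Multivariate coefficient of intrinsic dependence
#'
#' The same EDF statistic as [cid()] with the conditioning groups formed by
#' crossing per-variable rank bins (`round(K^(1/d))` bins per axis, minimum
#' 2), dropping empty joint cells and merging cells below `min_cell` into
#' their nearest grid neighbours.  Measures the joint association between
#' several TFs and a shared target.
#'
#' @param y response vector.
#' @param X numeric matrix with two or more conditioning columns.
#' @inheritParams cid
#' @param min_cell minimum joint-cell size before merging (default 2).
#' @return CID value in `[0,1]`.
#' @export
cid_multi <- function(y, X, K = 5, min_cell = 2L) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("X must have at least 2 conditioning columns")
  ok <- !is.na(y) & stats::complete.cases(X)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  if (length(y) < 4 * ncol(X)) stop("too few complete rows")
  st <- .cid_structure(y)
  b <- .joint_bins(X, K, min_cell)
  .cid_from_groups(st, b$g, b$sizes)
}

# permutation test for the multivariate statistic: rows of X permuted
# jointly, i.e. joint-cell labels permuted
.cid_multi_perm <- function(pc, K, B, seed) {
  X <- pc$x
  st <- .cid_structure(pc$y)
  b <- .joint_bins(X, K)
  s_obs <- sum(.cid_addends(st, b$g, b$sizes))
  smax <- sum(.cid_addends(st, .max_sep_labels(st, b$sizes), b$sizes))
  obs <- if (smax <= 0) 0 else min(s_obs / smax, 1)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  ge <- 0L
  for (bb in seq_len(B)) {
    sp <- sum(.cid_addends(st, sample(b$g), b$sizes))
    if (sp >= s_obs) ge <- ge + 1L
  }
  list(cid = obs, p_value = (1 + ge) / (B + 1), B = B, n_used = pc$n)
}

## ---- RNG bookkeeping -------------------------------------------------------

# statistics that take an explicit seed must not disturb the caller's stream
.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
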