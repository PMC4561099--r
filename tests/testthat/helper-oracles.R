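# Independent brute-force oracles, kept deliberately naive (double loops,
# O(K*n^2)) and separate from the package's optimized paths.

# near-equal rank-bin grouping (shared convention: remainder to lowest bins,
# stable ties)
oracle_bins <- function(x, K) {
  n <- length(x)
  sizes <- rep(n %/% K, K)
  r <- n %% K
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1
  g <- integer(n)
  g[order(x)] <- rep(seq_len(K), sizes)
  list(g = g, sizes = sizes)
}

# raw EDF separation S for a given grouping, by double loop
oracle_S <- function(y, g, K) {
  n <- length(y)
  Fpool <- vapply(y, function(v) mean(y <= v), 0)
  S <- 0
  for (k in seq_len(K)) {
    member <- y[g == k]
    Fk <- vapply(y, function(v) mean(member <= v), 0)
    S <- S + (length(member) / n) * mean((Fk - Fpool)^2)
  }
  S
}

# per-group addends (unnormalized), same double loop
oracle_addends <- function(y, g, K) {
  n <- length(y)
  Fpool <- vapply(y, function(v) mean(y <= v), 0)
  vapply(seq_len(K), function(k) {
    member <- y[g == k]
    Fk <- vapply(y, function(v) mean(member <= v), 0)
    (length(member) / n) * mean((Fk - Fpool)^2)
  }, 0)
}

# full naive CID: S / S_max with S_max from contiguous sorted-block labels
oracle_cid <- function(y, x, K) {
  b <- oracle_bins(x, K)
  S <- oracle_S(y, b$g, K)
  gmax <- integer(length(y))
  gmax[order(y)] <- rep(seq_len(K), b$sizes)
  Smax <- oracle_S(y, gmax, K)
  if (Smax <= 0) return(0)
  S / Smax
}

# hand-computed two-group log-rank fixture: group A (high) 1,3,5+,7,9,11+;
# group B (low) 2,4,6,8+,10,12.  Observed events in A = 4; expected and
# variance accumulated over the distinct event times by hand.
logrank_fixture <- function() {
  list(
    time = c(1, 3, 5, 7, 9, 11, 2, 4, 6, 8, 10, 12),
    event = c(1, 1, 0, 1, 1, 0, 1, 1, 1, 0, 1, 1),
    group = factor(rep(c("high", "low"), each = 6), levels = c("low", "high")),
    observed = 4,
    expected = 2 + 5 / 11 + 4 / 9 + 3 / 7 + 1 / 3,
    variance = 1 + 30 / 121 + 20 / 81 + 12 / 49 + 2 / 9,
    # product-limit values for group B at its event times 2,4,6,10,12
    km_low = data.frame(time = c(2, 4, 6, 10, 12),
                        surv = c(5 / 6, 4 / 6, 1 / 2, 1 / 4, 0))
  )
}
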