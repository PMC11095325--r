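# Independent brute-force oracles used across the test files.  These are
# deliberately written as plain enumerations, separate from the package's
# own (vectorized, closed-form) implementations.

# Mixed-keying outcome of a two-item comparison by explicit enumeration
# of the four keyed pairings: each keyed form earns +1/-1/0 per
# comparison, and a reversed form's points count against its item.
oracle_mixed_sum <- function(x, y, L) {
  xm <- L + 1 - x
  ym <- L + 1 - y
  pts <- function(a, b) if (a > b) 1L else if (a < b) -1L else 0L
  p1 <- pts(x, y) + pts(x, ym) - (pts(xm, ym) + pts(xm, y))
  p2 <- pts(y, x) + pts(y, xm) - (pts(ym, xm) + pts(ym, x))
  c(p1, p2)
}

# Squared canonical correlations by direct eigen-decomposition of
# solve(Sxx) Sxy solve(Syy) Syx.
oracle_cca_rho2 <- function(X, Y) {
  Sxx <- stats::cov(X)
  Syy <- stats::cov(Y)
  Sxy <- stats::cov(X, Y)
  M <- solve(Sxx) %*% Sxy %*% solve(Syy) %*% t(Sxy)
  sort(Re(eigen(M, only.values = TRUE)$values), decreasing = TRUE)
}

# Small deterministic inventory for design/response tests: K scales,
# ipp items per scale, ratings cycling over 1..L.
toy_dataset <- function(n = 20, K = 3, ipp = 4, L = 5, seed = 1) {
  set.seed(seed)
  ratings <- matrix(sample.int(L, n * K * ipp, replace = TRUE), n, K * ipp)
  likert_dataset(ratings, item_scale = rep(seq_len(K), each = ipp),
                 levels = c(1L, L))
}

# The 15 unordered preference pairs (x >= y) on a 5-level scale with
# their published mixed outcome sums, ties first.
published_outcome_table <- data.frame(
  x = c(1L, 2L, 3L, 4L, 5L, 2L, 3L, 4L, 5L, 3L, 4L, 5L, 4L, 5L, 5L),
  y = c(1L, 2L, 3L, 4L, 5L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 4L),
  sum1 = c(-2L, -2L, 0L, 2L, 2L, 0L, 0L, 0L, 2L, 0L, 2L, 4L, 4L, 4L, 4L),
  sum2 = c(-2L, -2L, 0L, 2L, 2L, -4L, -4L, -4L, -2L, -4L, -2L, 0L, 0L, 0L, 0L))
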