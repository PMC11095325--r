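test_that("recovery correlations of a score set with itself are the identity diagonal", {
  sc <- likert_scale_scores(toy_dataset(n = 60, K = 4, ipp = 3, seed = 1))
  cross <- recovery_correlations(sc, sc)
  expect_equal(unname(diag(cross)), rep(1, 4))
  expect_equal(cross, t(cross))
})

test_that("recovery against independent noise is near zero", {
  set.seed(2)
  a <- matrix(rnorm(5000 * 3), ncol = 3)
  b <- matrix(rnorm(5000 * 3), ncol = 3)
  cross <- recovery_correlations(a, b)
  expect_lt(max(abs(cross)), .05)
})

test_that("constant columns are reported as NA with a warning", {
  a <- matrix(rnorm(30), 10, 3)
  b <- a
  b[, 2] <- 1
  expect_warning(cross <- recovery_correlations(a, b), "constant")
  expect_true(all(is.na(cross[2, ])))
  expect_false(anyNA(cross[c(1, 3), ]))
})

test_that("intercorrelations are symmetric with unit diagonal", {
  sc <- likert_scale_scores(toy_dataset(n = 60, K = 4, ipp = 3, seed = 3))
  ic <- intercorrelations(sc)
  expect_equal(unname(diag(ic)), rep(1, 4))
  expect_equal(ic, t(ic))
  dup <- cbind(sc[, 1], sc[, 1])
  expect_equal(intercorrelations(dup)[1, 2], 1)
})

test_that("positive-only scoring induces negative inter-scale correlations", {
  for (s in 1:3) {
    cfg <- likert_config(n_respondents = 400, n_scales = 5,
                         items_per_scale = 8, r_within = .2,
                         r_between = 0, seed = 30 + s)
    d <- simulate_likert(cfg)
    des <- balanced_design(d, 20, keying = "positive_only", seed = 40 + s)
    sc <- classical_score(respond(d, des, seed = 50 + s))
    ic <- intercorrelations(sc)
    expect_true(all(ic[row(ic) != col(ic)] < 0))
  }
})

test_that("Pillai trace equals K for a perfect relation and ~0 for noise", {
  set.seed(4)
  X <- matrix(rnorm(2000 * 5), ncol = 5)
  res <- canonical_pillai(X, X)
  expect_equal(res$pillai, 5, tolerance = 1e-8)
  Y <- matrix(rnorm(2000 * 5), ncol = 5)
  # chance level for independent sets is about p*q/n = .0125
  expect_lt(canonical_pillai(X, Y)$pillai, .06)
})

test_that("canonical correlations match the brute-force eigen oracle", {
  set.seed(5)
  X <- matrix(rnorm(300 * 3), ncol = 3)
  Y <- X %*% matrix(c(1, .5, 0, 0, 1, .2, .3, 0, 1), 3, 3) +
    matrix(rnorm(300 * 3), ncol = 3)
  res <- canonical_pillai(X, Y)
  rho2 <- oracle_cca_rho2(X, Y)
  expect_equal(res$cancor^2, rho2, tolerance = 1e-8)
  expect_equal(res$pillai, sum(rho2), tolerance = 1e-8)
})

test_that("Pillai trace is invariant under nonsingular recombination", {
  set.seed(6)
  X <- matrix(rnorm(400 * 5), ncol = 5)
  Y <- X + matrix(rnorm(400 * 5), ncol = 5)
  base <- canonical_pillai(X, Y)$pillai
  for (i in 1:3) {
    M <- matrix(rnorm(25), 5, 5)
    while (abs(det(M)) < 1e-3) M <- matrix(rnorm(25), 5, 5)
    expect_equal(canonical_pillai(X, Y %*% M)$pillai, base,
                 tolerance = 1e-8)
  }
})

test_that("rank-deficient score sets raise a singularity error", {
  set.seed(7)
  X <- matrix(rnorm(100 * 3), ncol = 3)
  Xdef <- cbind(X, X[, 1] + X[, 2])
  expect_error(canonical_pillai(Xdef, X), "singularity")
  expect_error(canonical_pillai(X[1:5, ], X[1:5, ]), "more respondents")
})

test_that("selection ratios reflect item dominance and symmetry", {
  # an item always rated top against items rated bottom wins everything
  ratings <- cbind(rep(5L, 50), rep(1L, 50), rep(1L, 50))
  d <- likert_dataset(ratings, item_scale = 1:3, levels = c(1L, 5L))
  des <- balanced_design(d, 1, keying = "positive_only", seed = 1)
  sr <- selection_ratios(respond(d, des, seed = 2))
  top <- sr$items[sr$items$item_id == d$items$item_id[1], ]
  expect_equal(top$ratio, 1)
  # all-equal ratings: ties everywhere, mean ratio .50
  d2 <- likert_dataset(matrix(3L, 200, 6), item_scale = rep(1:3, 2),
                       levels = c(1L, 5L))
  des2 <- balanced_design(d2, 10, keying = "positive_only", seed = 3)
  sr2 <- selection_ratios(respond(d2, des2, seed = 4))
  expect_equal(unname(sr2$summary["mean"]), .5, tolerance = .02)
  # neutral synthetic data with factual +/-1 keys stays near .50
  cfg <- likert_config(n_respondents = 300, n_scales = 4,
                       items_per_scale = 6, r_within = .2, seed = 5)
  d3 <- simulate_likert(cfg)
  d3$items$key <- rep(c(1L, -1L), 12)
  des3 <- suppressWarnings(
    balanced_design(d3, 40, keying = "factual", seed = 6))
  sr3 <- selection_ratios(respond(d3, des3, seed = 7))
  expect_equal(unname(sr3$summary["mean"]), .5, tolerance = .05)
})

test_that("replication harness is deterministic and aggregates correctly", {
  cfg <- likert_config(n_respondents = 150, n_scales = 4,
                       items_per_scale = 6, r_within = .2)
  r1 <- run_replications(cfg, n_sets = 8, keying = "mixed_random",
                         n_reps = 2, seed = 9)
  r2 <- run_replications(cfg, n_sets = 8, keying = "mixed_random",
                         n_reps = 2, seed = 9)
  expect_identical(r1$replications, r2$replications)
  expect_equal(nrow(r1$replications), 2)
  expect_equal(
    r1$aggregate$mean[r1$aggregate$metric == "same"],
    mean(r1$replications$same))
})

test_that("mixed keying recovers at least as well as positive-only", {
  for (rw in c(.10, .30)) {
    cfg <- likert_config(n_respondents = 400, n_scales = 5,
                         items_per_scale = 12, r_within = rw,
                         r_between = 0)
    mix <- run_replications(cfg, 40, keying = "mixed_random",
                            n_reps = 2, seed = 60)
    pos <- run_replications(cfg, 40, keying = "positive_only",
                            n_reps = 2, seed = 61)
    expect_gt(mean(mix$replications$same), mean(pos$replications$same))
  }
})

test_that("recovery improves with the number of item sets", {
  cfg <- likert_config(n_respondents = 400, n_scales = 5,
                       items_per_scale = 12, r_within = .1)
  means <- sapply(c(10, 80), function(ns) {
    mean(run_replications(cfg, ns, keying = "mixed_random",
                          n_reps = 2, seed = 70)$replications$same)
  })
  expect_gt(means[2], means[1])
})

test_that("learning curves rank single-stimulus above forced choice at small m", {
  cfg <- likert_config(n_respondents = 400, n_scales = 3,
                       items_per_scale = 10, r_within = .2, seed = 80)
  d <- simulate_likert(cfg)
  lc <- learning_curve(d, item_counts = c(2, 8), n_draws = 8, seed = 81)
  expect_equal(nrow(lc), 6)
  at2 <- lc[lc$m == 2, ]
  expect_gt(at2$mean_correlation[at2$method == "single"],
            at2$mean_correlation[at2$method == "mfc_positive"])
  expect_gt(at2$mean_correlation[at2$method == "single"],
            at2$mean_correlation[at2$method == "mfc_mixed"])
  # monotone non-decreasing in m within pooled SD
  for (meth in unique(lc$method)) {
    sub <- lc[lc$method == meth, ]
    pooled <- sqrt(mean(sub$sd^2))
    expect_gt(sub$mean_correlation[2] - sub$mean_correlation[1], -pooled)
  }
})

test_that("a full-pool single subset reproduces the inventory exactly", {
  cfg <- likert_config(n_respondents = 200, n_scales = 3,
                       items_per_scale = 6, r_within = .2, seed = 90)
  d <- simulate_likert(cfg)
  lc <- learning_curve(d, item_counts = 6, n_draws = 2, replace = FALSE,
                       seed = 91)
  expect_equal(lc$mean_correlation[lc$method == "single"], 1)
})

test_that("split-half mode errors when m exceeds the half pool", {
  cfg <- likert_config(n_respondents = 100, n_scales = 3,
                       items_per_scale = 6, seed = 92)
  d <- simulate_likert(cfg)
  expect_error(learning_curve(d, item_counts = 4, mode = "split_half",
                              n_draws = 2, replace = FALSE, seed = 93),
               "exceeds")
  lc <- learning_curve(d, item_counts = 3, mode = "split_half",
                       n_draws = 3, seed = 94)
  expect_true(all(is.finite(lc$mean_correlation)))
})
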