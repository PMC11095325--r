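#' Configuration for the synthetic Likert inventory generator
#'
#' Bundles the parameters of the latent factor model that generates
#' Likert-type rating data: each scale has a common factor, factors across
#' scales are equicorrelated at `r_between`, and each item loads on its
#' scale factor such that two items of the same scale correlate `r_within`
#' on the latent (pre-discretization) metric.
#'
#' @param n_respondents Number of respondents (rows) to simulate.
#' @param n_scales Number of trait scales `K`.
#' @param items_per_scale Number of items per scale.
#' @param levels Number of Likert response levels `L` (default 5); ratings
#'   are coded `1..L`.
#' @param r_within Latent correlation between two items of the same scale,
#'   in `[0, 1)`.
#' @param r_between Correlation between any two scale factors, in
#'   `(-1, 1)`.  The implied latent correlation between items of different
#'   scales is `r_within * r_between`.
#' @param item_mean_offsets Optional numeric vector (length 1 or
#'   `n_scales * items_per_scale`) shifting each item's discretization
#'   thresholds on the latent z-metric; positive offsets lower the item
#'   mean (the item becomes "harder" to endorse).  Default all zero,
#'   giving equiprobable response categories.
#' @param seed Optional RNG seed making [simulate_likert()] deterministic.
#'
#' @return An object of class `likert_config`.
#' @seealso [simulate_likert()], [build_latent_structure()]
#' @export
likert_config <- function(n_respondents = 1000, n_scales = 5,
                          items_per_scale = 24, levels = 5,
                          r_within = 0.10, r_between = 0,
                          item_mean_offsets = NULL, seed = NULL) {
  n_respondents <- assert_count(n_respondents, "n_respondents")
  n_scales <- assert_count(n_scales, "n_scales")
  items_per_scale <- assert_count(items_per_scale, "items_per_scale")
  levels <- assert_count(levels, "levels", min = 2L)
  if (!is.numeric(r_within) || r_within < 0 || r_within >= 1)
    stop("`r_within` must be in [0, 1)", call. = FALSE)
  if (!is.numeric(r_between) || r_between <= -1 || r_between >= 1)
    stop("`r_between` must be in (-1, 1)", call. = FALSE)
  n_items <- n_scales * items_per_scale
  if (is.null(item_mean_offsets)) item_mean_offsets <- rep(0, n_items)
  if (length(item_mean_offsets) == 1L)
    item_mean_offsets <- rep(item_mean_offsets, n_items)
  if (length(item_mean_offsets) != n_items || !all(is.finite(item_mean_offsets)))
    stop("`item_mean_offsets` must be finite, length 1 or n_scales * items_per_scale",
         call. = FALSE)
  structure(
    list(n_respondents = n_respondents, n_scales = n_scales,
         items_per_scale = items_per_scale, levels = levels,
         r_within = r_within, r_between = r_between,
         item_mean_offsets = item_mean_offsets, seed = seed),
    class = "likert_config")
}

#' @export
print.likert_config <- function(x, ...) {
  cat(sprintf(
    "Likert simulation config: %d respondents, %d scales x %d items, %d levels\n",
    x$n_respondents, x$n_scales, x$items_per_scale, x$levels))
  cat(sprintf("  r_within = %.2f, r_between = %.2f\n", x$r_within, x$r_between))
  invisible(x)
}

#' Item-level latent correlation matrix implied by a Likert config
#'
#' Builds the correlation matrix of the latent item variables: unit
#' diagonal, `r_within` between items of the same scale and
#' `r_within * r_between` between items of different scales.  The matrix
#' is checked for positive semi-definiteness before it is used for
#' sampling.
#'
#' @param config A [likert_config()].
#' @return A `(K * items_per_scale)` square correlation matrix.
#' @export
build_latent_structure <- function(config) {
  stopifnot(inherits(config, "likert_config"))
  p <- config$n_scales * config$items_per_scale
  scale_of <- rep(seq_len(config$n_scales), each = config$items_per_scale)
  R <- matrix(config$r_within * config$r_between, p, p)
  same <- outer(scale_of, scale_of, "==")
  R[same] <- config$r_within
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(sprintf(
      "latent correlation matrix is not positive semi-definite (min eigenvalue %.3g) for r_within = %.2f, r_between = %.2f, K = %d",
      min(ev), config$r_within, config$r_between, config$n_scales),
      call. = FALSE)
  R
}

#' Simulate a synthetic Likert-type inventory
#'
#' Samples multivariate-normal latent item values with the correlation
#' structure of [build_latent_structure()] and discretizes each item at
#' `levels - 1` thresholds.  Default thresholds are the equiprobable
#' normal quantiles, shifted per item by `item_mean_offsets`, so that
#' without offsets every response category is equally likely in the
#' population (a "neutral" inventory whose item means sit at the scale
#' midpoint).
#'
#' @param config A [likert_config()].
#' @return A [likert_dataset()] with `n_respondents` rows and
#'   `n_scales * items_per_scale` columns; all items positively keyed.
#' @export
simulate_likert <- function(config) {
  stopifnot(inherits(config, "likert_config"))
  R <- build_latent_structure(config)
  p <- ncol(R)
  n <- config$n_respondents
  L <- config$levels
  Z <- with_seed(config$seed, matrix(stats::rnorm(n * p), n, p)) %*% chol(R)
  thresholds <- stats::qnorm(seq_len(L - 1) / L)
  ratings <- matrix(0L, n, p)
  for (j in seq_len(p)) {
    ratings[, j] <- findInterval(Z[, j], thresholds + config$item_mean_offsets[j]) + 1L
  }
  item_id <- sprintf("s%02d_i%02d",
                     rep(seq_len(config$n_scales), each = config$items_per_scale),
                     rep(seq_len(config$items_per_scale), config$n_scales))
  colnames(ratings) <- item_id
  likert_dataset(
    ratings,
    item_scale = rep(seq_len(config$n_scales), each = config$items_per_scale),
    item_key = rep(1L, p),
    levels = c(1L, L))
}

#' Construct a Likert-type rating dataset
#'
#' The common container for both simulated and imported single-stimulus
#' inventory data: an integer rating matrix plus per-item metadata (scale
#' membership and key direction).
#'
#' @param ratings Integer matrix, respondents in rows, items in columns.
#' @param item_scale Vector mapping each item (column) to a scale; any
#'   type coercible to a factor.
#' @param item_key Vector of `+1`/`-1` item key directions (default all
#'   `+1`).
#' @param levels Length-2 integer vector `c(min_level, max_level)`;
#'   inferred from the data if missing.
#' @return An object of class `likert_dataset` with elements `ratings`,
#'   `items` (data frame: `item_id`, `scale`, `key`) and `levels`.
#' @export
likert_dataset <- function(ratings, item_scale, item_key = NULL, levels = NULL) {
  ratings <- as.matrix(ratings)
  if (!is.numeric(ratings) || any(!is.finite(ratings)) ||
      any(ratings != round(ratings)))
    stop("`ratings` must be a finite integer matrix", call. = FALSE)
  storage.mode(ratings) <- "integer"
  p <- ncol(ratings)
  if (length(item_scale) != p)
    stop("`item_scale` must have one entry per rating column", call. = FALSE)
  if (is.null(item_key)) item_key <- rep(1L, p)
  if (length(item_key) != p || !all(item_key %in% c(-1L, 1L)))
    stop("`item_key` must be +1/-1, one entry per item", call. = FALSE)
  if (is.null(levels)) levels <- range(ratings)
  levels <- as.integer(levels)
  if (length(levels) != 2L || levels[2] <= levels[1])
    stop("`levels` must be c(min_level, max_level) with max > min", call. = FALSE)
  if (any(ratings < levels[1] | ratings > levels[2]))
    stop("ratings outside the declared level range", call. = FALSE)
  if (is.null(colnames(ratings)))
    colnames(ratings) <- sprintf("item%03d", seq_len(p))
  items <- data.frame(item_id = colnames(ratings),
                      scale = factor(item_scale),
                      key = as.integer(item_key),
                      stringsAsFactors = FALSE)
  structure(list(ratings = ratings, items = items, levels = levels),
            class = "likert_dataset")
}

#' @export
print.likert_dataset <- function(x, ...) {
  cat(sprintf(
    "Likert dataset: %d respondents x %d items, %d scales, levels %d..%d\n",
    nrow(x$ratings), ncol(x$ratings), nlevels(x$items$scale),
    x$levels[1], x$levels[2]))
  neg <- sum(x$items$key == -1L)
  if (neg > 0) cat(sprintf("  %d negatively keyed items\n", neg))
  invisible(x)
}

#' Number of scales in a Likert dataset
#' @param data A [likert_dataset()].
#' @return Integer scale count.
#' @export
n_scales <- function(data) {
  stopifnot(inherits(data, "likert_dataset"))
  nlevels(data$items$scale)
}

#' Empirical correlation structure of a Likert dataset
#'
#' Estimates the two quantities the generator controls: the mean Pearson
#' correlation over all same-scale item pairs, and the correlation matrix
#' of keyed scale sum scores.  Item pairs involving a zero-variance item
#' are dropped with a warning.
#'
#' @param data A [likert_dataset()].
#' @return A list with elements `r_within_mean` (scalar) and `scale_cor`
#'   (`K` by `K` correlation matrix of scale sum scores).
#' @export
empirical_structure <- function(data) {
  stopifnot(inherits(data, "likert_dataset"))
  if (nrow(data$ratings) < 2L) stop("need at least 2 respondents", call. = FALSE)
  scl <- data$items$scale
  if (min(table(scl)) < 2L) stop("need at least 2 items per scale", call. = FALSE)
  sds <- apply(data$ratings, 2, stats::sd)
  degenerate <- sds == 0
  if (any(degenerate))
    warning(sprintf("%d zero-variance item(s) excluded from within-scale correlations",
                    sum(degenerate)), call. = FALSE)
  within <- c()
  for (k in levels(scl)) {
    idx <- which(scl == k & !degenerate)
    if (length(idx) >= 2L) {
      cm <- stats::cor(data$ratings[, idx, drop = FALSE])
      within <- c(within, cm[upper.tri(cm)])
    }
  }
  if (length(within) == 0L)
    stop("no same-scale item pair with non-zero variance", call. = FALSE)
  scores <- likert_scale_scores(data)
  list(r_within_mean = mean(within),
       scale_cor = stats::cor(unclass(scores)))
}
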