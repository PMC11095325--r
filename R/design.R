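#' All unordered triples of scales
#'
#' A triplet item set draws its three items from three distinct scales;
#' this enumerates the `choose(K, 3)` possible scale combinations in
#' deterministic lexicographic order.  With 5 scales there are 10
#' combinations (30 binary variables); with 20 scales, 1140.
#'
#' @param n_scales Number of scales `K` (at least 3).
#' @return A `choose(K, 3)` by 3 integer matrix, one triple per row.
#' @export
scale_triples <- function(n_scales) {
  n_scales <- assert_count(n_scales, "n_scales")
  if (n_scales < 3L)
    stop("the minimum number of scales for triplet item sets is three",
         call. = FALSE)
  t(utils::combn(n_scales, 3L))
}

# Deterministic position schedule: cycle the lexicographic triple list
# and, for each set, place its three scales into positions 1..3 by the
# assignment that minimizes the current position-count imbalance (ties
# broken in fixed permutation order).  Whenever exact balance is
# attainable -- e.g. n_sets a multiple of choose(K,3) with per-scale
# appearance counts divisible by 3 -- the greedy schedule achieves it.
position_schedule <- function(n_scales, n_sets) {
  tri <- scale_triples(n_scales)
  nt <- nrow(tri)
  counts <- matrix(0L, n_scales, 3L)
  perms <- rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                 c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  out <- matrix(0L, n_sets, 3L)
  for (i in seq_len(n_sets)) {
    sc <- tri[((i - 1L) %% nt) + 1L, ]
    best <- perms[1L, ]
    best_cost <- Inf
    for (j in 1:6) {
      p <- perms[j, ]
      cost <- sum(counts[cbind(sc, p)])
      if (cost < best_cost) {
        best_cost <- cost
        best <- p
      }
    }
    counts[cbind(sc, best)] <- counts[cbind(sc, best)] + 1L
    out[i, best] <- sc  # out[i, position] = scale
  }
  out
}

#' Build a balanced forced-choice triplet design
#'
#' Constructs `n_sets` item sets of three items from three distinct
#' scales.  Scale triples are cycled in deterministic lexicographic
#' order, and the placement of scales into set positions (first, second,
#' third) follows a deterministic balancing schedule, so that across a
#' full cycle every scale occupies every position equally often.  Only
#' the item identities (drawn uniformly with replacement from each
#' scale's pool) and, under `mixed_random` keying, the key signs are
#' random.
#'
#' @param item_pool A [likert_dataset()] or its `items` data frame
#'   (columns `item_id`, `scale`, `key`) supplying the items available
#'   per scale.
#' @param n_sets Number of triplet item sets; each yields three binary
#'   variables.  If `n_sets` is not a multiple of `choose(K, 3)` the
#'   design is still emitted, with a warning that scale coverage is
#'   unbalanced.
#' @param keying `"positive_only"` (all keys `+1`),
#'   `"mixed_random"` (each slot's key an independent fair `+1`/`-1`
#'   draw, i.e. artificial random reversal), or `"factual"` (keys taken
#'   from the item metadata).
#' @param seed Optional RNG seed; the scale/position schedule is
#'   seed-independent, only item sampling and key draws depend on it.
#' @return An object of class `triplet_design`: a data frame with one row
#'   per slot (`set`, `position`, `item_id`, `scale`, `key`) plus
#'   attributes `keying` and `n_scales`.
#' @export
balanced_design <- function(item_pool, n_sets,
                            keying = c("positive_only", "mixed_random", "factual"),
                            seed = NULL) {
  keying <- match.arg(keying)
  n_sets <- assert_count(n_sets, "n_sets")
  items <- if (inherits(item_pool, "likert_dataset")) item_pool$items else item_pool
  stopifnot(all(c("item_id", "scale", "key") %in% names(items)))
  items$scale <- factor(items$scale)
  K <- nlevels(items$scale)
  if (K < 3L)
    stop("the minimum number of scales for triplet item sets is three",
         call. = FALSE)
  pool <- split(seq_len(nrow(items)), items$scale)
  if (any(lengths(pool) == 0L))
    stop("every scale needs at least one item", call. = FALSE)
  n_triples <- choose(K, 3)
  if (n_sets %% n_triples != 0)
    warning(sprintf(
      "n_sets = %d is not a multiple of the %d scale triples; scale coverage will be unbalanced",
      n_sets, n_triples), call. = FALSE)
  sched <- position_schedule(K, n_sets)  # [set, position] -> scale index
  scale_idx <- as.vector(t(sched))       # slot-major: set 1 pos 1..3, ...
  rows <- with_seed(seed, {
    picked <- vapply(scale_idx, function(k) {
      p <- pool[[k]]
      p[sample.int(length(p), 1L)]
    }, integer(1))
    key <- switch(keying,
      positive_only = rep(1L, length(picked)),
      mixed_random = sample(c(1L, -1L), length(picked), replace = TRUE),
      factual = items$key[picked])
    data.frame(
      set = rep(seq_len(n_sets), each = 3L),
      position = rep(1:3, n_sets),
      item_id = items$item_id[picked],
      item_index = picked,
      scale = items$scale[picked],
      key = key,
      stringsAsFactors = FALSE)
  })
  structure(rows, class = c("triplet_design", "data.frame"),
            keying = keying, n_scales = K,
            scale_levels = levels(items$scale), seed = seed)
}

#' Number of binary variables implied by a design
#' @param design A `triplet_design`.
#' @return `3 * n_sets`.
#' @export
n_binary_variables <- function(design) {
  stopifnot(inherits(design, "triplet_design"))
  3L * max(design$set)
}

#' @export
print.triplet_design <- function(x, ...) {
  cat(sprintf(
    "Forced-choice triplet design: %d item sets over %d scales (%s keying), %d binary variables\n",
    max(x$set), attr(x, "n_scales"), attr(x, "keying"), 3L * max(x$set)))
  invisible(x)
}

#' Balance diagnostics for a triplet design
#'
#' Summarizes how evenly a design spreads scales over sets, positions,
#' scale-pair co-occurrences, and key signs.
#'
#' @param design A `triplet_design` from [balanced_design()].
#' @return A list with `scale_counts` (slot appearances per scale),
#'   `position_counts` (scale by position matrix), `pair_counts`
#'   (scale by scale co-occurrence matrix), and `key_proportion_positive`.
#' @export
design_balance_report <- function(design) {
  stopifnot(inherits(design, "triplet_design"), nrow(design) > 0L)
  lev <- attr(design, "scale_levels")
  scl <- factor(design$scale, levels = lev)
  K <- length(lev)
  scale_counts <- table(scale = scl)
  position_counts <- table(scale = scl, position = design$position)
  pair_counts <- matrix(0L, K, K, dimnames = list(lev, lev))
  for (s in split(as.integer(scl), design$set)) {
    for (pr in utils::combn(sort(s), 2L, simplify = FALSE)) {
      pair_counts[pr[1], pr[2]] <- pair_counts[pr[1], pr[2]] + 1L
      pair_counts[pr[2], pr[1]] <- pair_counts[pr[2], pr[1]] + 1L
    }
  }
  list(scale_counts = scale_counts,
       position_counts = position_counts,
       pair_counts = pair_counts,
       key_proportion_positive = mean(design$key == 1L))
}

#' Write a design sheet to CSV
#' @param design A `triplet_design`.
#' @param file Path of the CSV to write.
#' @return `file`, invisibly.
#' @export
write_design_csv <- function(design, file) {
  stopifnot(inherits(design, "triplet_design"))
  utils::write.csv(
    design[, c("set", "position", "item_id", "scale", "key")],
    file, row.names = FALSE)
  invisible(file)
}
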