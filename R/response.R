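#' Effective preference of a keyed item
#'
#' The preference value an item carries into a forced-choice comparison:
#' the raw rating for positively keyed items, the reversed rating
#' `L + 1 - x` for negatively keyed items.
#'
#' @param rating Integer rating(s) in `1..levels`.
#' @param key `+1` or `-1` (vectorized).
#' @param levels Number of response levels.
#' @return The effective preference(s).
#' @export
effective_preference <- function(rating, key, levels = 5) {
  levels <- assert_count(levels, "levels", min = 2L)
  if (any(rating < 1 | rating > levels | rating != round(rating)))
    stop(sprintf("ratings must be integers in 1..%d", levels), call. = FALSE)
  if (any(!key %in% c(-1, 1)))
    stop("keys must be +1 or -1", call. = FALSE)
  ifelse(key == 1, rating, levels + 1 - rating)
}

#' Rank the three slots of a triplet by jittered preference
#'
#' Adds independent zero-mean Gaussian noise (default SD 0.1) to the
#' three effective preferences and returns the strict ranking of the
#' slots.  With integer preferences and a small SD the jitter never
#' overturns a genuine preference difference; its only role is to break
#' ties equiprobably, so tied slots are each ranked first with equal
#' probability across draws.
#'
#' @param preferences Numeric vector of three effective preferences.
#' @param jitter_sd Non-negative jitter standard deviation.
#' @return Integer vector of slot indices, best first (e.g. `c(2, 1, 3)`
#'   means slot 2 is preferred, slot 3 rejected).
#' @export
rank_triplet <- function(preferences, jitter_sd = 0.1) {
  stopifnot(length(preferences) == 3L)
  if (!is.numeric(jitter_sd) || jitter_sd < 0)
    stop("`jitter_sd` must be non-negative", call. = FALSE)
  v <- preferences + stats::rnorm(3L, 0, jitter_sd)
  while (anyDuplicated(v)) v <- preferences + stats::rnorm(3L, 0, jitter_sd)
  order(v, decreasing = TRUE)
}

#' Dummy-code a triplet ranking
#'
#' The three binary indicators of the pairwise preferences implied by a
#' strict ranking of a triplet: `Dummy1 = [slot1 over slot2]`,
#' `Dummy2 = [slot1 over slot3]`, `Dummy3 = [slot2 over slot3]`.  The
#' mapping is a bijection between the 6 strict rankings and 6 of the 8
#' binary patterns; the two intransitive patterns `(1,0,1)` and `(0,1,0)`
#' can never occur.
#'
#' @param ranking Integer permutation of `1:3`, best slot first, as
#'   returned by [rank_triplet()].
#' @return Integer vector `c(d1, d2, d3)` of 0/1 indicators.
#' @export
dummy_code <- function(ranking) {
  if (length(ranking) != 3L || !all(sort(ranking) == 1:3))
    stop("`ranking` must be a strict ranking: a permutation of 1:3",
         call. = FALSE)
  pos <- match(1:3, ranking)  # pos[s] = rank of slot s (1 = best)
  as.integer(c(pos[1] < pos[2], pos[1] < pos[3], pos[2] < pos[3]))
}

#' Convert Likert ratings into forced-choice binary responses
#'
#' For every respondent and every item set of the design: apply the slot
#' keys to the ratings ([effective_preference()]), add independent
#' Gaussian tie-breaking jitter per respondent, set and slot, and code
#' the resulting strict ranking into the three pairwise dummy variables
#' ([dummy_code()]).  The respondent effectively selects the
#' highest-preference item as most typical and the lowest as least
#' typical, with ties resolved at random.
#'
#' @param data A [likert_dataset()].
#' @param design A `triplet_design` from [balanced_design()] whose items
#'   exist in `data`.
#' @param jitter_sd Tie-breaking jitter SD (default 0.1).
#' @param seed Optional RNG seed for the jitter draws.
#' @return An object of class `mfc_binary`: list with `values`
#'   (`n_respondents` by `3 * n_sets` 0/1 matrix), `pairs` (per-column
#'   metadata: set, compared slots, items, scales, keys), `design`,
#'   `jitter_sd`, `seed`.
#' @export
respond <- function(data, design, jitter_sd = 0.1, seed = NULL) {
  stopifnot(inherits(data, "likert_dataset"),
            inherits(design, "triplet_design"))
  if (!is.numeric(jitter_sd) || jitter_sd < 0)
    stop("`jitter_sd` must be non-negative", call. = FALSE)
  idx <- match(design$item_id, data$items$item_id)
  if (anyNA(idx)) {
    missing <- unique(design$item_id[is.na(idx)])
    stop("design items missing from the dataset: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  n <- nrow(data$ratings)
  n_sets <- max(design$set)
  L <- data$levels[2] - data$levels[1] + 1L
  # slot matrices [set, position]
  item_m <- matrix(idx, n_sets, 3L, byrow = TRUE)
  key_m <- matrix(design$key, n_sets, 3L, byrow = TRUE)
  values <- matrix(0L, n, 3L * n_sets)
  pair_slots <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  meta <- vector("list", n_sets)
  jitter <- with_seed(seed, stats::rnorm(n * 3L * n_sets, 0, jitter_sd))
  dim(jitter) <- c(n, 3L, n_sets)
  base <- data$ratings - data$levels[1] + 1L  # canonical 1..L
  for (i in seq_len(n_sets)) {
    eff <- matrix(0, n, 3L)
    for (s in 1:3) {
      r <- base[, item_m[i, s]]
      eff[, s] <- if (key_m[i, s] == 1L) r else L + 1L - r
    }
    v <- eff + jitter[, , i]
    cols <- (i - 1L) * 3L + 1:3
    values[, cols[1]] <- (v[, 1] > v[, 2]) + 0L
    values[, cols[2]] <- (v[, 1] > v[, 3]) + 0L
    values[, cols[3]] <- (v[, 2] > v[, 3]) + 0L
    meta[[i]] <- data.frame(
      column = cols, set = i,
      slot_a = pair_slots[, 1], slot_b = pair_slots[, 2],
      item_a = data$items$item_id[item_m[i, pair_slots[, 1]]],
      item_b = data$items$item_id[item_m[i, pair_slots[, 2]]],
      scale_a = as.character(design$scale[(i - 1L) * 3L + pair_slots[, 1]]),
      scale_b = as.character(design$scale[(i - 1L) * 3L + pair_slots[, 2]]),
      key_a = key_m[i, pair_slots[, 1]],
      key_b = key_m[i, pair_slots[, 2]],
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, meta)
  colnames(values) <- sprintf("set%04d_d%d", pairs$set,
                              rep(1:3, n_sets))
  structure(list(values = values, pairs = pairs, design = design,
                 scale_levels = attr(design, "scale_levels"),
                 jitter_sd = jitter_sd, seed = seed),
            class = "mfc_binary")
}

#' @export
print.mfc_binary <- function(x, ...) {
  cat(sprintf(
    "MFC binary responses: %d respondents x %d dummy variables (%d item sets, jitter SD %.2g)\n",
    nrow(x$values), ncol(x$values), max(x$pairs$set), x$jitter_sd))
  invisible(x)
}

#' Write an MFC binary response matrix to CSV
#'
#' Emits the 0/1 matrix with dummy-variable column names; the companion
#' pair metadata (which items and scales each column compares) is written
#' alongside with suffix `"_pairs"` so the pair round-trips with the
#' design sheet.
#'
#' @param binaries An `mfc_binary` from [respond()].
#' @param file Path of the CSV to write.
#' @return `file`, invisibly.
#' @export
write_binary_csv <- function(binaries, file) {
  stopifnot(inherits(binaries, "mfc_binary"))
  utils::write.csv(binaries$values, file, row.names = FALSE)
  meta_file <- sub("(\\.[Cc][Ss][Vv])?$", "_pairs\\1",
                   file)
  if (identical(meta_file, file)) meta_file <- paste0(file, "_pairs")
  utils::write.csv(binaries$pairs, meta_file, row.names = FALSE)
  invisible(file)
}
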