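#' Reverse a preference rating
#'
#' Maps a rating `x` on an `L`-level scale to its mirror `L + 1 - x`, the
#' standard reversal applied to negatively keyed items (on a 5-level
#' scale, 4 becomes 2 and 2 becomes 4).  The operation is an involution.
#'
#' @param x Integer rating(s) in `1..levels`.
#' @param levels Number of response levels `L`.
#' @return The reversed rating(s).
#' @export
reverse_preference <- function(x, levels = 5) {
  levels <- assert_count(levels, "levels", min = 2L)
  if (any(x < 1 | x > levels | x != round(x)))
    stop(sprintf("ratings must be integers in 1..%d", levels), call. = FALSE)
  levels + 1 - x
}

#' Compare two preference ratings
#'
#' The elementary forced-choice comparison: the higher preference earns
#' `+1`, the lower `-1`, and a tie earns both items `0`.
#'
#' @param a,b Ratings on a common level scale (vectorized).
#' @return `sign(a - b)`: `+1`, `0` or `-1` for item `a`.
#' @export
compare_preferences <- function(a, b) {
  sign(a - b)
}

#' Outcome of a two-item forced-choice comparison
#'
#' For a pair of items with preferences `x` and `y`, computes each item's
#' outcome sum under two keying regimes.  Under `"positive_only"` there is
#' a single comparison and the outcome is simply `sign(x - y)` for item 1
#' (ipsative: the two outcomes always cancel).  Under `"mixed"` keying
#' each item also exists in a reversed (negatively keyed) version, giving
#' four comparisons -- positive vs positive, reversed vs reversed, and the
#' two cross pairings -- and an item's outcome is the points it wins in
#' its positive form minus the points won by its reversed form.  The
#' mixed sums retain information about absolute levels: two top ratings
#' both score positively instead of cancelling.
#'
#' @param x,y Integer preferences in `1..levels` (vectorized).
#' @param levels Number of response levels.
#' @param mode `"mixed"` or `"positive_only"`.
#' @return A data frame with columns `x`, `y`, `sum1`, `sum2`.
#' @export
pair_outcome <- function(x, y, levels = 5, mode = c("mixed", "positive_only")) {
  mode <- match.arg(mode)
  levels <- assert_count(levels, "levels", min = 2L)
  if (any(c(x, y) < 1 | c(x, y) > levels | c(x, y) != round(c(x, y))))
    stop(sprintf("preferences must be integers in 1..%d", levels), call. = FALSE)
  if (mode == "positive_only") {
    s1 <- as.integer(compare_preferences(x, y))
    s2 <- -s1
  } else {
    xm <- levels + 1 - x
    ym <- levels + 1 - y
    # points won by each of the four keyed forms
    p_x  <- compare_preferences(x, y) + compare_preferences(x, ym)
    p_xm <- compare_preferences(xm, ym) + compare_preferences(xm, y)
    p_y  <- compare_preferences(y, x) + compare_preferences(y, xm)
    p_ym <- compare_preferences(ym, xm) + compare_preferences(ym, x)
    # reversed forms count against their item
    s1 <- as.integer(p_x - p_xm)
    s2 <- as.integer(p_y - p_ym)
  }
  data.frame(x = as.integer(x), y = as.integer(y), sum1 = s1, sum2 = s2)
}

#' Enumerate all pairwise comparison outcomes on an L-level scale
#'
#' @param levels Number of response levels.
#' @param grid `"triangle"` for the `L(L+1)/2` unordered pairs with
#'   `x >= y` (ties first, then off-diagonal pairs ordered by the lower
#'   rating), or `"ordered"` for the full `L x L` grid.
#' @param mode Keying regime passed to [pair_outcome()].
#' @return A data frame with columns `x`, `y`, `sum1`, `sum2`.
#' @export
enumerate_outcomes <- function(levels = 5, grid = c("triangle", "ordered"),
                               mode = c("mixed", "positive_only")) {
  grid <- match.arg(grid)
  mode <- match.arg(mode)
  levels <- assert_count(levels, "levels", min = 2L)
  g <- expand.grid(x = seq_len(levels), y = seq_len(levels))
  if (grid == "triangle") {
    g <- g[g$x >= g$y, ]
    # ties first, then by the lower rating, as conventionally tabulated
    g <- g[order(g$x != g$y, g$y, g$x), ]
  }
  rownames(g) <- NULL
  pair_outcome(g$x, g$y, levels = levels, mode = mode)
}

#' Correlation between an item's rating and its comparison outcome
#'
#' Quantifies how much absolute-level information the pairwise outcome
#' retains: the Pearson correlation between one item's preference value
#' and its outcome sum over an enumeration table.
#'
#' @param table A data frame from [enumerate_outcomes()] (columns `x`,
#'   `y`, `sum1`, `sum2`).
#' @param item Which item, `1` or `2`.
#' @return The Pearson correlation.
#' @export
rating_outcome_correlation <- function(table, item = 1) {
  stopifnot(item %in% c(1, 2))
  pref <- if (item == 1) table$x else table$y
  out <- if (item == 1) table$sum1 else table$sum2
  if (length(unique(pref)) < 2L || length(unique(out)) < 2L)
    stop("correlation undefined: constant preference or outcome column",
         call. = FALSE)
  stats::cor(pref, out)
}
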