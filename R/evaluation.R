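#' Cross-correlations between original and recovered scale scores
#'
#' The central recovery diagnostic: Pearson correlations between every
#' recovered (forced-choice) scale score and every original (Likert sum)
#' scale score.  The diagonal holds the same-scale recovery correlations;
#' the off-diagonal cells show how much the recovered scores leak onto
#' other scales.
#'
#' @param original A `scale_scores` matrix (the reference scores).
#' @param recovered A `scale_scores` matrix on the same respondents with
#'   the same scale order.
#' @return A `K` by `K` matrix: rows are recovered scales, columns
#'   original scales.  Cells involving a constant score column are `NA`
#'   with a warning.
#' @export
recovery_correlations <- function(original, recovered) {
  original <- as.matrix(original)
  recovered <- as.matrix(recovered)
  if (nrow(original) != nrow(recovered))
    stop("score matrices must cover the same respondents", call. = FALSE)
  if (ncol(original) != ncol(recovered))
    stop("score matrices must have the same scales", call. = FALSE)
  const <- apply(original, 2, stats::sd) == 0 |
    apply(recovered, 2, stats::sd) == 0
  if (any(const))
    warning("constant score column(s); affected correlations are NA",
            call. = FALSE)
  suppressWarnings(stats::cor(recovered, original))
}

#' Mean same-scale and other-scale recovery correlations
#'
#' @param cross A matrix from [recovery_correlations()].
#' @return Named numeric vector `c(same, other)`: the mean diagonal and
#'   the mean off-diagonal correlation.
#' @export
recovery_summary <- function(cross) {
  stopifnot(is.matrix(cross), nrow(cross) == ncol(cross))
  c(same = mean(diag(cross), na.rm = TRUE),
    other = mean(cross[row(cross) != col(cross)], na.rm = TRUE))
}

#' Inter-scale correlation matrix of a score set
#'
#' @param scores A `scale_scores` matrix (or any respondent-by-scale
#'   matrix).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
intercorrelations <- function(scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 2L) stop("need at least 2 scales", call. = FALSE)
  const <- apply(scores, 2, stats::sd) == 0
  if (any(const))
    warning("constant score column(s); affected correlations are NA",
            call. = FALSE)
  suppressWarnings(stats::cor(scores))
}

#' Canonical correlations and Pillai trace between two score sets
#'
#' Canonical correlation analysis of two respondent-by-scale matrices,
#' summarized by the Pillai trace (the sum of squared canonical
#' correlations, bounded by the number of dimensions).  A trace near `K`
#' means all `K` dimensions of one set are linearly recoverable from the
#' other.
#'
#' @param X,Y Numeric matrices with the same number of rows.
#' @param cond_cutoff Condition-number cutoff for the within-set
#'   correlation matrices beyond which the input is declared singular
#'   (default `1e10`), instead of silently regularizing.
#' @return A list with `cancor` (canonical correlations, decreasing) and
#'   `pillai`.
#' @export
canonical_pillai <- function(X, Y, cond_cutoff = 1e10) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same rows", call. = FALSE)
  if (nrow(X) <= ncol(X) + ncol(Y))
    stop("need more respondents than total score columns", call. = FALSE)
  Xs <- scale(X)
  Ys <- scale(Y)
  if (anyNA(Xs) || anyNA(Ys))
    stop("canonical correlation failed: constant score column", call. = FALSE)
  for (S in list(stats::cor(X), stats::cor(Y))) {
    if (kappa(S, exact = TRUE) > cond_cutoff)
      stop("canonical correlation failed because of singularity in the correlation matrix",
           call. = FALSE)
  }
  cc <- stats::cancor(Xs, Ys, xcenter = FALSE, ycenter = FALSE)
  rho <- cc$cor
  list(cancor = rho, pillai = sum(rho^2))
}

#' Per-item selection ratios of a binary response matrix
#'
#' The proportion of pairwise comparisons each item wins, over all
#' respondents and all dummy variables it appears in.  Items with a
#' near-.50 ratio are selected about as often as rejected; extreme ratios
#' flag items that dominate (or never survive) their comparisons, as
#' happens when item means differ a lot.
#'
#' @param binaries An `mfc_binary` from [respond()].
#' @return A list with `items` (data frame: `item_id`, `wins`,
#'   `appearances`, `ratio`) and `summary` (mean, SD, range of the
#'   ratios).  Items that never entered a comparison are absent.
#' @export
selection_ratios <- function(binaries) {
  stopifnot(inherits(binaries, "mfc_binary"))
  V <- binaries$values
  pairs <- binaries$pairs
  n <- nrow(V)
  wins_a <- colSums(V)
  wins_b <- n - wins_a
  tab <- rbind(
    data.frame(item_id = pairs$item_a, wins = wins_a, n = n),
    data.frame(item_id = pairs$item_b, wins = wins_b, n = n))
  agg <- stats::aggregate(cbind(wins, n) ~ item_id, data = tab, FUN = sum)
  agg$ratio <- agg$wins / agg$n
  names(agg)[names(agg) == "n"] <- "appearances"
  list(items = agg,
       summary = c(mean = mean(agg$ratio), sd = stats::sd(agg$ratio),
                   min = min(agg$ratio), max = max(agg$ratio)))
}

#' Replicated end-to-end recovery simulation
#'
#' Runs the full pipeline -- simulate a Likert inventory, build a balanced
#' triplet design, convert to forced-choice binaries, score classically,
#' and compare with the original Likert sum scores -- `n_reps` times with
#' independent seeds, and aggregates the recovery metrics.
#'
#' @param config A [likert_config()] describing the generated inventory.
#' @param n_sets Number of triplet item sets per replication.
#' @param keying Keying mode passed to [balanced_design()].
#' @param jitter_sd Tie-breaking jitter SD passed to [respond()].
#' @param n_reps Number of replications (default 10).
#' @param seed Master seed; all per-replication seeds derive from it.
#' @return An object of class `mfc_replications`: list with
#'   `replications` (one row per replication: `same` and `other` mean
#'   recovery correlations, per-scale diagonal, `pillai`, mean absolute
#'   off-diagonal of the original and recovered inter-scale matrices),
#'   `aggregate` (mean and SD over replications), `mean_recovery` (the
#'   averaged cross-correlation matrix), and the call parameters.
#' @export
run_replications <- function(config, n_sets, keying = "mixed_random",
                             jitter_sd = 0.1, n_reps = 10, seed = 1) {
  stopifnot(inherits(config, "likert_config"))
  n_reps <- assert_count(n_reps, "n_reps")
  seeds <- matrix(derive_seeds(seed, 3L * n_reps), ncol = 3L)
  K <- config$n_scales
  rows <- vector("list", n_reps)
  mean_recovery <- matrix(0, K, K)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- seeds[r, 1]
    data <- simulate_likert(cfg)
    design <- suppressWarnings(
      balanced_design(data, n_sets, keying = keying, seed = seeds[r, 2]))
    binaries <- respond(data, design, jitter_sd = jitter_sd,
                        seed = seeds[r, 3])
    recovered <- classical_score(binaries)
    original <- likert_scale_scores(data)
    cross <- recovery_correlations(original, recovered)
    mean_recovery <- mean_recovery + cross / n_reps
    summ <- recovery_summary(cross)
    pillai <- tryCatch(canonical_pillai(original, recovered)$pillai,
                       error = function(e) NA_real_)
    orig_ic <- intercorrelations(original)
    rec_ic <- intercorrelations(recovered)
    off <- row(orig_ic) != col(orig_ic)
    rows[[r]] <- data.frame(
      rep = r, same = summ["same"], other = summ["other"],
      t(stats::setNames(diag(cross), paste0("r_scale", seq_len(K)))),
      pillai = pillai,
      orig_between = mean(orig_ic[off]),
      recovered_between = mean(rec_ic[off]),
      row.names = NULL)
  }
  reps <- do.call(rbind, rows)
  num <- reps[, setdiff(names(reps), "rep")]
  aggregate <- data.frame(
    metric = names(num),
    mean = vapply(num, mean, numeric(1), na.rm = TRUE),
    sd = vapply(num, stats::sd, numeric(1), na.rm = TRUE),
    row.names = NULL)
  structure(list(replications = reps, aggregate = aggregate,
                 mean_recovery = mean_recovery,
                 config = config, n_sets = n_sets, keying = keying,
                 jitter_sd = jitter_sd, n_reps = n_reps, seed = seed),
            class = "mfc_replications")
}

#' @export
print.mfc_replications <- function(x, ...) {
  cat(sprintf(
    "MFC recovery simulation: %d replications, %d sets, %s keying\n",
    x$n_reps, x$n_sets, x$keying))
  same <- x$aggregate[x$aggregate$metric == "same", ]
  other <- x$aggregate[x$aggregate$metric == "other", ]
  cat(sprintf("  mean same-scale recovery r = %.2f (SD %.2f)\n",
              same$mean, same$sd))
  cat(sprintf("  mean other-scale r         = %.2f (SD %.2f)\n",
              other$mean, other$sd))
  invisible(x)
}

#' Recovery as a function of item count
#'
#' Compares three ways of shortening an inventory: forced-choice triplet
#' sets with positive-only keying, forced-choice sets with mixed random
#' keying, and plain random subsets of single-stimulus items.  For each
#' item count `m`, `n_draws` random item selections are generated (for
#' the forced-choice methods, `m` triplet sets; for the single-stimulus
#' method, `m` items per scale) and the mean same-scale correlation with
#' the reference scale scores is pooled over draws.
#'
#' In `"full"` mode items are drawn from the whole inventory and judged
#' against the full-inventory scores.  In `"split_half"` mode each
#' scale's item pool is randomly halved per draw: items are drawn from
#' one half and judged against scale scores computed from the other
#' half, so the shortened instrument is evaluated on items it never saw.
#'
#' @param data A [likert_dataset()].
#' @param item_counts Integer vector of item counts `m` to evaluate.
#' @param mode `"full"` or `"split_half"`.
#' @param n_draws Random selections pooled per item count (default 100).
#' @param jitter_sd Tie-breaking jitter SD for the forced-choice methods.
#' @param replace Whether single-stimulus subsets are drawn with
#'   replacement (default `TRUE`; forced-choice designs always sample
#'   with replacement).
#' @param seed Master seed.
#' @return A data frame with one row per `m` and method
#'   (`"mfc_positive"`, `"mfc_mixed"`, `"single"`): pooled mean and SD
#'   of the mean same-scale correlation.
#' @export
learning_curve <- function(data, item_counts, mode = c("full", "split_half"),
                           n_draws = 100, jitter_sd = 0.1, replace = TRUE,
                           seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "likert_dataset"))
  K <- n_scales(data)
  if (K < 3L) stop("need at least 3 scales", call. = FALSE)
  pool_sizes <- table(data$items$scale)
  half_sizes <- floor(pool_sizes / 2)
  for (m in item_counts) {
    avail <- if (mode == "split_half") min(half_sizes) else min(pool_sizes)
    if (!replace && m > avail)
      stop(sprintf("m = %d exceeds the available item pool (%d per scale)",
                   m, avail), call. = FALSE)
  }
  methods <- c("mfc_positive", "mfc_mixed", "single")
  seeds <- derive_seeds(seed, length(item_counts) * n_draws)
  dim(seeds) <- c(length(item_counts), n_draws)
  out <- list()
  for (mi in seq_along(item_counts)) {
    m <- item_counts[mi]
    vals <- matrix(NA_real_, n_draws, 3L,
                   dimnames = list(NULL, methods))
    for (d in seq_len(n_draws)) {
      sub_seeds <- derive_seeds(seeds[mi, d], 4L)
      split_sets <- with_seed(sub_seeds[1], {
        lapply(split(seq_len(nrow(data$items)), data$items$scale),
               function(idx) {
                 if (mode == "split_half") {
                   a <- sample(idx, floor(length(idx) / 2))
                   list(model = a, test = setdiff(idx, a))
                 } else list(model = idx, test = idx)
               })
      })
      model_idx <- sort(unlist(lapply(split_sets, `[[`, "model")))
      test_idx <- sort(unlist(lapply(split_sets, `[[`, "test")))
      model_data <- subset_items(data, model_idx)
      reference <- likert_scale_scores(subset_items(data, test_idx))
      for (keying in c("positive_only", "mixed_random")) {
        design <- suppressWarnings(
          balanced_design(model_data, m, keying = keying,
                          seed = sub_seeds[2]))
        binaries <- respond(model_data, design, jitter_sd = jitter_sd,
                            seed = sub_seeds[3])
        cross <- recovery_correlations(reference, classical_score(binaries))
        col <- if (keying == "positive_only") "mfc_positive" else "mfc_mixed"
        vals[d, col] <- mean(diag(cross))
      }
      single_idx <- with_seed(sub_seeds[4], {
        unlist(lapply(split_sets, function(s) {
          s$model[sample.int(length(s$model), m, replace = replace)]
        }))
      })
      single_scores <- likert_scale_scores(subset_items(data, single_idx))
      cross <- recovery_correlations(reference, single_scores)
      vals[d, "single"] <- mean(diag(cross))
    }
    out[[mi]] <- data.frame(
      m = m, method = methods,
      mean_correlation = colMeans(vals),
      sd = apply(vals, 2, stats::sd),
      row.names = NULL)
  }
  do.call(rbind, out)
}

# Restrict a likert_dataset to a subset of item columns (indices may
# repeat, e.g. for sampling with replacement); repeated columns get
# disambiguated item ids.
subset_items <- function(data, idx) {
  ratings <- data$ratings[, idx, drop = FALSE]
  ids <- data$items$item_id[idx]
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  colnames(ratings) <- ids
  likert_dataset(ratings,
                 item_scale = data$items$scale[idx],
                 item_key = data$items$key[idx],
                 levels = data$levels)
}

#' Regenerate the package's reference tables
#'
#' Convenience harness around the module functions: `"outcomes"` emits
#' the full pairwise outcome enumeration on a 5-level scale, and
#' `"recovery_mixed"` / `"recovery_positive"` run the replicated
#' synthetic recovery study over a grid of within- and between-scale
#' correlations (5 scales of 24 five-level items, 80 sets, 240 binary
#' variables).
#'
#' @param table One of `"outcomes"`, `"recovery_mixed"`,
#'   `"recovery_positive"`.
#' @param r_within,r_between Correlation grids for the recovery tables;
#'   crossed pairwise (recycled to equal length).
#' @param n_reps Replications per grid cell.
#' @param n_respondents Respondents per replication.
#' @param seed Master seed.
#' @return A data frame.
#' @export
reproduce_table <- function(table = c("outcomes", "recovery_mixed",
                                      "recovery_positive"),
                            r_within = c(.10, .20, .30),
                            r_between = c(0, .20, .45, .60, .73),
                            n_reps = 10, n_respondents = 1000, seed = 1) {
  table <- match.arg(table)
  if (table == "outcomes")
    return(enumerate_outcomes(5, grid = "triangle", mode = "mixed"))
  keying <- if (table == "recovery_mixed") "mixed_random" else "positive_only"
  grid <- expand.grid(r_within = r_within, r_between = r_between)
  grid <- grid[order(grid$r_within, grid$r_between), ]
  seeds <- derive_seeds(seed, nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- likert_config(n_respondents = n_respondents, n_scales = 5,
                         items_per_scale = 24, levels = 5,
                         r_within = grid$r_within[i],
                         r_between = grid$r_between[i])
    res <- run_replications(cfg, n_sets = 80, keying = keying,
                            n_reps = n_reps, seed = seeds[i])
    agg <- res$aggregate
    data.frame(
      r_within = grid$r_within[i], r_between = grid$r_between[i],
      original_between = agg$mean[agg$metric == "orig_between"],
      same = agg$mean[agg$metric == "same"],
      other = agg$mean[agg$metric == "other"])
  })
  do.call(rbind, rows)
}
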