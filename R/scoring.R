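#' Scale score matrices
#'
#' Internal constructor tagging a respondent-by-scale score matrix with
#' its provenance (`"likert_sum"` or `"mfc_classical"`).
#' @noRd
scale_scores <- function(scores, provenance) {
  structure(scores, class = c("scale_scores", class(scores)),
            provenance = provenance)
}

#' @export
print.scale_scores <- function(x, ...) {
  cat(sprintf("Scale scores (%s): %d respondents x %d scales\n",
              attr(x, "provenance"), nrow(x), ncol(x)))
  invisible(x)
}

#' Classical (+1/-1) scoring of forced-choice binary responses
#'
#' The classical coding of forced choice, with every item weighted 1: in
#' each pairwise comparison the preferred item contributes `+1` times its
#' key to its scale and the rejected item `-1` times its key, and a
#' respondent's score on a scale is the total over all comparisons.  For
#' positive-only designs each comparison is zero-sum, so the scores are
#' fully ipsative (they sum to exactly zero per respondent across
#' scales); mixed keying breaks that constraint and restores
#' absolute-level information.
#'
#' @param binaries An `mfc_binary` from [respond()], or any list with a
#'   0/1 `values` matrix and a `pairs` metadata data frame (columns
#'   `scale_a`, `scale_b`, `key_a`, `key_b`) plus `scale_levels`.
#' @return A `scale_scores` matrix (`n_respondents` by `K`, provenance
#'   `"mfc_classical"`).
#' @export
classical_score <- function(binaries) {
  if (is.null(binaries$values) || is.null(binaries$pairs))
    stop("`binaries` must carry both values and pair metadata", call. = FALSE)
  pairs <- binaries$pairs
  need <- c("scale_a", "scale_b", "key_a", "key_b")
  if (!all(need %in% names(pairs)))
    stop("pair metadata must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (nrow(pairs) != ncol(binaries$values))
    stop("every dummy column needs one metadata row", call. = FALSE)
  lev <- binaries$scale_levels
  if (is.null(lev)) lev <- sort(unique(c(pairs$scale_a, pairs$scale_b)))
  V <- binaries$values
  n <- nrow(V)
  K <- length(lev)
  scores <- matrix(0, n, K, dimnames = list(NULL, lev))
  ia <- match(pairs$scale_a, lev)
  ib <- match(pairs$scale_b, lev)
  # wins of slot a are V[, j]; contribution of a: key_a * (2V - 1), of b:
  # key_b * (1 - 2V)
  signed <- 2 * V - 1
  for (k in seq_len(K)) {
    ca <- which(ia == k)
    cb <- which(ib == k)
    if (length(ca))
      scores[, k] <- scores[, k] +
        signed[, ca, drop = FALSE] %*% pairs$key_a[ca]
    if (length(cb))
      scores[, k] <- scores[, k] -
        signed[, cb, drop = FALSE] %*% pairs$key_b[cb]
  }
  scale_scores(scores, "mfc_classical")
}

#' Keyed Likert sum scores
#'
#' Per-scale sum scores of a single-stimulus inventory, with negatively
#' keyed items reversed (`L + 1 - x` on the canonical `1..L` metric)
#' before summing -- the "original data" scores that forced-choice
#' recovery is judged against.
#'
#' @param data A [likert_dataset()].
#' @return A `scale_scores` matrix (provenance `"likert_sum"`).
#' @export
likert_scale_scores <- function(data) {
  stopifnot(inherits(data, "likert_dataset"))
  base <- data$ratings - data$levels[1] + 1L
  L <- data$levels[2] - data$levels[1] + 1L
  keyed <- base
  neg <- data$items$key == -1L
  if (any(neg)) keyed[, neg] <- L + 1L - base[, neg]
  lev <- levels(data$items$scale)
  scores <- vapply(lev, function(k) {
    rowSums(keyed[, data$items$scale == k, drop = FALSE])
  }, numeric(nrow(keyed)))
  scale_scores(as.matrix(scores), "likert_sum")
}

#' Write scale scores to CSV
#' @param scores A `scale_scores` matrix.
#' @param file Path of the CSV to write.
#' @return `file`, invisibly.
#' @export
write_scores_csv <- function(scores, file) {
  stopifnot(inherits(scores, "scale_scores"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# provenance: %s", attr(scores, "provenance")), con)
  utils::write.csv(
    data.frame(respondent = seq_len(nrow(scores)), unclass(scores)),
    con, row.names = FALSE)
  invisible(file)
}
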