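#' Load a single-stimulus inventory from CSV files
#'
#' Reads a respondent-by-item rating matrix and its companion item
#' metadata sheet.  The ratings CSV has a header row of item ids and
#' optionally a first column of respondent ids; the metadata CSV has
#' columns `item_id`, `scale`, `key` (`+1`/`-1`).  Inventories coded on a
#' 0-based level range (e.g. 0--4) are shifted to the canonical `1..L`
#' metric; sum scores are equivariant to that shift.  Rows containing
#' missing ratings are dropped with a message reporting the count.
#'
#' @param ratings_csv Path to the ratings CSV.
#' @param metadata_csv Path to the item-metadata CSV.
#' @param levels Optional `c(min_level, max_level)` declared range; if
#'   omitted, inferred from the data.
#' @return A [likert_dataset()].
#' @export
load_inventory <- function(ratings_csv, metadata_csv, levels = NULL) {
  ratings <- utils::read.csv(ratings_csv, check.names = FALSE)
  meta <- utils::read.csv(metadata_csv, stringsAsFactors = FALSE)
  need <- c("item_id", "scale", "key")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  first_is_id <- !names(ratings)[1] %in% meta$item_id &&
    (!is.numeric(ratings[[1]]) ||
       tolower(names(ratings)[1]) %in% c("respondent", "respondent_id", "id"))
  if (first_is_id) ratings <- ratings[, -1, drop = FALSE]
  unmapped <- setdiff(names(ratings), meta$item_id)
  if (length(unmapped))
    stop("rating columns not in the item metadata: ",
         paste(utils::head(unmapped, 5), collapse = ", "), call. = FALSE)
  meta <- meta[match(names(ratings), meta$item_id), ]
  complete <- stats::complete.cases(ratings)
  if (any(!complete)) {
    message(sprintf("dropping %d row(s) with missing ratings", sum(!complete)))
    ratings <- ratings[complete, , drop = FALSE]
  }
  m <- as.matrix(ratings)
  if (!is.numeric(m) || any(m != round(m)))
    stop("ratings must be integers", call. = FALSE)
  if (is.null(levels)) levels <- range(m)
  if (any(m < levels[1] | m > levels[2])) {
    bad <- which(m < levels[1] | m > levels[2], arr.ind = TRUE)[1, ]
    stop(sprintf("rating outside declared range %d..%d at row %d, item %s",
                 levels[1], levels[2], bad[1], colnames(m)[bad[2]]),
         call. = FALSE)
  }
  # shift to the canonical 1..L metric
  m <- m - as.integer(levels[1]) + 1L
  L <- as.integer(levels[2]) - as.integer(levels[1]) + 1L
  likert_dataset(m, item_scale = meta$scale, item_key = meta$key,
                 levels = c(1L, L))
}

#' Write a Likert dataset to CSV
#'
#' Writes the rating matrix and the companion item-metadata sheet
#' (suffix `"_items"`); the pair round-trips through [load_inventory()].
#'
#' @param data A [likert_dataset()].
#' @param file Path of the ratings CSV to write.
#' @return `file`, invisibly.
#' @export
write_inventory_csv <- function(data, file) {
  stopifnot(inherits(data, "likert_dataset"))
  utils::write.csv(
    data.frame(respondent = seq_len(nrow(data$ratings)), data$ratings,
               check.names = FALSE),
    file, row.names = FALSE)
  meta_file <- sub("(\\.[Cc][Ss][Vv])?$", "_items\\1", file)
  if (identical(meta_file, file)) meta_file <- paste0(file, "_items")
  utils::write.csv(data$items, meta_file, row.names = FALSE)
  invisible(file)
}

#' Assemble a full simulation run configuration
#'
#' @param likert A [likert_config()] (or a list of its arguments).
#' @param n_sets Number of triplet item sets.
#' @param keying Keying mode for [balanced_design()].
#' @param jitter_sd Tie-breaking jitter SD.
#' @param n_reps Replications for the evaluation stage.
#' @param seed Master seed; component streams derive from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(likert = likert_config(), n_sets = 80,
                       keying = "positive_only", jitter_sd = 0.1,
                       n_reps = 10, seed = 1) {
  if (!inherits(likert, "likert_config"))
    likert <- do.call(likert_config, likert)
  keying <- match.arg(keying, c("positive_only", "mixed_random", "factual"))
  structure(
    list(likert = likert, n_sets = assert_count(n_sets, "n_sets"),
         keying = keying, jitter_sd = jitter_sd,
         n_reps = assert_count(n_reps, "n_reps"),
         seed = as.integer(seed)),
    class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' The file mirrors the [run_config()] fields, with `likert` holding the
#' [likert_config()] fields by name.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(run_config, cfg)
}

#' Execute a full simulation run and write its artifacts
#'
#' Runs one end-to-end pass (simulate, design, respond, score) under the
#' configured master seed, writes the design sheet, binary matrix and
#' both score sets as CSV, runs the replicated evaluation, and records a
#' manifest with the configuration and derived seeds.  Rerunning with the
#' same configuration reproduces the numeric outputs exactly.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 4L)
  cfg <- config$likert
  cfg$seed <- seeds[1]
  data <- simulate_likert(cfg)
  design <- suppressWarnings(
    balanced_design(data, config$n_sets, keying = config$keying,
                    seed = seeds[2]))
  binaries <- respond(data, design, jitter_sd = config$jitter_sd,
                      seed = seeds[3])
  recovered <- classical_score(binaries)
  original <- likert_scale_scores(data)
  write_inventory_csv(data, file.path(out_dir, "ratings.csv"))
  write_design_csv(design, file.path(out_dir, "design.csv"))
  write_binary_csv(binaries, file.path(out_dir, "binary.csv"))
  write_scores_csv(original, file.path(out_dir, "scores_likert.csv"))
  write_scores_csv(recovered, file.path(out_dir, "scores_mfc.csv"))
  evaluation <- run_replications(cfg, config$n_sets, keying = config$keying,
                                 jitter_sd = config$jitter_sd,
                                 n_reps = config$n_reps, seed = seeds[4])
  utils::write.csv(evaluation$replications,
                   file.path(out_dir, "evaluation_replications.csv"),
                   row.names = FALSE)
  utils::write.csv(evaluation$aggregate,
                   file.path(out_dir, "evaluation_aggregate.csv"),
                   row.names = FALSE)
  manifest <- list(
    package = "mfcsim",
    version = as.character(utils::packageVersion("mfcsim")),
    config = list(
      likert = config$likert[setdiff(names(config$likert), "seed")],
      n_sets = config$n_sets, keying = config$keying,
      jitter_sd = config$jitter_sd, n_reps = config$n_reps,
      seed = config$seed),
    derived_seeds = list(likert = seeds[1], design = seeds[2],
                         jitter = seeds[3], evaluation = seeds[4]),
    files = c("ratings.csv", "ratings_items.csv", "design.csv",
              "binary.csv", "binary_pairs.csv", "scores_likert.csv",
              "scores_mfc.csv", "evaluation_replications.csv",
              "evaluation_aggregate.csv"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
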