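write_toy_inventory <- function(dir, zero_based = FALSE) {
  ratings <- data.frame(
    respondent = 1:3,
    e1 = c(5L, 3L, 1L), e2 = c(4L, 3L, 2L),
    a1 = c(2L, 2L, 5L), a2 = c(1L, 3L, 4L),
    c1 = c(3L, 3L, 3L), c2 = c(5L, 1L, 2L))
  if (zero_based) ratings[, -1] <- ratings[, -1] - 1L
  meta <- data.frame(item_id = c("e1", "e2", "a1", "a2", "c1", "c2"),
                     scale = rep(c("E", "A", "C"), each = 2),
                     key = c(1L, -1L, 1L, 1L, -1L, 1L))
  rp <- file.path(dir, "ratings.csv")
  mp <- file.path(dir, "items.csv")
  write.csv(ratings, rp, row.names = FALSE)
  write.csv(meta, mp, row.names = FALSE)
  list(ratings = rp, meta = mp)
}

test_that("a toy inventory CSV loads with scales, keys and level range", {
  dir <- withr::local_tempdir()
  f <- write_toy_inventory(dir)
  d <- load_inventory(f$ratings, f$meta)
  expect_s3_class(d, "likert_dataset")
  expect_equal(n_scales(d), 3)
  expect_equal(dim(d$ratings), c(3L, 6L))
  expect_equal(d$items$key[d$items$item_id == "e2"], -1L)
})

test_that("0-based inventories are shifted to 1..L and scores are equivariant", {
  dir <- withr::local_tempdir()
  f1 <- write_toy_inventory(dir)
  d1 <- load_inventory(f1$ratings, f1$meta, levels = c(1, 5))
  f0dir <- withr::local_tempdir()
  f0 <- write_toy_inventory(f0dir, zero_based = TRUE)
  d0 <- load_inventory(f0$ratings, f0$meta, levels = c(0, 4))
  expect_identical(d0$ratings, d1$ratings)
  expect_identical(unclass(likert_scale_scores(d0)),
                   unclass(likert_scale_scores(d1)))
})

test_that("raw ratings are preserved: keys act only at scoring/response time", {
  dir <- withr::local_tempdir()
  f <- write_toy_inventory(dir)
  d <- load_inventory(f$ratings, f$meta)
  out <- file.path(dir, "export.csv")
  write_inventory_csv(d, out)
  back <- load_inventory(out, file.path(dir, "export_items.csv"),
                         levels = c(1, 5))
  expect_identical(back$ratings, d$ratings)
  expect_identical(back$items$key, d$items$key)
  # e2 is negatively keyed yet its stored ratings are the raw ones
  expect_equal(unname(back$ratings[, "e2"]), c(4L, 3L, 2L))
})

test_that("unmapped columns, bad ranges and missing rows are handled", {
  dir <- withr::local_tempdir()
  f <- write_toy_inventory(dir)
  meta <- read.csv(f$meta)
  meta <- meta[meta$item_id != "c2", ]
  mp2 <- file.path(dir, "partial.csv")
  write.csv(meta, mp2, row.names = FALSE)
  expect_error(load_inventory(f$ratings, mp2), "c2")
  expect_error(load_inventory(f$ratings, f$meta, levels = c(1, 4)),
               "outside declared range")
  ratings <- read.csv(f$ratings)
  ratings$e1[2] <- NA
  rp2 <- file.path(dir, "missing.csv")
  write.csv(ratings, rp2, row.names = FALSE)
  expect_message(d <- load_inventory(rp2, f$meta), "1 row")
  expect_equal(nrow(d$ratings), 2)
})

test_that("design and binary sheets round-trip through CSV", {
  dir <- withr::local_tempdir()
  d <- toy_dataset(n = 15, K = 3, ipp = 2, seed = 2)
  des <- balanced_design(d, 3, keying = "mixed_random", seed = 3)
  dp <- file.path(dir, "design.csv")
  write_design_csv(des, dp)
  back <- read.csv(dp)
  expect_equal(nrow(back), 9)
  expect_equal(back$item_id, des$item_id)
  b <- respond(d, des, seed = 4)
  bp <- file.path(dir, "binary.csv")
  write_binary_csv(b, bp)
  vals <- as.matrix(read.csv(bp))
  expect_equal(unname(vals), unname(b$values))
  prs <- read.csv(file.path(dir, "binary_pairs.csv"))
  expect_equal(prs$item_a, b$pairs$item_a)
})

test_that("run configs round-trip through JSON and YAML", {
  dir <- withr::local_tempdir()
  cfg <- run_config(likert = likert_config(n_respondents = 50, n_scales = 3,
                                           items_per_scale = 4),
                    n_sets = 5, keying = "mixed_random", n_reps = 2,
                    seed = 7)
  jp <- file.path(dir, "cfg.json")
  jsonlite::write_json(
    list(likert = list(n_respondents = 50, n_scales = 3,
                       items_per_scale = 4),
         n_sets = 5, keying = "mixed_random", n_reps = 2, seed = 7),
    jp, auto_unbox = TRUE)
  expect_equal(load_run_config(jp)$likert$n_respondents, 50)
  expect_equal(load_run_config(jp)$keying, "mixed_random")
  yp <- file.path(dir, "cfg.yaml")
  yaml::write_yaml(
    list(likert = list(n_respondents = 50, n_scales = 3,
                       items_per_scale = 4),
         n_sets = 5, keying = "mixed_random", n_reps = 2, seed = 7),
    yp)
  expect_equal(load_run_config(yp)$n_sets, cfg$n_sets)
  expect_error(run_config(keying = "sideways"), "arg")
})

test_that("the bundled synthetic inventory loads and scores end to end", {
  rp <- system.file("extdata", "synthetic_inventory_ratings.csv",
                    package = "mfcsim")
  mp <- system.file("extdata", "synthetic_inventory_items.csv",
                    package = "mfcsim")
  d <- load_inventory(rp, mp, levels = c(0, 4))
  expect_equal(n_scales(d), 3)
  expect_equal(d$levels, c(1L, 5L))
  des <- balanced_design(d, 6, keying = "factual", seed = 1)
  sc <- classical_score(respond(d, des, seed = 2))
  expect_equal(dim(unclass(sc)), c(40L, 3L))
})

test_that("the pipeline writes a reproducible artifact set", {
  cfg <- run_config(likert = likert_config(n_respondents = 40, n_scales = 3,
                                           items_per_scale = 4),
                    n_sets = 3, keying = "positive_only", n_reps = 2,
                    seed = 11)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- run_pipeline(cfg, d1)
  m2 <- run_pipeline(cfg, d2)
  expect_true(all(file.exists(file.path(d1, m1$files))))
  expect_identical(m1$derived_seeds, m2$derived_seeds)
  for (f in m1$files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})
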