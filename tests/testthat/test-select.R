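# Small dense fixtures keep the forests fast; the full-scale encoding is
# exercised in the recovery tests.
make_planted_matrix <- function(n = 300L, p = 50L, seed = 1L) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("A_", seq_len(p))))
  labels <- as.integer(x[, 1L] > 0)             # label driven by column 1
  list(x = x, labels = labels)
}

test_that("a column that determines the label tops the importance ranking", {
  fx <- make_planted_matrix()
  tab <- rank_features_by_importance(
    fx$x, fx$labels,
    selection_config(n_trees = 100L, repeats = 5L, seed = 4L)
  )
  expect_s3_class(tab, "importance_table")
  expect_equal(nrow(tab), 50L)
  expect_identical(tab$feature[1L], "A_1")
  expect_true(all(tab$mean_importance >= 0))
  expect_identical(tab$rank, seq_len(50L))
  expect_true(all(diff(tab$mean_importance) <= 0))   # sorted descending
})

test_that("zero-variance columns get zero importance", {
  fx <- make_planted_matrix(n = 150L, p = 10L, seed = 5L)
  fx$x[, 7L] <- 1
  tab <- rank_features_by_importance(
    fx$x, fx$labels, selection_config(n_trees = 50L, repeats = 2L, seed = 1L)
  )
  expect_equal(tab$mean_importance[tab$feature == "A_7"], 0)
})

test_that("importance ranking is deterministic given the config seed", {
  fx <- make_planted_matrix(n = 120L, p = 15L, seed = 6L)
  cfg <- selection_config(n_trees = 60L, repeats = 3L, seed = 99L)
  t1 <- rank_features_by_importance(fx$x, fx$labels, cfg)
  t2 <- rank_features_by_importance(fx$x, fx$labels, cfg)
  expect_identical(t1$mean_importance, t2$mean_importance)
  expect_identical(t1$feature, t2$feature)
})

test_that("single-class labels are rejected", {
  fx <- make_planted_matrix(n = 50L, p = 5L)
  expect_error(
    rank_features_by_importance(fx$x, rep(1L, 50L),
                                selection_config(n_trees = 10L, repeats = 1L)),
    "single-class"
  )
})

test_that("repeat-averaging reduces the variance of importance estimates", {
  fx <- make_planted_matrix(n = 120L, p = 20L, seed = 7L)
  imp_of <- function(repeats, seed) {
    tab <- rank_features_by_importance(
      fx$x, fx$labels,
      selection_config(n_trees = 40L, repeats = repeats, seed = seed)
    )
    tab$mean_importance[tab$feature == "A_2"]   # a non-signal feature
  }
  seeds <- seq(101L, 115L)
  sd_single <- sd(vapply(seeds, function(s) imp_of(1L, s), numeric(1L)))
  sd_avg <- sd(vapply(seeds, function(s) imp_of(5L, s * 10L), numeric(1L)))
  expect_lt(sd_avg, sd_single)
})

test_that("threshold selection is strict and monotone (nested)", {
  tab <- data.frame(
    feature = letters[1:5],
    mean_importance = c(5, 3, 2, 2, 0.5),
    rank = 1:5
  )
  class(tab) <- c("importance_table", "data.frame")
  expect_identical(select_by_threshold(tab, 10), character(0))
  expect_identical(select_by_threshold(tab, 0), letters[1:5])
  expect_identical(select_by_threshold(tab, 2), c("a", "b"))  # strict >
  thresholds <- c(0, 0.5, 1, 2, 3, 5, 6)
  sets <- lapply(thresholds, select_by_threshold, table = tab)
  for (i in seq_along(sets)[-1L]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1L]]))
  }
})

test_that("the ANOVA filter keeps significant features in one pass", {
  set.seed(8)
  n <- 200L
  x <- cbind(sig = rnorm(n), noise = rnorm(n))
  scores <- 2 * x[, "sig"] + rnorm(n, sd = 0.5)
  flt <- anova_redundancy_filter(x, scores, alpha = 0.05)
  expect_true("sig" %in% flt$retained)
  expect_named(flt$p_values, c("sig", "noise"), ignore.order = TRUE)

  # alpha = 1 retains every estimable feature
  flt1 <- anova_redundancy_filter(x, scores, alpha = 1)
  expect_setequal(flt1$retained, c("sig", "noise"))

  # an exact duplicate column is aliased and reported, not fatal
  xd <- cbind(x, sig_copy = x[, "sig"])
  fltd <- anova_redundancy_filter(xd, scores, alpha = 0.05)
  expect_identical(fltd$aliased, "sig_copy")
  expect_false("sig_copy" %in% fltd$retained)
})

test_that("a pure-noise feature is dropped in at least 90% of runs", {
  drops <- vapply(1:100, function(s) {
    set.seed(s)
    n <- 120L
    x <- cbind(sig = rnorm(n), noise = rnorm(n))
    scores <- 1.5 * x[, "sig"] + rnorm(n, sd = 0.5)
    flt <- anova_redundancy_filter(x, scores, alpha = 0.05)
    !"noise" %in% flt$retained
  }, logical(1L))
  expect_gte(mean(drops), 0.9)
})

test_that("category summary normalizes the 12 encoding categories", {
  one <- data.frame(feature = "G_24", mean_importance = 3.2, rank = 1L)
  class(one) <- c("importance_table", "data.frame")
  s1 <- category_importance_summary(one)
  expect_equal(nrow(s1), 12L)
  expect_equal(s1$normalized_importance[s1$category == "1stPSF"], 1)
  expect_true(all(s1$normalized_importance[s1$category != "1stPSF"] == 0))

  # uniform importance: category sums proportional to category sizes
  nm <- feature_names()
  unif <- data.frame(feature = nm, mean_importance = 1,
                     rank = seq_along(nm))
  class(unif) <- c("importance_table", "data.frame")
  su <- category_importance_summary(unif)
  expect_equal(su$normalized_importance[su$category == "4thPSF"], 1)
  expect_equal(su$normalized_importance[su$category == "1stPSF"],
               120 / 6912)
  expect_equal(su$normalized_importance[su$category == "MFE"], 1 / 6912)

  bad <- data.frame(feature = "banana", mean_importance = 1, rank = 1L)
  class(bad) <- c("importance_table", "data.frame")
  expect_error(category_importance_summary(bad), "unrecognized")
})

test_that("importance tables serialize as CSV plus manifest", {
  fx <- make_planted_matrix(n = 80L, p = 8L, seed = 9L)
  cfg <- selection_config(n_trees = 30L, repeats = 2L, seed = 5L)
  tab <- rank_features_by_importance(fx$x, fx$labels, cfg)
  path <- tempfile(fileext = ".csv")
  write_importance_table(tab, path)
  back <- utils::read.csv(path)
  expect_identical(back$feature, tab$feature)
  expect_equal(back$mean_importance, tab$mean_importance, tolerance = 1e-12)
  manifest <- jsonlite::read_json(paste0(path, ".manifest.json"))
  expect_equal(manifest$n_trees, 30L)
})
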