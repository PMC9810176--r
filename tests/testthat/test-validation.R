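test_that("out-of-sample metrics match hand computation and invariances", {
  m <- oos_metrics(c(0.5, 0.7), c(0.4, 0.8))
  expect_equal(m[["rmse"]], 0.1)
  expect_equal(m[["mae"]], 0.1)
  expect_equal(m[["prop_over"]], 0.5)
  expect_equal(m[["pearson"]], 1.0)

  a <- c(0.2, 0.4, 0.6, 0.8)
  expect_equal(oos_metrics(a, a),
               c(rmse = 0, pearson = 1, prop_over = 0, mae = 0))
  shift <- oos_metrics(a + 0.05, a)
  expect_equal(shift[["prop_over"]], 1.0)
  expect_equal(shift[["mae"]], 0.05)

  ## permutation invariance of paired metrics
  set.seed(3)
  p <- runif(20); act <- runif(20)
  perm <- sample(20)
  expect_equal(oos_metrics(p, act), oos_metrics(p[perm], act[perm]))

  ## constant actual: correlation undefined, other metrics intact
  m2 <- oos_metrics(c(0.3, 0.6), c(0.5, 0.5))
  expect_true(is.na(m2[["pearson"]]))
  expect_false(anyNA(m2[c("rmse", "mae", "prop_over")]))

  ## rmse always at least mae
  expect_gte(oos_metrics(p, act)[["rmse"]], oos_metrics(p, act)[["mae"]])
})

make_groups_frame <- function(regions, habitats) {
  n <- length(regions)
  g <- data.frame(group_id = sprintf("AG%02d", seq_len(n)),
                  state = "NE", region = regions, habitat = habitats,
                  n_raptor = 10, n_gamebird = 10, seasons = "fall",
                  sites = "s", studies = "s", stringsAsFactors = FALSE)
  class(g) <- c("cpt_groups", "data.frame")
  g
}

test_that("stratified splits respect the singleton rule and form a partition", {
  ## cell A (R1/cropland) is a singleton; cell B (R2/grassland) has 3 groups
  g <- make_groups_frame(c("R1", "R2", "R2", "R2"),
                         c("cropland", rep("grassland", 3)))
  splits <- stratified_splits(g, n_sets = 20, train_target = 0.5, seed = 9)
  for (sp in splits) {
    expect_true("AG01" %in% sp$train)                 # singleton always trains
    expect_setequal(c(sp$train, sp$holdout), g$group_id)
    expect_length(intersect(sp$train, sp$holdout), 0)
    expect_gte(length(intersect(sp$train, g$group_id[-1])), 1)
    expect_gte(length(sp$holdout), 1)
  }
  ## the hold-out composition varies across splits
  holds <- vapply(splits, function(sp) paste(sp$holdout, collapse = ","), "")
  expect_gt(length(unique(holds)), 1)

  ## child seeds: the first splits are unchanged when more are requested
  s3 <- stratified_splits(g, n_sets = 3, seed = 9, train_target = 0.5)
  s5 <- stratified_splits(g, n_sets = 5, seed = 9, train_target = 0.5)
  expect_equal(s3, s5[1:3])

  ## all-singleton configuration cannot be validated
  g_single <- make_groups_frame(c("R1", "R2"), c("cropland", "grassland"))
  expect_error(stratified_splits(g_single), "singleton")
})

test_that("training fractions track the target when the cells allow it", {
  g <- make_groups_frame(rep(c("R1", "R2"), each = 10),
                         rep("cropland", 20))
  splits <- stratified_splits(g, n_sets = 10, train_target = 0.52, seed = 4)
  fracs <- vapply(splits, function(sp) length(sp$train) / 20, numeric(1))
  expect_true(all(abs(fracs - 0.52) <= 0.05))
})

test_that("cross-validation refits on training groups and scores hold-outs", {
  ## low-noise, well-specified generator: small group dispersions so that
  ## fixed-effects-only hold-out prediction can be sharp
  cfg <- meta_sim_config(n_groups = 30, n_per_group = 40,
                         regions = c("R1", "R2"), habitats = "cropland",
                         seasons = "fall",
                         scaling_truth = list(slope = 4, re_sd_intercept = 0.1,
                                              re_sd_slope = 0.4,
                                              resid_sd = 0.1,
                                              fixed_offsets = list()),
                         seed = 15)
  sim <- simulate_meta_dataset(cfg)
  gr <- build_analysis_groups(summarize_studies(sim$trials))
  s1 <- stage1_pairs(gr, sim$trials, B = 60, seed = 4)
  cv <- suppressMessages(
    cross_validate(s1, gr, fixed_terms = character(0), n_sets = 4, seed = 11))
  expect_equal(nrow(cv$metrics), 4)
  expect_named(cv$metrics, c("split", "rmse", "pearson", "prop_over", "mae",
                             "n_holdout"))
  ok <- !is.na(cv$metrics$rmse)
  expect_gt(sum(ok), 0)
  ## a well-specified low-noise generator keeps hold-out error small
  expect_lt(median(cv$metrics$rmse[ok]), 0.1)
  expect_true(all(cv$metrics$rmse[ok] >= cv$metrics$mae[ok] - 1e-12))
  ## hold-out groups never enter their split's training set
  for (s in seq_along(cv$splits)) {
    expect_length(intersect(cv$splits[[s]]$train, cv$splits[[s]]$holdout), 0)
  }
})
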