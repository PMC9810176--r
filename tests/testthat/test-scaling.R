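test_that("logit and inverse logit round-trip and clip at the boundary", {
  p <- c(1e-6, 0.01, 0.31, 0.5, 0.9, 1 - 1e-6)
  expect_equal(inv_logit(logit(p)), p, tolerance = 1e-12)
  ## out-of-range values are clipped, keeping the transform finite
  expect_true(is.finite(logit(0)))
  expect_true(is.finite(logit(1)))
  expect_equal(logit(0), logit(1e-6))
})

test_that("analysis groups aggregate by site, then state+habitat, never across states", {
  mk <- function(study, site, state, nr, ng, habitat = "cropland",
                 region = "R3") {
    data.frame(study_id = study, site_id = site, state = state,
               region = region, habitat = habitat, n_raptor = nr,
               n_gamebird = ng, seasons = "fall", stringsAsFactors = FALSE)
  }
  ## two years at one site combine to reach the threshold
  st <- rbind(mk("y1", "siteA", "IA", 5, 8), mk("y2", "siteA", "IA", 6, 8))
  g <- build_analysis_groups(st)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_raptor, 11)
  expect_setequal(strsplit(g$studies, ",")[[1]], c("y1", "y2"))

  ## same state and habitat: two sites merge
  st2 <- rbind(mk("a", "s1", "NE", 5, 9), mk("b", "s2", "NE", 5, 9))
  g2 <- build_analysis_groups(st2)
  expect_equal(nrow(g2), 1)
  expect_equal(g2$n_raptor, 10)

  ## different states never merge; both fall short and are excluded
  st3 <- rbind(mk("a", "s1", "NE", 6, 9), mk("b", "s2", "KS", 6, 9))
  expect_error(build_analysis_groups(st3), "no analysis group")

  ## one state short, the other sufficient: only the sufficient one remains
  st4 <- rbind(mk("a", "s1", "NE", 6, 9), mk("b", "s2", "KS", 9, 9))
  g4 <- build_analysis_groups(st4)
  expect_equal(nrow(g4), 1)
  expect_equal(g4$state, "KS")
  exc <- attr(g4, "excluded")
  expect_equal(nrow(exc), 1)
  expect_match(exc$reason, "min_n")

  ## a trailing remainder folds into the last closed group of its stratum
  st5 <- rbind(mk("a", "s1", "NE", 9, 9), mk("b", "s2", "NE", 3, 3))
  g5 <- build_analysis_groups(st5)
  expect_equal(nrow(g5), 1)
  expect_equal(g5$n_raptor, 12)
})

test_that("stage-1 pairing yields B replicates per group-season-interval, paired by index", {
  cfg <- meta_sim_config(n_groups = 2, n_per_group = 15, seed = 3)
  sim <- simulate_meta_dataset(cfg)
  gr <- build_analysis_groups(summarize_studies(sim$trials))
  s1 <- stage1_pairs(gr, sim$trials, intervals = c(14, 30, 60, 90), B = 50,
                     seed = 2)
  n_cells <- nrow(unique(s1$draws[, c("group_id", "season")]))
  expect_equal(nrow(s1$draws), 50 * n_cells * 4)
  ## every (group, season, interval) has exactly replicates 1..B
  by_cell <- split(s1$draws$replicate,
                   paste(s1$draws$group_id, s1$draws$season,
                         s1$draws$interval))
  expect_true(all(vapply(by_cell, function(r) identical(sort(r), 1:50),
                         logical(1))))
  expect_true(all(s1$draws$gamebird_r > 0 & s1$draws$gamebird_r <= 1))
  expect_true(all(s1$points$raptor_r > 0 & s1$points$raptor_r <= 1))
})

test_that("predict_raptor applies the linear predictor, BLUPs, and level checks", {
  ## all coefficients zero: inverse-logit(0) = 0.5 for any input
  null_model <- scaling_model(intercept = 0, slope = 0,
                              region = c(R2 = 0), habitat = c(grassland = 0))
  expect_equal(predict_raptor(null_model, 0.31), 0.5)
  expect_equal(predict_raptor(null_model, 0.9, season = "winter",
                              region = "R2", habitat = "grassland"), 0.5)

  m <- reference_scaling_model()
  ## a known group with zero BLUPs equals the new-group prediction
  m2 <- m
  m2$blups <- data.frame(group_id = "AG01", intercept = 0, slope = 0)
  expect_equal(predict_raptor(m2, 0.4, group_id = "AG01"),
               predict_raptor(m, 0.4))
  ## nonzero BLUPs shift the prediction
  m2$blups$intercept <- 0.5
  expect_gt(predict_raptor(m2, 0.4, group_id = "AG01"),
            predict_raptor(m, 0.4))
  ## prediction is strictly increasing in game bird persistence
  r <- vapply(seq(0.05, 0.95, by = 0.1), function(g)
    predict_raptor(m, g), numeric(1))
  expect_true(all(diff(r) > 0))
  ## unfitted level is refused by name
  expect_error(predict_raptor(m, 0.3, region = "R5"), "R5")
})

test_that("fit_scaling recovers a known scaling relation end to end", {
  ## moderate design so the test stays fast; the acceptance suite runs the
  ## full 30-group configuration
  cfg <- meta_sim_config(n_groups = 16, n_per_group = 25,
                         regions = c("R1", "R2"), habitats = "cropland",
                         seasons = "fall",
                         scaling_truth = list(slope = 4, re_sd_intercept = 0.4,
                                              re_sd_slope = 1.5,
                                              resid_sd = 0.25,
                                              fixed_offsets = list()),
                         seed = 61)
  sim <- simulate_meta_dataset(cfg)
  gr <- build_analysis_groups(summarize_studies(sim$trials))
  s1 <- stage1_pairs(gr, sim$trials, B = 100, seed = 6)
  m <- suppressMessages(fit_scaling(s1))
  se <- sqrt(m$vcov_fixed["gamebird_r", "gamebird_r"])
  expect_lt(abs(m$slope - 4), 3 * se)
  expect_gt(m$slope, 0)
  expect_equal(m$n_groups, length(unique(s1$draws$group_id)))
  ## ICC is reported with its defining formula
  expect_equal(m$icc,
               m$random[["sd_intercept"]]^2 /
                 (m$random[["sd_intercept"]]^2 + m$resid_sd^2))
  expect_match(m$icc_formula, "sd_intercept")
})

test_that("the reference scaling model carries the published structure", {
  m <- reference_scaling_model()
  expect_equal(unname(m$baselines),
               c("fall", "R1", "cropland"))
  ## interval prediction needs a coefficient covariance
  expect_error(predict_raptor(m, 0.3, interval = TRUE), "covariance")
})
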