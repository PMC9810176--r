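test_that("survival functions obey boundary conditions and closed forms", {
  for (fam in c("exponential", "weibull", "loglogistic", "lognormal")) {
    expect_equal(surv_prob(fam, 0, log(30), 0.7), 1)
    s <- surv_prob(fam, c(1, 5, 20, 80, 400), log(30), 0.7)
    expect_true(all(diff(s) < 0))
    expect_lt(surv_prob(fam, 1e6, log(30), 0.7), 1e-3)
  }
  expect_equal(surv_prob("exponential", 30, log(30)), exp(-1))
  ## weibull with sigma = 1 is the exponential
  tt <- c(0.5, 3, 17, 56, 200)
  expect_equal(surv_prob("weibull", tt, log(12), 1),
               surv_prob("exponential", tt, log(12)))
  expect_error(surv_prob("weibull", -1, log(30), 1), "negative")
})

test_that("the interval-censored negative log-likelihood matches closed forms", {
  spec <- model_spec("exponential")
  obs1 <- data.frame(left = 0, right = Inf)
  expect_equal(neg_loglik(spec, log(30), obs1), 0)

  obs2 <- data.frame(left = 56, right = Inf)
  expect_equal(neg_loglik(spec, log(30), obs2), 56 / 30, tolerance = 1e-9)

  obs3 <- data.frame(left = 7, right = 14)
  expect_equal(neg_loglik(spec, log(30), obs3),
               -log(exp(-7 / 30) - exp(-14 / 30)), tolerance = 1e-9)

  ## zero-probability interval gives Inf, not an error
  spec_w <- model_spec("weibull")
  expect_equal(neg_loglik(spec_w, c(log(1e-8), log(1e-6)),
                          data.frame(left = 50, right = 51)), Inf)
})

test_that("AICc has the stated form and boundary behaviour", {
  expect_equal(aicc(-50, 2, 10), 105.7142857, tolerance = 1e-7)
  expect_equal(aicc(-50, 2, 1e9), 104, tolerance = 1e-6)  # AIC limit
  expect_equal(aicc(-50, 2, 3), Inf)                       # n = k + 1
})

test_that("select_model prefers parsimony within 2 AICc, order-invariantly", {
  f <- function(aicc, k, tag) list(aicc = aicc, k = k, spec = tag)
  fits <- list(f(100.0, 3, "a"), f(101.5, 2, "b"), f(103.0, 1, "c"))
  expect_equal(select_model(fits)$spec, "b")
  expect_equal(select_model(fits[2])$spec, "b")            # singleton
  ## k tie broken by lower AICc
  fits2 <- list(f(100.0, 2, "a"), f(101.9, 2, "b"))
  expect_equal(select_model(fits2)$spec, "a")
  ## order invariance over all permutations of a 4-candidate list
  fits3 <- list(f(100.0, 4, "a"), f(100.5, 2, "b"), f(101.8, 2, "c"),
                f(105, 1, "d"))
  perms <- list(c(1,2,3,4), c(4,3,2,1), c(2,4,1,3), c(3,1,4,2))
  picks <- vapply(perms, function(p) select_model(fits3[p])$spec, "")
  expect_true(all(picks == "b"))
  expect_error(select_model(list()), "empty")
})

test_that("median persistence matches the closed forms per family", {
  expect_equal(median_time(known_fit("exponential", log(30))), 30 * log(2),
               tolerance = 1e-9)
  expect_equal(median_time(known_fit("weibull", log(30), 0.5)),
               30 * log(2)^0.5, tolerance = 1e-9)
  expect_equal(median_time(known_fit("loglogistic", log(30), 1.7)), 30)
  expect_equal(median_time(known_fit("lognormal", log(30), 0.4)), 30)
  ## the closed form is the root of S(t) - 0.5
  for (fam in c("exponential", "weibull", "loglogistic", "lognormal")) {
    fit <- known_fit(fam, log(22), 0.8)
    med <- median_time(fit)
    root <- uniroot(function(t) surv_prob(fam, t, log(22),
                                          if (fam == "exponential") 1 else 0.8) - 0.5,
                    c(1e-6, 1e4), tol = 1e-10)$root
    expect_equal(med, root, tolerance = 1e-6)
  }
})

test_that("average persistence agrees with the exponential closed form and is monotone", {
  fit <- known_fit("exponential", log(30))
  expect_equal(avg_persistence(fit, t = 30), 1 - exp(-1), tolerance = 1e-8)
  ## r-hat(t) -> 1 as t -> 0+
  expect_equal(avg_persistence(fit, t = 1e-6), 1, tolerance = 1e-5)
  ## monotone non-increasing in the interval length, any family
  for (fam in c("weibull", "loglogistic", "lognormal")) {
    r <- avg_persistence(known_fit(fam, log(25), 0.9), t = c(14, 30, 60, 90))
    expect_true(all(diff(r) < 0))
  }
  expect_error(avg_persistence(fit, t = 0), "positive")
})

test_that("fitting narrow-interval exponential data recovers the sample mean", {
  obs <- data.frame(left = c(10, 20, 30) - 0.01, right = c(10, 20, 30))
  f <- fit_icsurv(model_spec("exponential"), obs, n_starts = 3)
  expect_lt(abs(exp(f$beta[[1]]) - 20), 0.5)
})

test_that("fit matches an independent uncensored survival MLE on exact-time data", {
  skip_if_not_installed("survival")
  set.seed(77)
  n <- 300
  grp <- rep(c("fall", "summer"), each = n / 2)
  mu <- ifelse(grp == "fall", log(8), log(20))
  x <- exp(mu + 0.6 * log(rexp(n)))
  obs <- data.frame(left = pmax(x - 1e-5, 0), right = x, season = grp)
  f <- fit_icsurv(model_spec("weibull", location = "season"), obs, n_starts = 3)
  sr <- survival::survreg(survival::Surv(x) ~ grp, dist = "weibull")
  expect_lt(max(abs(f$beta - coef(sr))), 1e-3)
  expect_lt(abs(exp(f$gamma[[1]]) - sr$scale), 1e-3)
})

test_that("degenerate inputs refuse to fit", {
  obs_cens <- data.frame(left = rep(56, 20), right = rep(Inf, 20))
  expect_error(fit_icsurv(model_spec("exponential"), obs_cens), "censored")
  obs_small <- data.frame(left = c(1, 2), right = c(2, 3))
  expect_error(fit_icsurv(model_spec("weibull"), obs_small), "too few")
})

test_that("bootstrap draws respect count, degenerate covariance, and the log-scale link", {
  cell <- cell_spec("weibull", log(15), 0.8, n = 150)
  f <- fit_icsurv(model_spec("weibull"),
                  make_intervals(simulate_cell_trials(cell, seed = 2)),
                  n_starts = 2)
  d <- bootstrap_draws(f, 250, seed = 5)
  expect_equal(dim(d), c(250, 2))
  ## every draw yields sigma > 0 through the log link
  expect_true(all(exp(d[, 2]) > 0))
  ## zero covariance: all draws equal the point estimate
  f0 <- f; f0$vcov <- matrix(0, 2, 2, dimnames = dimnames(f$vcov))
  d0 <- bootstrap_draws(f0, 10, seed = 1)
  expect_equal(unname(d0), matrix(rep(unname(f$coef), each = 10), 10))
  ## non-PSD covariance is refused
  fbad <- f; fbad$vcov <- matrix(c(1, 2, 2, 1), 2, 2,
                                 dimnames = dimnames(f$vcov))
  expect_error(bootstrap_draws(fbad, 10), "positive semidefinite")
})

test_that("percentile CIs interpolate order statistics", {
  expect_equal(percentile_ci(1:10, level = 0.8), c(lo = 1.9, hi = 9.1))
  expect_equal(percentile_ci(rep(3.3, 5)), c(lo = 3.3, hi = 3.3))
  sym <- c(-4, -2, -1, 0, 1, 2, 4)
  ci <- percentile_ci(sym, 0.9)
  expect_equal(ci[["lo"]], -ci[["hi"]])
  expect_error(percentile_ci(1), "2 values")
})

test_that("persistence_estimate brackets the point estimates with its CIs", {
  cell <- cell_spec("lognormal", log(18), 0.7, n = 200)
  f <- fit_icsurv(model_spec("lognormal"),
                  make_intervals(simulate_cell_trials(cell, seed = 8)),
                  n_starts = 2)
  est <- persistence_estimate(f, intervals = c(30, 60, 90), n_boot = 300,
                              seed = 3)
  expect_true(est$median$lo <= est$median$estimate &&
                est$median$estimate <= est$median$hi)
  expect_true(all(est$r_hat$lo <= est$r_hat$estimate &
                    est$r_hat$estimate <= est$r_hat$hi))
  expect_true(all(diff(est$r_hat$estimate) < 0))
  expect_true(all(est$r_hat$estimate > 0 & est$r_hat$estimate <= 1))
})
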