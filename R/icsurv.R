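## Interval-censored location-scale survival core.
##
## All four families are log-location-scale: T = exp(mu + sigma * W) with W
## standard normal (lognormal), logistic (log-logistic) or Gumbel-minimum
## (Weibull); the exponential is the Weibull with sigma fixed at 1.
## Covariates enter mu linearly under treatment coding and log(sigma)
## linearly, so every parameter vector yields a valid sigma > 0.

surv_families <- function() c("exponential", "weibull", "loglogistic", "lognormal")

canonical_levels <- function() {
  list(region = region_levels(), habitat = habitat_levels(),
       season = season_levels(), bird_type = bird_type_levels())
}

#' Specify a candidate survival model
#'
#' @param family one of `"exponential"`, `"weibull"`, `"loglogistic"`,
#'   `"lognormal"`.
#' @param location,scale character vectors of categorical covariate terms for
#'   the location and log-scale linear predictors. Two-way interactions are
#'   written `"a:b"` and require both main effects in the same term list.
#'   The exponential family admits no scale terms (sigma is fixed at 1).
#' @return a `cpt_spec` object.
#' @export
model_spec <- function(family, location = character(0), scale = character(0)) {
  family <- match.arg(family, surv_families())
  check_terms <- function(terms, what) {
    inter <- terms[grepl(":", terms, fixed = TRUE)]
    for (tm in inter) {
      mains <- strsplit(tm, ":", fixed = TRUE)[[1]]
      if (!all(mains %in% terms)) {
        stop("interaction ", tm, " in ", what,
             " terms requires both main effects", call. = FALSE)
      }
    }
  }
  check_terms(location, "location")
  check_terms(scale, "scale")
  if (family == "exponential" && length(scale)) {
    stop("exponential family has a fixed scale; no scale terms allowed",
         call. = FALSE)
  }
  structure(list(family = family, location = location, scale = scale),
            class = "cpt_spec")
}

#' @export
print.cpt_spec <- function(x, ...) {
  fmt <- function(tm) if (length(tm)) paste(tm, collapse = " + ") else "1"
  cat(x$family, ": location ~ ", fmt(x$location),
      ", log-scale ~ ", fmt(x$scale), "\n", sep = "")
  invisible(x)
}

spec_vars <- function(spec) {
  unique(unlist(strsplit(c(spec$location, spec$scale), ":", fixed = TRUE)))
}

## Restrict each factor to its observed levels, in canonical order, so
## treatment coding stays full rank on unbalanced meta-data and the baseline
## is always the first canonical level present (fall / R1 / cropland / raptor).
observed_xlevels <- function(data, vars) {
  canon <- canonical_levels()
  out <- list()
  for (v in vars) {
    if (!v %in% names(data)) stop("covariate not in data: ", v, call. = FALSE)
    lev <- canon[[v]]
    if (is.null(lev)) lev <- sort(unique(as.character(data[[v]])))
    out[[v]] <- intersect(lev, unique(as.character(data[[v]])))
  }
  out
}

design_matrix <- function(terms, data, xlevels) {
  if (!length(terms)) {
    return(matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)")))
  }
  f <- stats::reformulate(terms)
  vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  df <- data[, vars, drop = FALSE]
  for (v in vars) {
    lv <- xlevels[[v]]
    val <- as.character(df[[v]])
    bad <- setdiff(unique(val), lv)
    if (length(bad)) {
      stop("level(s) not among fitted levels for ", v, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    df[[v]] <- factor(val, levels = lv)
  }
  stats::model.matrix(f, df)
}

## Survival function of each family; vectorized over t, S(0) = 1,
## S(Inf) = 0 by construction.
surv_prob <- function(family, t, mu, sigma = 1) {
  if (any(t < 0)) stop("negative time in survival function", call. = FALSE)
  z <- (t / exp(mu))^(1 / sigma)
  switch(family,
    exponential = exp(-(t / exp(mu))),
    weibull = exp(-z),
    loglogistic = 1 / (1 + z),
    lognormal = {
      s <- ifelse(t == 0, 1, 1 - stats::pnorm((log(pmax(t, 1e-300)) - mu) / sigma))
      s
    },
    stop("unknown family: ", family, call. = FALSE))
}

split_params <- function(params, p_loc, p_scale) {
  list(beta = params[seq_len(p_loc)],
       gamma = if (p_scale) params[p_loc + seq_len(p_scale)] else numeric(0))
}

nll_core <- function(family, params, X, Z, left, right) {
  p_loc <- ncol(X)
  p_scale <- if (is.null(Z)) 0L else ncol(Z)
  pp <- split_params(params, p_loc, p_scale)
  mu <- drop(X %*% pp$beta)
  sigma <- if (p_scale) exp(drop(Z %*% pp$gamma)) else rep(1, nrow(X))
  sL <- surv_prob(family, left, mu, sigma)
  fin <- is.finite(right)
  sR <- numeric(length(right))
  sR[fin] <- surv_prob(family, right[fin], mu[fin], sigma[fin])
  pr <- sL - sR
  if (any(pr <= 0) || any(!is.finite(pr))) return(Inf)
  -sum(log(pr))
}

#' Negative log-likelihood of an interval-censored sample
#'
#' Computes `sum_i -log(S(L_i) - S(R_i))` with `S(Inf) = 0`, the likelihood
#' of half-open removal intervals under a location-scale survival model.
#' Returns `Inf` (not an error) when any interval has zero probability mass,
#' so optimizers can back away from degenerate parameter values.
#'
#' @param spec a [model_spec()].
#' @param params coefficient vector, location block then log-scale block.
#' @param obs a `cpt_obs` data frame (columns `left`, `right`, covariates).
#' @return a scalar negative log-likelihood.
#' @export
neg_loglik <- function(spec, params, obs) {
  stopifnot(inherits(spec, "cpt_spec"))
  if (any(obs$left < 0) || any(obs$right <= obs$left))
    stop("invalid intervals: need 0 <= left < right", call. = FALSE)
  xlev <- observed_xlevels(obs, spec_vars(spec))
  X <- design_matrix(spec$location, obs, xlev)
  Z <- if (spec$family == "exponential") NULL else
    design_matrix(spec$scale, obs, xlev)
  k <- ncol(X) + if (is.null(Z)) 0L else ncol(Z)
  if (length(params) != k)
    stop("params has length ", length(params), "; expected ", k, call. = FALSE)
  nll_core(spec$family, params, X, Z, obs$left, obs$right)
}

fit_error <- function(msg) {
  stop(structure(class = c("cpt_fit_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

moment_start <- function(obs, p_loc, p_scale) {
  fin <- is.finite(obs$right)
  mid <- ifelse(fin, (obs$left + obs$right) / 2, obs$left * 1.5 + 1)
  lmid <- log(pmax(mid, 0.01))
  mu0 <- mean(lmid)
  s0 <- stats::sd(lmid)
  if (!is.finite(s0) || s0 < 0.05) s0 <- 0.8
  start <- numeric(p_loc + p_scale)
  start[1] <- mu0
  if (p_scale) start[p_loc + 1] <- log(s0)
  start
}

#' Fit an interval-censored location-scale survival model
#'
#' Maximizes the interval-censored likelihood by multi-start quasi-Newton
#' (BFGS) optimization: a method-of-moments start from interval midpoints
#' plus jittered restarts. The coefficient covariance is the inverse observed
#' information at the optimum, and the fit carries its AICc (with n the
#' carcass count).
#'
#' @param spec a [model_spec()].
#' @param obs a `cpt_obs` data frame (from [make_intervals()] or simulation).
#' @param n_starts number of optimizer starts (first is moment-based).
#' @param seed integer seed for the start jitter.
#' @return a `cpt_fit` object with elements `spec`, `beta`, `gamma`, `coef`,
#'   `vcov`, `loglik`, `k`, `n`, `aicc`, `xlevels`.
#' @export
fit_icsurv <- function(spec, obs, n_starts = 5, seed = 1) {
  stopifnot(inherits(spec, "cpt_spec"), is.data.frame(obs))
  if (any(obs$left < 0) || any(obs$right <= obs$left))
    fit_error("invalid intervals: need 0 <= left < right")
  if (all(!is.finite(obs$right)))
    fit_error("all observations right-censored; likelihood maximized at boundary")

  xlev <- observed_xlevels(obs, spec_vars(spec))
  X <- design_matrix(spec$location, obs, xlev)
  Z <- if (spec$family == "exponential") NULL else
    design_matrix(spec$scale, obs, xlev)
  if (any(colSums(abs(X)) == 0) || (!is.null(Z) && any(colSums(abs(Z)) == 0)))
    fit_error("design matrix has an all-zero column (unsampled level combination)")
  p_loc <- ncol(X)
  p_scale <- if (is.null(Z)) 0L else ncol(Z)
  k <- p_loc + p_scale
  n <- nrow(obs)
  if (n < k + 2) fit_error(paste0("too few observations (n = ", n,
                                  ") for k = ", k, " parameters"))

  obj <- function(par) {
    v <- nll_core(spec$family, par, X, Z, obs$left, obs$right)
    if (!is.finite(v)) 1e10 else v
  }
  start0 <- moment_start(obs, p_loc, p_scale)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  starts <- list(start0)
  if (n_starts > 1) {
    for (i in seq_len(n_starts - 1)) {
      starts[[i + 1]] <- start0 + stats::rnorm(k, 0, 0.5)
    }
  }
  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      stats::optim(st, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best) || best$value >= 1e10)
    fit_error("optimization failed from all starts")

  H <- tryCatch(
    stats::optimHess(best$par, obj),
    error = function(e) NULL)
  vcov <- if (is.null(H)) NULL else tryCatch(solve(H), error = function(e) NULL)
  if (is.null(vcov) || any(!is.finite(vcov)) || any(diag(vcov) <= 0))
    fit_error("singular observed information; fit is boundary/degenerate")

  coef_names <- c(paste0("loc:", colnames(X)),
                  if (p_scale) paste0("logscale:", colnames(Z)))
  est <- best$par
  names(est) <- coef_names
  dimnames(vcov) <- list(coef_names, coef_names)
  structure(list(
    spec = spec,
    beta = est[seq_len(p_loc)],
    gamma = if (p_scale) est[p_loc + seq_len(p_scale)] else numeric(0),
    coef = est,
    vcov = vcov,
    loglik = -best$value,
    k = k, n = n,
    aicc = aicc(-best$value, k, n),
    p_loc = p_loc, p_scale = p_scale,
    xlevels = xlev,
    convergence = best$convergence
  ), class = "cpt_fit")
}

#' @export
print.cpt_fit <- function(x, ...) {
  cat("Interval-censored survival fit (", x$spec$family, ")\n", sep = "")
  cat("  n = ", x$n, ", k = ", x$k, ", logLik = ",
      format(x$loglik, digits = 6), ", AICc = ",
      format(x$aicc, digits = 6), "\n", sep = "")
  print(round(x$coef, 4))
  invisible(x)
}

#' Small-sample-corrected Akaike information criterion
#'
#' `-2 logLik + 2k + 2k(k+1)/(n-k-1)`; returns `Inf` when `n <= k + 1`
#' (the model is inadmissible at that sample size).
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations (carcasses).
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) return(Inf)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Parsimony-first model selection within 2 AICc of the best
#'
#' Among candidates whose AICc is within 2 points of the minimum, returns the
#' one with the fewest parameters; ties on parameter count break to the lower
#' AICc. The result is invariant to the order of the input list.
#'
#' @param fits a nonempty list of objects carrying `$aicc` and `$k`.
#' @return the selected element of `fits`.
#' @export
select_model <- function(fits) {
  if (!length(fits)) stop("empty candidate list", call. = FALSE)
  aiccs <- vapply(fits, function(f) as.numeric(f$aicc), numeric(1))
  ks <- vapply(fits, function(f) as.numeric(f$k), numeric(1))
  if (all(!is.finite(aiccs))) stop("no candidate has finite AICc", call. = FALSE)
  cand <- which(aiccs - min(aiccs) <= 2)
  ## stable key so exact ties are order-invariant
  key <- vapply(fits, function(f) paste(deparse(f$spec), collapse = ""), "")
  ord <- order(ks[cand], aiccs[cand], key[cand])
  fits[[cand[ord[1]]]]
}

## location/scale at a covariate cell, for the point estimate or a draw
cell_params <- function(fit, cell, params = fit$coef) {
  vars <- spec_vars(fit$spec)
  df <- as.data.frame(as.list(cell), stringsAsFactors = FALSE)
  missing_vars <- setdiff(vars, names(df))
  if (length(missing_vars))
    stop("cell is missing covariate(s): ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  if (!nrow(df)) df <- data.frame(row.names = 1)
  X <- design_matrix(fit$spec$location, df, fit$xlevels)
  mu <- unname(drop(X %*% params[seq_len(fit$p_loc)]))
  sigma <- 1
  if (fit$p_scale) {
    Z <- design_matrix(fit$spec$scale, df, fit$xlevels)
    sigma <- exp(unname(drop(Z %*% params[fit$p_loc + seq_len(fit$p_scale)])))
  }
  c(mu = mu, sigma = sigma)
}

#' Median persistence time
#'
#' The unique `t` with `S(t) = 0.5`: `exp(mu) log(2)` for the exponential,
#' `exp(mu) log(2)^sigma` for the Weibull, and `exp(mu)` for the log-logistic
#' and lognormal (symmetric on the log scale).
#'
#' @param fit a `cpt_fit`.
#' @param cell named list/vector of covariate labels (empty for an
#'   intercept-only model).
#' @param params optional coefficient vector (e.g. a bootstrap draw).
#' @return median persistence in days.
#' @export
median_time <- function(fit, cell = list(), params = fit$coef) {
  ps <- cell_params(fit, cell, params)
  mu <- ps[["mu"]]; sigma <- ps[["sigma"]]
  switch(fit$spec$family,
    exponential = exp(mu) * log(2),
    weibull = exp(mu) * log(2)^sigma,
    loglogistic = exp(mu),
    lognormal = exp(mu))
}

avg_persistence_params <- function(family, mu, sigma, t) {
  stats::integrate(function(u) surv_prob(family, u, mu, sigma),
                   lower = 0, upper = t,
                   abs.tol = 1e-8, rel.tol = 1e-10,
                   subdivisions = 500L)$value / t
}

#' Average probability of persistence over a search interval
#'
#' The time-average of the survival function, `(1/t) integral_0^t S(u) du`,
#' evaluated by adaptive quadrature (absolute tolerance 1e-8). This is the
#' persistence component of carcass detection probability for a search
#' interval of `t` days; for the exponential family it has the closed form
#' `(exp(mu)/t) (1 - exp(-t/exp(mu)))`, used as a cross-check in the test
#' suite.
#'
#' @param fit a `cpt_fit`.
#' @param cell named list/vector of covariate labels.
#' @param t search interval length(s) in days, each > 0.
#' @param params optional coefficient vector (e.g. a bootstrap draw).
#' @return vector of probabilities, one per element of `t`.
#' @export
avg_persistence <- function(fit, cell = list(), t, params = fit$coef) {
  if (any(t <= 0)) stop("search interval t must be positive", call. = FALSE)
  ps <- cell_params(fit, cell, params)
  vapply(t, function(tt)
    avg_persistence_params(fit$spec$family, ps[["mu"]], ps[["sigma"]], tt),
    numeric(1))
}

#' Parametric bootstrap draws of the coefficient vector
#'
#' Multivariate-normal draws centered at the estimates with the fitted
#' covariance. Scale coefficients live on the log link, so every draw yields
#' sigma > 0. A covariance that is not positive semidefinite is an error;
#' no silent nearest-PSD repair is applied.
#'
#' @param fit a `cpt_fit`.
#' @param n_boot number of draws.
#' @param seed integer seed.
#' @return `n_boot` x `k` matrix of coefficient draws.
#' @export
bootstrap_draws <- function(fit, n_boot, seed = 1) {
  stopifnot(inherits(fit, "cpt_fit"), n_boot >= 1)
  if (any(!is.finite(fit$vcov)))
    fit_error("non-finite covariance; cannot bootstrap")
  ev <- eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    fit_error("coefficient covariance is not positive semidefinite")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  draws <- MASS::mvrnorm(n_boot, mu = fit$coef, Sigma = fit$vcov)
  if (n_boot == 1) draws <- matrix(draws, 1, dimnames = list(NULL, names(fit$coef)))
  colnames(draws) <- names(fit$coef)
  draws
}

#' Percentile confidence interval
#'
#' Empirical quantiles at `(1 - level)/2` and `1 - (1 - level)/2` with linear
#' interpolation between order statistics.
#'
#' @param values numeric vector (length >= 2).
#' @param level coverage level in (0, 1); default 0.90.
#' @return named vector `c(lo, hi)`.
#' @export
percentile_ci <- function(values, level = 0.9) {
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  stopifnot(level > 0, level < 1)
  q <- stats::quantile(values, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE, type = 7)
  c(lo = q[1], hi = q[2])
}

#' Persistence summary for one covariate cell
#'
#' Median persistence time and average probability of persistence for each
#' search interval, with percentile bootstrap confidence intervals from
#' [bootstrap_draws()].
#'
#' @param fit a `cpt_fit`.
#' @param cell named list/vector of covariate labels.
#' @param intervals search intervals in days.
#' @param n_boot bootstrap draws (0 for point estimates only).
#' @param seed integer seed.
#' @param level CI coverage level.
#' @return a `cpt_persistence` list with `median` and `r_hat` tables.
#' @export
persistence_estimate <- function(fit, cell = list(),
                                 intervals = c(14, 30, 60, 90),
                                 n_boot = 1000, seed = 1, level = 0.9) {
  med <- median_time(fit, cell)
  r <- avg_persistence(fit, cell, intervals)
  out <- list(cell = cell,
              median = data.frame(estimate = med, lo = NA_real_, hi = NA_real_),
              r_hat = data.frame(interval = intervals, estimate = r,
                                 lo = NA_real_, hi = NA_real_),
              n_boot = n_boot)
  if (n_boot >= 2) {
    draws <- bootstrap_draws(fit, n_boot, seed)
    med_b <- apply(draws, 1, function(p) median_time(fit, cell, params = p))
    ci <- percentile_ci(med_b, level)
    out$median$lo <- ci[["lo"]]; out$median$hi <- ci[["hi"]]
    for (j in seq_along(intervals)) {
      r_b <- apply(draws, 1, function(p)
        avg_persistence(fit, cell, intervals[j], params = p))
      ci <- percentile_ci(r_b, level)
      out$r_hat$lo[j] <- ci[["lo"]]; out$r_hat$hi[j] <- ci[["hi"]]
    }
  }
  class(out) <- "cpt_persistence"
  out
}

#' @export
print.cpt_persistence <- function(x, ...) {
  if (length(x$cell))
    cat("Cell:", paste(names(x$cell), unlist(x$cell), sep = "=",
                       collapse = ", "), "\n")
  cat("Median persistence:", format(x$median$estimate, digits = 4), "days")
  if (is.finite(x$median$lo))
    cat(" (", format(x$median$lo, digits = 4), "-",
        format(x$median$hi, digits = 4), ")", sep = "")
  cat("\nAverage probability of persistence:\n")
  print(x$r_hat, row.names = FALSE, digits = 3)
  invisible(x)
}
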