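## Two-stage scaling of game bird persistence up to raptor persistence:
## analysis-group construction, Stage-1 bootstrap pairs of average
## persistence probabilities, and the Stage-2 logit-linear mixed-effects
## model with random intercept and slope by analysis group.

#' Logit and inverse logit
#'
#' `logit()` clips its argument to `[eps, 1 - eps]` (default `eps = 1e-6`)
#' before transforming, so bootstrap draws of probabilities at or beyond the
#' unit boundary stay finite with negligible distortion.
#'
#' @param p probabilities; `x` real values.
#' @param eps clipping bound.
#' @export
logit <- function(p, eps = 1e-6) {
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

#' @rdname logit
#' @export
inv_logit <- function(x) stats::plogis(x)

#' Summarize trial records by study
#'
#' Per-study carcass counts by bird type, the study's site/state/region/
#' habitat labels, and the seasons present: the input to
#' [build_analysis_groups()].
#'
#' @param trials a `cpt_trials` data frame.
#' @return data frame with one row per study.
#' @export
summarize_studies <- function(trials) {
  stopifnot(inherits(trials, "cpt_trials"))
  sp <- split(as.data.frame(trials), trials$study_id)
  rows <- lapply(sp, function(d) {
    data.frame(study_id = d$study_id[1], site_id = d$site_id[1],
               state = d$state[1], region = d$region[1],
               habitat = d$habitat[1],
               n_raptor = sum(d$bird_type == "raptor"),
               n_gamebird = sum(d$bird_type == "gamebird"),
               seasons = paste(sort(unique(d$season)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$site_id, out$study_id), ]
}

merge_units <- function(units) {
  data.frame(state = units$state[1], region = units$region[1],
             habitat = units$habitat[1],
             n_raptor = sum(units$n_raptor),
             n_gamebird = sum(units$n_gamebird),
             seasons = paste(sort(unique(unlist(
               strsplit(units$seasons, ",")))), collapse = ","),
             sites = paste(sort(unique(units$site_id)), collapse = ","),
             studies = paste(sort(unique(unlist(
               strsplit(units$studies, ",")))), collapse = ","),
             stringsAsFactors = FALSE)
}

#' Aggregate studies into analysis groups
#'
#' Greedy aggregation toward a minimum of `min_n` carcasses of each bird
#' type: studies at the same site are combined first; site units still below
#' the threshold are then combined with other sites in the same state and
#' habitat, walking sites alphabetically. Groups never span states. A
#' trailing remainder below the threshold merges into the previously closed
#' group of its state-habitat stratum when one exists; otherwise it is
#' excluded, with the reason recorded in the `excluded` attribute.
#'
#' @param studies per-study summaries from [summarize_studies()].
#' @param min_n minimum carcasses of each bird type per group.
#' @return a `cpt_groups` data frame (one row per analysis group, with the
#'   member sites and studies as comma-joined strings) carrying an
#'   `excluded` attribute.
#' @export
build_analysis_groups <- function(studies, min_n = 8) {
  stopifnot(is.data.frame(studies),
            all(c("study_id", "site_id", "state", "region", "habitat",
                  "n_raptor", "n_gamebird") %in% names(studies)))
  if (!"seasons" %in% names(studies)) studies$seasons <- ""

  ## step 1: aggregate by site
  sp <- split(studies, studies$site_id)
  site_units <- lapply(sp, function(d) {
    cbind(site_id = d$site_id[1],
          merge_units(transform(d, studies = study_id)))
  })
  site_units <- do.call(rbind, site_units)
  site_units <- site_units[order(site_units$site_id), ]

  ## step 2: within each state-habitat stratum, close groups greedily
  groups <- list(); excluded <- list()
  strata <- split(site_units,
                  paste(site_units$state, site_units$habitat, sep = "|"))
  for (str_units in strata) {
    open_idx <- integer(0)
    closed_here <- integer(0)
    for (i in seq_len(nrow(str_units))) {
      open_idx <- c(open_idx, i)
      cand <- merge_units(transform(
        str_units[open_idx, , drop = FALSE],
        site_id = str_units$sites[open_idx]))
      if (cand$n_raptor >= min_n && cand$n_gamebird >= min_n) {
        groups <- c(groups, list(cand))
        closed_here <- c(closed_here, length(groups))
        open_idx <- integer(0)
      }
    }
    if (length(open_idx)) {
      rem <- str_units[open_idx, , drop = FALSE]
      if (length(closed_here)) {
        last <- closed_here[length(closed_here)]
        both <- rbind(groups[[last]],
                      merge_units(transform(rem, site_id = rem$sites)))
        groups[[last]] <- merge_units(transform(both, site_id = both$sites))
      } else {
        excluded <- c(excluded, list(cbind(
          merge_units(transform(rem, site_id = rem$sites)),
          reason = paste0("below min_n = ", min_n,
                          " after exhausting candidates in ",
                          rem$state[1], "/", rem$habitat[1]))))
      }
    }
  }
  out <- do.call(rbind, groups)
  if (is.null(out)) stop("no analysis group reached min_n", call. = FALSE)
  out <- out[order(out$state, out$habitat, out$sites), , drop = FALSE]
  out$group_id <- sprintf("AG%02d", seq_len(nrow(out)))
  out <- out[, c("group_id", "state", "region", "habitat",
                 "n_raptor", "n_gamebird", "seasons", "sites", "studies")]
  rownames(out) <- NULL
  class(out) <- c("cpt_groups", "data.frame")
  attr(out, "excluded") <- if (length(excluded)) do.call(rbind, excluded) else NULL
  out
}

#' @export
print.cpt_groups <- function(x, ...) {
  cat("Analysis groups:", nrow(x), "\n")
  NextMethod()
  exc <- attr(x, "excluded")
  if (!is.null(exc)) cat("Excluded site sets:", nrow(exc), "\n")
  invisible(x)
}

group_study_lookup <- function(groups) {
  st <- strsplit(groups$studies, ",", fixed = TRUE)
  data.frame(study_id = unlist(st),
             group_id = rep(groups$group_id, lengths(st)),
             stringsAsFactors = FALSE)
}

## Candidate grid for one analysis-group model: season enters (location
## and/or scale) only when every season present has at least min_n carcasses
## of this bird type.
group_candidates <- function(obs_bird, min_n) {
  season_n <- table(obs_bird$season)
  season_ok <- length(season_n) >= 2 && all(season_n >= min_n)
  covs <- if (season_ok) "season" else character(0)
  candidate_grid(covariates = covs, allow_interactions = FALSE)
}

#' Stage 1: bootstrap-paired persistence probabilities per analysis group
#'
#' For each analysis group and bird type, fits the candidate survival
#' families (season admitted as a covariate only when every season in the
#' group has at least `min_n` carcasses of that bird type), applies the
#' parsimony selection rule, draws `B` parametric-bootstrap coefficient
#' sets, and evaluates the average probability of persistence for every
#' stratum and search interval under each draw. Game bird and raptor values
#' are paired by replicate index within (group, season, interval), which
#' preserves both marginal uncertainties without imposing cross-correlation.
#' A group whose fits fail for either bird type is dropped with a recorded
#' reason.
#'
#' @param groups a `cpt_groups` data frame.
#' @param trials a `cpt_trials` data frame (or prebuilt `cpt_obs`).
#' @param intervals search intervals in days.
#' @param B bootstrap replicates per model.
#' @param seed integer seed.
#' @param min_n season-admissibility threshold (carcasses per season).
#' @param camera_delta passed to [make_intervals()].
#' @return a `cpt_stage1` list: `draws` (rows group_id, season, region,
#'   habitat, interval, replicate, gamebird_r, raptor_r), `points` (the
#'   point-estimate counterpart), `dropped` (group ids and reasons).
#' @export
stage1_pairs <- function(groups, trials, intervals = c(14, 30, 60, 90),
                         B = 1000, seed = 1, min_n = 8, camera_delta = 0.04) {
  stopifnot(inherits(groups, "cpt_groups"))
  obs <- if (inherits(trials, "cpt_obs")) trials else
    make_intervals(trials, camera_delta)
  lookup <- group_study_lookup(groups)
  obs$group_id <- lookup$group_id[match(obs$study_id, lookup$study_id)]

  draws_rows <- list(); point_rows <- list(); dropped <- list()
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    obs_g <- obs[!is.na(obs$group_id) & obs$group_id == g$group_id, ]
    per_bird <- list()
    fail <- NULL
    for (bt in c("gamebird", "raptor")) {
      obs_b <- obs_g[obs_g$bird_type == bt, ]
      if (nrow(obs_b) < min_n) { fail <- paste0("fewer than ", min_n, " ", bt,
                                                " carcasses"); break }
      grid <- group_candidates(obs_b, min_n)
      fits <- list()
      for (spec in grid) {
        f <- tryCatch(fit_icsurv(spec, obs_b, seed = seed + i),
                      error = function(e) NULL)
        if (!is.null(f)) fits <- c(fits, list(f))
      }
      if (!length(fits)) { fail <- paste0("no ", bt, " model converged"); break }
      best <- select_model(fits)
      per_bird[[bt]] <- list(fit = best, obs = obs_b)
    }
    if (!is.null(fail)) {
      dropped <- c(dropped, list(data.frame(group_id = g$group_id,
                                            reason = fail)))
      next
    }

    ## strata: shared seasons when either selected model uses season,
    ## else a single stratum labelled with the group's modal season
    uses_season <- any(vapply(per_bird, function(pb)
      "season" %in% spec_vars(pb$fit$spec), logical(1)))
    shared <- intersect(unique(per_bird$gamebird$obs$season),
                        unique(per_bird$raptor$obs$season))
    seasons <- if (uses_season && length(shared)) sort(shared) else {
      tab <- table(obs_g$season)
      names(tab)[which.max(tab)]
    }

    draw_r <- function(pb, b_seed) {
      dr <- bootstrap_draws(pb$fit, B, seed = b_seed)
      vars <- spec_vars(pb$fit$spec)
      out <- array(NA_real_, c(B, length(seasons), length(intervals)))
      for (s in seq_along(seasons)) {
        cell <- if ("season" %in% vars) list(season = seasons[s]) else list()
        cell_ok <- !("season" %in% vars) ||
          seasons[s] %in% pb$fit$xlevels$season
        if (!cell_ok) next
        for (b in seq_len(B)) {
          out[b, s, ] <- avg_persistence(pb$fit, cell, intervals,
                                         params = dr[b, ])
        }
      }
      out
    }
    point_r <- function(pb) {
      vars <- spec_vars(pb$fit$spec)
      out <- matrix(NA_real_, length(seasons), length(intervals))
      for (s in seq_along(seasons)) {
        cell <- if ("season" %in% vars) list(season = seasons[s]) else list()
        if ("season" %in% vars && !(seasons[s] %in% pb$fit$xlevels$season)) next
        out[s, ] <- avg_persistence(pb$fit, cell, intervals)
      }
      out
    }
    res <- tryCatch(list(
      gb_d = draw_r(per_bird$gamebird, seed + 1000L + i),
      rp_d = draw_r(per_bird$raptor, seed + 2000L + i),
      gb_p = point_r(per_bird$gamebird),
      rp_p = point_r(per_bird$raptor)), error = function(e) e)
    if (inherits(res, "error")) {
      dropped <- c(dropped, list(data.frame(group_id = g$group_id,
                                            reason = conditionMessage(res))))
      next
    }
    gb_d <- res$gb_d; rp_d <- res$rp_d; gb_p <- res$gb_p; rp_p <- res$rp_p

    for (s in seq_along(seasons)) {
      if (any(is.na(gb_p[s, ])) || any(is.na(rp_p[s, ]))) next
      draws_rows[[length(draws_rows) + 1L]] <- data.frame(
        group_id = g$group_id, season = seasons[s], region = g$region,
        habitat = g$habitat,
        interval = rep(intervals, each = B),
        replicate = rep(seq_len(B), length(intervals)),
        gamebird_r = as.vector(gb_d[, s, ]),
        raptor_r = as.vector(rp_d[, s, ]),
        stringsAsFactors = FALSE)
      point_rows[[length(point_rows) + 1L]] <- data.frame(
        group_id = g$group_id, season = seasons[s], region = g$region,
        habitat = g$habitat, interval = intervals,
        gamebird_r = gb_p[s, ], raptor_r = rp_p[s, ],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(draws_rows)) stop("stage 1 produced no pairs", call. = FALSE)
  structure(list(draws = do.call(rbind, draws_rows),
                 points = do.call(rbind, point_rows),
                 dropped = if (length(dropped)) do.call(rbind, dropped) else NULL,
                 intervals = intervals, B = B),
            class = "cpt_stage1")
}

#' @export
print.cpt_stage1 <- function(x, ...) {
  cat("Stage-1 bootstrap pairs: ", nrow(x$draws), " rows (",
      length(unique(x$draws$group_id)), " groups x strata x ",
      length(x$intervals), " intervals x B = ", x$B, ")\n", sep = "")
  if (!is.null(x$dropped))
    cat("Dropped groups:", paste(x$dropped$group_id, collapse = ", "), "\n")
  invisible(x)
}

scaling_factorize <- function(df) {
  canon <- canonical_levels()
  for (v in c("season", "region", "habitat")) {
    if (v %in% names(df)) {
      lev <- intersect(canon[[v]], unique(as.character(df[[v]])))
      df[[v]] <- factor(as.character(df[[v]]), levels = lev)
    }
  }
  df
}

all_fixed_subsets <- function(covs = c("season", "region", "habitat")) {
  sets <- list(character(0))
  for (v in covs) sets <- c(sets, lapply(sets, function(s) c(s, v)))
  sets
}

#' Construct a scaling model from explicit coefficients
#'
#' Builds a `cpt_scaling` object directly from fixed-effect values, e.g. the
#' published national-scale model coefficients, so predictions can be made
#' without refitting. Offsets are named vectors keyed by non-baseline level;
#' the baselines (fall, Region 1, cropland by convention) are absorbed in
#' the intercept.
#'
#' @param intercept fixed intercept on the logit scale.
#' @param slope coefficient of game bird average probability of persistence.
#' @param season,region,habitat named offset vectors (possibly empty).
#' @param baselines named character vector of baseline levels.
#' @param re_sd_intercept,re_sd_slope,re_correlation random-effect
#'   dispersions by analysis group.
#' @param resid_sd residual standard deviation.
#' @param vcov_fixed optional covariance of (intercept, slope, offsets...)
#'   for prediction intervals.
#' @return a `cpt_scaling` object.
#' @export
scaling_model <- function(intercept, slope,
                          season = c(spring = 0, summer = 0, winter = 0),
                          region = numeric(0), habitat = numeric(0),
                          baselines = c(season = "fall", region = "R1",
                                        habitat = "cropland"),
                          re_sd_intercept = 0, re_sd_slope = 0,
                          re_correlation = 0, resid_sd = NA_real_,
                          vcov_fixed = NULL) {
  structure(list(
    intercept = intercept, slope = slope,
    offsets = list(season = season, region = region, habitat = habitat),
    baselines = baselines,
    fixed_terms = names(Filter(length, list(season = season, region = region,
                                            habitat = habitat))),
    random = c(sd_intercept = re_sd_intercept, sd_slope = re_sd_slope,
               correlation = re_correlation),
    resid_sd = resid_sd,
    icc = if (is.na(resid_sd)) NA_real_ else
      re_sd_intercept^2 / (re_sd_intercept^2 + resid_sd^2),
    icc_formula = "sd_intercept^2 / (sd_intercept^2 + resid_sd^2)",
    blups = NULL, vcov_fixed = vcov_fixed, n_groups = NA_integer_,
    aicc = NA_real_, k = NA_integer_),
    class = "cpt_scaling")
}

#' The published national-scale game bird to raptor scaling model
#'
#' The fixed effects, random-effect dispersions and residual error of the
#' best-supported logit-linear mixed-effects model relating raptor to game
#' bird average probability of persistence across U.S. wind-facility
#' persistence studies (intercept -0.66 absorbing fall / Region 1 /
#' cropland; game bird slope 4.19; season, Region and habitat offsets;
#' group dispersions 0.53 and 2.32; residual 0.29). Intended for
#' practitioners who need a raptor persistence probability from
#' site-specific game bird data without refitting.
#'
#' @return a `cpt_scaling` object.
#' @seealso [predict_raptor()]
#' @export
reference_scaling_model <- function() {
  scaling_model(
    intercept = -0.66, slope = 4.19,
    season = c(spring = -0.05, summer = -0.03, winter = -0.08),
    region = c(R2 = 0.47, R3 = 0.33, R4 = -0.39, R6 = 1.25, R8 = 2.86),
    habitat = c(grassland = 0.39, shrub_scrub = -2.20),
    re_sd_intercept = 0.53, re_sd_slope = 2.32, resid_sd = 0.29)
}

#' Stage 2: fit the logit-linear mixed-effects scaling model
#'
#' Fits `logit(raptor_r) ~ gamebird_r + <fixed covariates> +
#' (1 + gamebird_r | group)` by maximum likelihood for every candidate
#' fixed-effect set (all subsets of season, Region and habitat by default;
#' the game bird slope is always included; no interactions), ranks the
#' candidates by AICc, and applies the parsimony-within-2 rule. A candidate
#' covariate with fewer than two levels in the data is dropped from that
#' candidate with a note. The ICC is reported as
#' `sd_intercept^2 / (sd_intercept^2 + resid_sd^2)`, stated with its formula
#' because the intra-class correlation is ambiguous under a random slope.
#'
#' @param pairs a `cpt_stage1` object or its `draws` data frame.
#' @param candidate_fixed list of character vectors of fixed covariates.
#' @param seed integer seed (kept for interface symmetry; the ML fit is
#'   deterministic).
#' @param eps logit clipping bound.
#' @return a `cpt_scaling` object with `blups`, `vcov_fixed`, `aicc`,
#'   `candidates` (the AICc table) populated.
#' @export
fit_scaling <- function(pairs, candidate_fixed = all_fixed_subsets(),
                        seed = 1, eps = 1e-6) {
  data <- if (inherits(pairs, "cpt_stage1")) pairs$draws else pairs
  stopifnot(all(c("group_id", "season", "region", "habitat",
                  "gamebird_r", "raptor_r") %in% names(data)))
  if (length(unique(data$group_id)) < 2)
    stop("need at least 2 analysis groups", call. = FALSE)
  data <- scaling_factorize(as.data.frame(data))
  data$logit_raptor <- logit(data$raptor_r, eps)

  usable <- vapply(c("season", "region", "habitat"),
                   function(v) nlevels(droplevels(data[[v]])) >= 2, logical(1))
  cands <- list()
  for (fx in candidate_fixed) {
    dropped <- fx[!usable[fx]]
    if (length(dropped))
      message("covariate(s) with a single level dropped from candidate: ",
              paste(dropped, collapse = ", "))
    fx <- fx[usable[fx]]
    key <- paste(sort(fx), collapse = "+")
    if (!key %in% names(cands)) cands[[if (nzchar(key)) key else "(none)"]] <- fx
  }

  fits <- list()
  for (key in names(cands)) {
    fx <- cands[[key]]
    fml <- stats::as.formula(paste(
      "logit_raptor ~ gamebird_r",
      if (length(fx)) paste("+", paste(fx, collapse = " + ")) else "",
      "+ (1 + gamebird_r | group_id)"))
    fit <- tryCatch(
      lme4::lmer(fml, data = data, REML = FALSE,
                 control = lme4::lmerControl(calc.derivs = FALSE)),
      error = function(e) e)
    if (inherits(fit, "error"))
      stop("scaling candidate failed to converge (", key, "): ",
           conditionMessage(fit), call. = FALSE)
    ll <- stats::logLik(fit)
    fits[[key]] <- list(fit = fit, fixed = fx, spec = key,
                        k = attr(ll, "df"),
                        aicc = aicc(as.numeric(ll), attr(ll, "df"),
                                    stats::nobs(fit)))
  }
  best <- select_model(fits)
  as_scaling(best$fit, best$fixed,
             candidates = data.frame(
               fixed = names(fits),
               k = vapply(fits, function(f) f$k, numeric(1)),
               aicc = vapply(fits, function(f) f$aicc, numeric(1)),
               row.names = NULL))
}

## Extract a cpt_scaling object from a fitted merMod.
as_scaling <- function(fit, fixed_terms, candidates = NULL) {
  fe <- lme4::fixef(fit)
  vc <- lme4::VarCorr(fit)
  re <- vc$group_id
  sds <- attr(re, "stddev")
  corr <- attr(re, "correlation")
  resid_sd <- attr(vc, "sc")

  offsets <- list(season = numeric(0), region = numeric(0),
                  habitat = numeric(0))
  baselines <- c(season = NA_character_, region = NA_character_,
                 habitat = NA_character_)
  mf <- stats::model.frame(fit)
  for (v in intersect(fixed_terms, c("season", "region", "habitat"))) {
    lev <- levels(mf[[v]])
    baselines[v] <- lev[1]
    cf <- fe[paste0(v, lev[-1])]
    names(cf) <- lev[-1]
    offsets[[v]] <- cf
  }
  rr <- lme4::ranef(fit)$group_id
  ll <- stats::logLik(fit)
  out <- scaling_model(
    intercept = unname(fe["(Intercept)"]),
    slope = unname(fe["gamebird_r"]),
    season = offsets$season, region = offsets$region,
    habitat = offsets$habitat, baselines = baselines,
    re_sd_intercept = unname(sds["(Intercept)"]),
    re_sd_slope = unname(sds["gamebird_r"]),
    re_correlation = if (!is.null(corr) && ncol(corr) == 2)
      corr[1, 2] else 0,
    resid_sd = resid_sd,
    vcov_fixed = as.matrix(stats::vcov(fit)))
  out$fixed_terms <- fixed_terms
  out$blups <- data.frame(group_id = rownames(rr),
                          intercept = rr[["(Intercept)"]],
                          slope = rr[["gamebird_r"]],
                          stringsAsFactors = FALSE)
  out$n_groups <- nrow(rr)
  out$k <- attr(ll, "df")
  out$aicc <- aicc(as.numeric(ll), attr(ll, "df"), stats::nobs(fit))
  out$candidates <- candidates
  out$fit <- fit
  out
}

#' @export
print.cpt_scaling <- function(x, ...) {
  cat("Logit-linear scaling model: raptor ~ game bird persistence\n")
  cat("  intercept ", format(x$intercept, digits = 3),
      " (baselines: ", paste(stats::na.omit(x$baselines), collapse = ", "),
      "), game bird slope ", format(x$slope, digits = 3), "\n", sep = "")
  for (v in names(x$offsets)) {
    if (length(x$offsets[[v]]))
      cat("  ", v, ": ", paste(names(x$offsets[[v]]),
                               round(x$offsets[[v]], 2),
                               sep = "=", collapse = ", "), "\n", sep = "")
  }
  cat("  random effects (by group): sd_intercept ",
      format(x$random["sd_intercept"], digits = 3),
      ", sd_slope ", format(x$random["sd_slope"], digits = 3),
      "; residual sd ", format(x$resid_sd, digits = 3), "\n", sep = "")
  if (!is.na(x$icc))
    cat("  ICC = ", format(x$icc, digits = 3), "  [", x$icc_formula, "]\n",
        sep = "")
  if (!is.na(x$n_groups)) cat("  n groups =", x$n_groups, "\n")
  invisible(x)
}

lookup_offset <- function(model, var, level) {
  if (!var %in% model$fixed_terms) return(0)
  if (!is.na(model$baselines[var]) && level == model$baselines[var]) return(0)
  off <- model$offsets[[var]]
  if (!level %in% names(off))
    stop("level not among fitted levels for ", var, ": ", level,
         call. = FALSE)
  unname(off[level])
}

#' Predict raptor persistence from game bird persistence
#'
#' Applies the scaling model's linear predictor
#' `eta = intercept + slope * gamebird_r + offsets` and returns
#' `inv_logit(eta)`. For a `group_id` present in the fitted groups, the
#' group's BLUP intercept and slope deviations are added; for a new group
#' the prediction uses fixed effects only. An optional interval is obtained
#' by simulating fixed-coefficient uncertainty (requires `vcov_fixed`) plus,
#' for a new group, the random-effect law.
#'
#' @param model a `cpt_scaling` object.
#' @param gamebird_r game bird average probability of persistence, in (0,1).
#' @param season,region,habitat stratum labels (baselines by default).
#' @param group_id optional analysis-group id for BLUP-level prediction.
#' @param interval if `TRUE`, also return a percentile interval.
#' @param level interval coverage.
#' @param n_sim simulation draws for the interval.
#' @param seed integer seed for the interval simulation.
#' @return the predicted probability, or (with `interval = TRUE`) a list
#'   with `estimate`, `lo`, `hi`.
#' @export
predict_raptor <- function(model, gamebird_r, season = "fall",
                           region = "R1", habitat = "cropland",
                           group_id = NULL, interval = FALSE,
                           level = 0.9, n_sim = 1000, seed = 1) {
  stopifnot(inherits(model, "cpt_scaling"),
            gamebird_r > 0, gamebird_r < 1)
  off <- lookup_offset(model, "season", season) +
    lookup_offset(model, "region", region) +
    lookup_offset(model, "habitat", habitat)
  b0 <- 0; b1 <- 0; known_group <- FALSE
  if (!is.null(group_id) && !is.null(model$blups)) {
    j <- match(group_id, model$blups$group_id)
    if (!is.na(j)) {
      b0 <- model$blups$intercept[j]; b1 <- model$blups$slope[j]
      known_group <- TRUE
    }
  }
  eta <- model$intercept + b0 + (model$slope + b1) * gamebird_r + off
  est <- inv_logit(eta)
  if (!interval) return(est)

  if (is.null(model$vcov_fixed))
    stop("model carries no fixed-effect covariance; interval unavailable",
         call. = FALSE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  fe_names <- rownames(model$vcov_fixed)
  fe_mean <- numeric(length(fe_names)); names(fe_mean) <- fe_names
  fe_mean["(Intercept)"] <- model$intercept
  fe_mean["gamebird_r"] <- model$slope
  for (v in names(model$offsets)) {
    for (lv in names(model$offsets[[v]])) {
      nm <- paste0(v, lv)
      if (nm %in% fe_names) fe_mean[nm] <- model$offsets[[v]][lv]
    }
  }
  sims <- MASS::mvrnorm(n_sim, fe_mean, model$vcov_fixed)
  x <- numeric(length(fe_names)); names(x) <- fe_names
  x["(Intercept)"] <- 1
  x["gamebird_r"] <- gamebird_r
  for (v in c("season", "region", "habitat")) {
    lv <- switch(v, season = season, region = region, habitat = habitat)
    nm <- paste0(v, lv)
    if (nm %in% fe_names) x[nm] <- 1
  }
  eta_sim <- drop(sims %*% x)
  if (!known_group) {
    sd0 <- model$random[["sd_intercept"]]; sd1 <- model$random[["sd_slope"]]
    rho <- model$random[["correlation"]]
    sig <- matrix(c(sd0^2, rho * sd0 * sd1, rho * sd0 * sd1, sd1^2), 2, 2)
    bs <- MASS::mvrnorm(n_sim, c(0, 0), sig)
    eta_sim <- eta_sim + bs[, 1] + bs[, 2] * gamebird_r
  } else {
    eta_sim <- eta_sim + b0 + b1 * gamebird_r
  }
  ci <- percentile_ci(inv_logit(eta_sim), level)
  list(estimate = est, lo = ci[["lo"]], hi = ci[["hi"]])
}
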