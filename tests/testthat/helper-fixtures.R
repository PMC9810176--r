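## Shared fixtures: tiny in-code trial sets and a CSV writer.

trial_row <- function(carcass_id, last_present, first_absent,
                      monitor_mode = "in_person", study_id = "st1",
                      site_id = "siteA", state = "NE", region = "R6",
                      habitat = "grassland", season = "fall",
                      bird_type = "gamebird", trial_length = 56) {
  data.frame(carcass_id = carcass_id, study_id = study_id, site_id = site_id,
             state = state, region = region, habitat = habitat,
             season = season, bird_type = bird_type, species = NA_character_,
             placement_time = 0, last_present = last_present,
             first_absent = first_absent, monitor_mode = monitor_mode,
             trial_length = trial_length, stringsAsFactors = FALSE)
}

tiny_trials <- function() {
  df <- rbind(
    trial_row("c1", 14, 21),
    trial_row("c2", 56, NA),                       # right-censored
    trial_row("c3", 3.2, 3.2, monitor_mode = "camera")
  )
  class(df) <- c("cpt_trials", "data.frame")
  df
}

write_trials_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, na = "")
  path
}

## A cpt_fit with known coefficients and zero covariance: lets closed-form
## checks exercise the public prediction surface without an optimizer run.
known_fit <- function(family, mu, sigma = 1) {
  p_scale <- if (family == "exponential") 0L else 1L
  coef <- c("loc:(Intercept)" = mu)
  if (p_scale) coef <- c(coef, "logscale:(Intercept)" = log(sigma))
  k <- length(coef)
  structure(list(
    spec = model_spec(family,
                      scale = character(0)),
    beta = coef[1], gamma = if (p_scale) coef[2] else numeric(0),
    coef = coef, vcov = matrix(0, k, k, dimnames = list(names(coef), names(coef))),
    loglik = NA_real_, k = k, n = NA_integer_, aicc = NA_real_,
    p_loc = 1L, p_scale = p_scale, xlevels = list(), convergence = 0L),
    class = "cpt_fit")
}

## Independent brute-force enumeration of the admissible candidate grid,
## used as the oracle for candidate_grid().
brute_force_grid_size <- function(n_cov, families = 4, allow_interactions = TRUE) {
  covs <- seq_len(n_cov)
  mains_sets <- unlist(lapply(0:n_cov, function(m)
    combn(covs, m, simplify = FALSE)), recursive = FALSE)
  n_term_sets <- sum(vapply(mains_sets, function(m) {
    if (!allow_interactions || length(m) < 2) return(1)
    2^choose(length(m), 2)
  }, numeric(1)))
  ## families - 1 location-scale families x loc x scale + exponential x loc
  (families - 1) * n_term_sets^2 + 1 * n_term_sets
}
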