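## Covariate-grid model selection over the meta-dataset, and
## strata-restricted persistence estimate tables.

## All term sets built from the mains plus (optionally) two-way
## interactions whose main effects are both present.
admissible_term_sets <- function(covariates, allow_interactions) {
  mains_sets <- list(character(0))
  for (v in covariates) {
    mains_sets <- c(mains_sets, lapply(mains_sets, function(s) c(s, v)))
  }
  out <- list()
  for (mains in mains_sets) {
    out <- c(out, list(mains))
    if (allow_interactions && length(mains) >= 2) {
      pairs <- utils::combn(sort(mains), 2, simplify = FALSE)
      inter_all <- vapply(pairs, paste, "", collapse = ":")
      inter_sets <- list(character(0))
      for (tm in inter_all) {
        inter_sets <- c(inter_sets, lapply(inter_sets, function(s) c(s, tm)))
      }
      for (isel in inter_sets[-1]) {
        out <- c(out, list(c(mains, isel)))
      }
    }
  }
  out
}

#' Enumerate the candidate model grid
#'
#' Every admissible combination of survival family, location terms and
#' scale terms built from the covariate pool: term sets are all subsets of
#' the main effects, optionally extended by two-way interactions whose main
#' effects are both included; the exponential family carries no scale terms.
#' Ordering is deterministic.
#'
#' @param covariates subset of `c("season", "habitat", "region")` (other
#'   categorical columns are accepted for simulated data).
#' @param families survival families to include.
#' @param allow_interactions admit two-way interaction terms.
#' @return a `cpt_grid` list of [model_spec()] objects.
#' @export
candidate_grid <- function(covariates = c("season", "habitat", "region"),
                           families = surv_families(),
                           allow_interactions = TRUE) {
  known <- c("season", "habitat", "region", "bird_type")
  bad <- setdiff(covariates, known)
  if (length(bad)) {
    stop("unknown covariate(s): ", paste(bad, collapse = ", "),
         "; expected among: ", paste(known, collapse = ", "), call. = FALSE)
  }
  families <- match.arg(families, surv_families(), several.ok = TRUE)
  term_sets <- admissible_term_sets(covariates, allow_interactions)
  specs <- list()
  for (fam in families) {
    scale_sets <- if (fam == "exponential") list(character(0)) else term_sets
    for (loc in term_sets) {
      for (sc in scale_sets) {
        specs <- c(specs, list(model_spec(fam, loc, sc)))
      }
    }
  }
  structure(specs, class = "cpt_grid")
}

#' @export
print.cpt_grid <- function(x, ...) {
  cat("Candidate model grid:", length(x), "specifications\n")
  fams <- table(vapply(x, function(s) s$family, ""))
  cat("  ", paste(names(fams), fams, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

## Strata (label combinations) that actually occur in the data, in
## deterministic order.
sampled_strata <- function(obs, covariates) {
  if (!length(covariates)) return(data.frame(row.names = 1))
  strata <- unique(as.data.frame(obs)[, covariates, drop = FALSE])
  ord <- do.call(order, lapply(covariates, function(v) strata[[v]]))
  strata <- strata[ord, , drop = FALSE]
  rownames(strata) <- NULL
  strata
}

#' Fit the candidate grid to meta-data for one bird type and tabulate
#' persistence by sampled strata
#'
#' Fits every specification in the grid to the bird type's observations,
#' applies the parsimony-within-2-AICc selection rule, and produces median
#' persistence and average-probability-of-persistence estimates (with
#' percentile bootstrap CIs) for each stratum that has data. Specifications
#' that fail to fit (degenerate strata, unsampled level combinations) are
#' dropped from selection with a warning. Estimates are emitted only for
#' sampled strata: model output for covariate combinations without data is
#' never reported.
#'
#' @param obs a `cpt_obs` data frame (may contain both bird types).
#' @param bird_type `"raptor"` or `"gamebird"`.
#' @param grid a [candidate_grid()].
#' @param intervals search intervals in days.
#' @param n_boot bootstrap draws for the CIs (0 to skip).
#' @param seed integer seed.
#' @param level CI coverage level.
#' @return a `cpt_meta` list: `fit` (the selected `cpt_fit`), `fits` (all
#'   converged candidates), `strata` (the estimates table), `n_failed`.
#' @export
fit_meta <- function(obs, bird_type, grid, intervals = c(30, 60, 90),
                     n_boot = 1000, seed = 1, level = 0.9) {
  stopifnot(inherits(grid, "cpt_grid"))
  obs_bt <- obs[obs$bird_type == bird_type, , drop = FALSE]
  if (!nrow(obs_bt)) stop("no observations for bird_type ", bird_type,
                          call. = FALSE)
  covariates <- sort(unique(unlist(lapply(grid, spec_vars))))

  fits <- list(); n_failed <- 0L
  for (spec in grid) {
    f <- tryCatch(fit_icsurv(spec, obs_bt, seed = seed),
                  cpt_fit_error = function(e) e, error = function(e) e)
    if (inherits(f, "cpt_fit")) {
      fits <- c(fits, list(f))
    } else {
      n_failed <- n_failed + 1L
      warning("candidate dropped (", spec$family, ", loc ~ ",
              paste(c("1", spec$location), collapse = " + "), "): ",
              conditionMessage(f), call. = FALSE)
    }
  }
  if (!length(fits)) stop("no candidate model converged", call. = FALSE)
  best <- select_model(fits)

  strata <- sampled_strata(obs_bt, covariates)
  rows <- list()
  n_strata <- max(nrow(strata), 1)
  for (i in seq_len(n_strata)) {
    cell <- if (ncol(strata)) as.list(strata[i, , drop = FALSE]) else list()
    est <- persistence_estimate(best, cell, intervals, n_boot,
                                seed = seed + i, level = level)
    sel <- rep(TRUE, nrow(obs_bt))
    for (v in names(cell)) sel <- sel & obs_bt[[v]] == cell[[v]]
    row <- data.frame(bird_type = bird_type,
                      n_carcasses = sum(sel),
                      median_days = est$median$estimate,
                      median_lo = est$median$lo, median_hi = est$median$hi,
                      stringsAsFactors = FALSE)
    if (length(cell)) row <- cbind(as.data.frame(cell, stringsAsFactors = FALSE), row)
    for (j in seq_along(intervals)) {
      row[[paste0("r", intervals[j])]] <- est$r_hat$estimate[j]
      row[[paste0("r", intervals[j], "_lo")]] <- est$r_hat$lo[j]
      row[[paste0("r", intervals[j], "_hi")]] <- est$r_hat$hi[j]
    }
    rows[[i]] <- row
  }
  structure(list(fit = best, fits = fits,
                 strata = do.call(rbind, rows),
                 n_failed = n_failed, bird_type = bird_type),
            class = "cpt_meta")
}

#' @export
print.cpt_meta <- function(x, ...) {
  cat("Meta-analysis persistence fit for", x$bird_type, "\n")
  cat("Selected model: "); print(x$fit$spec)
  cat(length(x$fits), "candidates converged;", x$n_failed, "dropped\n")
  cat("Strata estimates:\n")
  print(utils::head(x$strata, 10), row.names = FALSE, digits = 3)
  if (nrow(x$strata) > 10) cat("  ...", nrow(x$strata), "strata total\n")
  invisible(x)
}
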