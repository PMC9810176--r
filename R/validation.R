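## Stratified cross-validation of the scaling model and the four
## out-of-sample prediction metrics.

#' Stratified training/hold-out splits of the analysis groups
#'
#' Groups are stratified by Region x habitat. Every singleton cell's group
#' is always placed in the training set (so the selected model can be refit
#' without unseen levels); every multi-group cell contributes at least one
#' randomly sampled training group; further groups are added at random until
#' the training fraction is as close to `train_target` as those constraints
#' allow. Each split draws from an independent child seed, so adding splits
#' never perturbs earlier ones.
#'
#' @param groups a `cpt_groups` data frame.
#' @param n_sets number of splits.
#' @param train_target target training fraction.
#' @param seed integer seed.
#' @return list of `n_sets` lists with elements `train` and `holdout`
#'   (disjoint, exhaustive vectors of group ids).
#' @export
stratified_splits <- function(groups, n_sets = 10, train_target = 0.52,
                              seed = 1) {
  stopifnot(inherits(groups, "cpt_groups"), nrow(groups) >= 2)
  cell <- paste(groups$region, groups$habitat, sep = "|")
  cells <- split(groups$group_id, cell)
  singletons <- unlist(cells[lengths(cells) == 1], use.names = FALSE)
  multis <- cells[lengths(cells) > 1]
  if (!length(multis))
    stop("every Region x habitat cell is a singleton; no hold-out possible",
         call. = FALSE)
  target_n <- round(train_target * nrow(groups))

  splits <- vector("list", n_sets)
  for (s in seq_len(n_sets)) {
    set.seed((as.integer(seed) * 1009L + s) %% .Machine$integer.max)
    train <- singletons
    pool <- character(0)
    for (ids in multis) {
      pick <- sample(ids, 1)
      train <- c(train, pick)
      pool <- c(pool, setdiff(ids, pick))
    }
    ## top up toward the target, never emptying the hold-out
    n_extra <- min(max(target_n - length(train), 0), length(pool) - 1)
    if (n_extra > 0) train <- c(train, sample(pool, n_extra))
    holdout <- setdiff(groups$group_id, train)
    splits[[s]] <- list(train = sort(train), holdout = sort(holdout))
  }
  splits
}

#' Out-of-sample prediction metrics
#'
#' Root mean-square error, Pearson correlation, the proportion of
#' predictions exceeding the out-of-sample estimates (direction of error),
#' and mean absolute error.
#'
#' @param predicted,actual equal-length probability vectors (length >= 2).
#' @return named vector `c(rmse, pearson, prop_over, mae)`; `pearson` is
#'   `NA` when `actual` is constant.
#' @export
oos_metrics <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual), length(actual) >= 2)
  err <- predicted - actual
  pearson <- if (stats::sd(actual) == 0) NA_real_ else
    stats::cor(predicted, actual)
  c(rmse = sqrt(mean(err^2)),
    pearson = pearson,
    prop_over = mean(predicted > actual),
    mae = mean(abs(err)))
}

#' Cross-validate the scaling model
#'
#' For each stratified split, refits the selected fixed-effect form on the
#' training groups' Stage-1 bootstrap pairs, predicts every hold-out
#' group's raptor average probability of persistence from its game bird
#' point estimates using fixed effects only (hold-out groups are new to the
#' refit model, so no BLUPs exist for them), and scores the predictions
#' against the hold-out groups' own Stage-1 raptor point estimates.
#'
#' @param stage1 a `cpt_stage1` object.
#' @param groups the `cpt_groups` the pairs were built from.
#' @param fixed_terms fixed covariates of the selected model (character
#'   vector), e.g. `fit$fixed_terms` from [fit_scaling()].
#' @param n_sets number of cross-validation splits.
#' @param train_target target training fraction.
#' @param seed integer seed.
#' @return a `cpt_validation` object: per-split metric rows, `n_splits`,
#'   `n_failed`, `seed`.
#' @export
cross_validate <- function(stage1, groups, fixed_terms = character(0),
                           n_sets = 10, train_target = 0.52, seed = 1) {
  stopifnot(inherits(stage1, "cpt_stage1"))
  fitted_ids <- unique(stage1$draws$group_id)
  groups <- groups[groups$group_id %in% fitted_ids, , drop = FALSE]
  class(groups) <- c("cpt_groups", "data.frame")
  splits <- stratified_splits(groups, n_sets, train_target, seed)

  rows <- list(); n_failed <- 0L
  for (s in seq_along(splits)) {
    sp <- splits[[s]]
    train_draws <- stage1$draws[stage1$draws$group_id %in% sp$train, ]
    model <- tryCatch(
      fit_scaling(train_draws, candidate_fixed = list(fixed_terms)),
      error = function(e) e)
    if (inherits(model, "error")) {
      n_failed <- n_failed + 1L
      rows[[s]] <- data.frame(split = s, rmse = NA_real_, pearson = NA_real_,
                              prop_over = NA_real_, mae = NA_real_,
                              n_holdout = 0L)
      next
    }
    hold <- stage1$points[stage1$points$group_id %in% sp$holdout, ]
    pred <- rep(NA_real_, nrow(hold))
    for (i in seq_len(nrow(hold))) {
      pred[i] <- tryCatch(
        predict_raptor(model, hold$gamebird_r[i],
                       season = as.character(hold$season[i]),
                       region = as.character(hold$region[i]),
                       habitat = as.character(hold$habitat[i])),
        error = function(e) NA_real_)
    }
    ok <- !is.na(pred)
    m <- oos_metrics(pred[ok], hold$raptor_r[ok])
    rows[[s]] <- data.frame(split = s, rmse = m[["rmse"]],
                            pearson = m[["pearson"]],
                            prop_over = m[["prop_over"]], mae = m[["mae"]],
                            n_holdout = sum(ok))
  }
  structure(list(metrics = do.call(rbind, rows), n_splits = n_sets,
                 n_failed = n_failed, seed = seed, splits = splits),
            class = "cpt_validation")
}

#' @export
print.cpt_validation <- function(x, ...) {
  cat("Stratified cross-validation:", x$n_splits, "splits")
  if (x$n_failed) cat(" (", x$n_failed, " failed)", sep = "")
  cat("\n")
  print(x$metrics, row.names = FALSE, digits = 3)
  invisible(x)
}
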