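---
title: "Carcass persistence models and game bird to raptor scaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carcass persistence models and game bird to raptor scaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cptscale)
```

## The model

Carcass persistence trials (CPT) produce interval-censored removal times:
a carcass checked on a schedule is known to have been removed between the
last check at which it was present and the first at which it was absent,
written `[L, R)`; a carcass still present at the final check is
right-censored, `[L, Inf)`. Camera-monitored trials record the removal
time essentially exactly; we encode those as narrow intervals of width
`camera_delta` (default 0.04 d, about an hour) so a single likelihood
serves both monitoring modes.

Removal times are modelled with log-location-scale survival families,
`T = exp(mu + sigma * W)`:

| family       | W                | survival function                          |
|--------------|------------------|--------------------------------------------|
| lognormal    | standard normal  | `1 - Phi((log t - mu)/sigma)`              |
| log-logistic | standard logistic| `1 / (1 + (t/e^mu)^(1/sigma))`             |
| Weibull      | Gumbel minimum   | `exp(-(t/e^mu)^(1/sigma))`                 |
| exponential  | Weibull, sigma=1 | `exp(-t/e^mu)`                             |

Categorical covariates (season, habitat, USFWS Region) enter `mu`
linearly under treatment coding and `log(sigma)` linearly, so any
coefficient vector yields a valid `sigma > 0`. Factor baselines are the
first canonical level present in the data (fall, Region 1, cropland,
raptor), which is also where the published scaling model absorbs its
baselines. The likelihood is the product of interval masses
`S(L) - S(R)`; `neg_loglik()` returns `Inf` (not an error) for parameter
values that zero out an interval, so the optimizer can recover.

Fitting (`fit_icsurv()`) is multi-start BFGS: a method-of-moments start
from log interval midpoints plus jittered restarts (default 5). The
coefficient covariance is the inverse observed information (numeric
Hessian); a singular information matrix, an all-censored stratum, or
`n < k + 2` refuses to fit rather than returning boundary estimates.
Candidate models are ranked by AICc with `n` the carcass count and `k`
every estimated coefficient including intercepts, and `select_model()`
implements the parsimony rule: among candidates within 2 AICc of the
minimum, the fewest parameters win, ties broken by lower AICc; the result
is invariant to input order.

Two summary metrics drive monitoring practice. Median persistence time is
the root of `S(t) = 0.5` (closed form per family). The average
probability of persistence over a search interval of `t` days is

$$\hat r(t) = \frac{1}{t}\int_0^t S(u)\,du,$$

computed by adaptive quadrature at absolute tolerance 1e-8; for the
exponential family the closed form `(e^mu/t)(1 - e^{-t/e^mu})` is used as
an independent cross-check in the tests (agreement to 1e-6 over
`e^mu` from 2 to 600 days). Confidence intervals are parametric
bootstrap: multivariate-normal draws of the full coefficient vector at
the fitted covariance (the log-scale link keeps every draw valid),
percentile intervals at 90%. We chose the percentile flavor; the
literature this implements does not state which flavor was used. A
covariance that is not positive semidefinite is an error — no silent
nearest-PSD repair.

## The two-stage scaling procedure

Game bird surrogates are cheap and common in monitoring, but their
carcasses are removed much faster than raptor carcasses. The scaling
procedure turns paired CPT studies into a predictive bridge.

**Analysis groups.** Studies with both bird types are aggregated until
each group has at least 8 carcasses per bird type: first across years at
the same site, then across sites within the same state and habitat
(walking sites alphabetically — a deterministic tie-break the source
material leaves open). Groups never span states. A trailing remainder
below the threshold is folded into the previously closed group of its
stratum when one exists; otherwise it is excluded with a recorded reason.

**Stage 1.** Per group and bird type, the four families are fit and the
parsimony rule applied; season is admitted as a covariate only when every
season in the group has at least 8 carcasses of that bird type. From each
selected model, `B = 1000` bootstrap coefficient draws yield `r̂` at 14,
30, 60 and 90-day intervals for each season stratum. Game bird and raptor
draws are paired by replicate index within (group, season, interval):
this preserves the marginal uncertainty of both quantities without
inventing a cross-correlation between two independently fitted models.
When neither selected model uses season, the group contributes a single
stratum labelled with its modal season.

**Stage 2.** The pairs feed a linear mixed-effects model on the logit
scale:

$$\mathrm{logit}(\hat r_{raptor}) = \beta_0 + \beta_1\,\hat r_{gamebird}
+ \text{season} + \text{Region} + \text{habitat}
+ (b_0 + b_1\,\hat r_{gamebird} \mid \text{group}),$$

with probabilities clipped to `[1e-6, 1 - 1e-6]` before the transform
(bootstrap draws can hit 1 for long-persisting strata; the clip keeps the
response finite with negligible distortion). Candidates are the eight
subsets of {season, Region, habitat}, always including the game bird
slope and never interactions; all candidates are fit by maximum
likelihood — not REML — because AICc comparisons across different fixed
effects require it, and the winner is reported from the same ML fit. The
intra-class correlation is reported as
`sd_intercept^2 / (sd_intercept^2 + resid_sd^2)` and always printed with
its formula, because the ICC is ambiguous under a random slope; we do not
attempt to match any particular published ICC value.

`predict_raptor()` applies the fixed effects (plus a group's BLUPs when
the group was in the training data) and inverse-logit. Prediction
intervals simulate fixed-coefficient uncertainty and, for new groups, the
random-effect law. `reference_scaling_model()` ships the published
national-scale coefficients so practitioners can scale site-specific game
bird estimates without refitting.

**Cross-validation.** `stratified_splits()` builds training/hold-out
partitions stratified by Region × habitat: singleton cells always train
(the refit model must see every level), multi-group cells contribute at
least one random training group, and groups are added until the training
fraction is as close to 52% as the constraints allow. Each split uses an
independent child seed, so requesting more splits never changes earlier
ones. Hold-out groups are scored with fixed effects only — they are new
to the refit model by construction — against their own Stage-1 point
estimates, with RMSE, Pearson correlation, proportion of predictions
exceeding the hold-out value, and mean absolute error.

## The synthetic-data generator

`simulate_meta_dataset()` builds datasets in which the scaling relation
is known. Per group: a game bird removal law is drawn (default Weibull,
`mu` uniform on log(3)–log(40) days, `sigma` uniform on 0.7–1.2, spanning
the 2–48 day game bird medians seen in large-bird persistence data); its
true `r̂` values at the anchor intervals are computed by the same
quadrature the estimation side uses; raptor targets follow the
logit-linear relation with group-level random effects and a
per-(group, interval) residual; and the raptor removal law is the
*Weibull matched to those targets* by least squares on the logit scale.
Keeping the generating law inside the candidate family class matters: an
earlier design that hit the targets exactly with a piecewise-exponential
law made every Stage-1 raptor fit misspecified and biased the recovered
Stage-2 slope upward by about a standard error; with the matched-Weibull
design the full pipeline recovers the generating slope within sampling
error. The (small) lack of fit to the four targets behaves as extra
residual noise and is recorded in the truth ledger (`match_loss`,
realized `r_raptor`).

The generator's scaling-truth defaults are the published national-scale
model (intercept −0.66, slope 4.19, the published season/Region/habitat
offsets, group dispersions 0.53 and 2.32, residual 0.29); the check
protocol defaults to the modal CPT schedule (days 1–4, 7, 10, 14, 21, 28,
then weekly to 56). What the generator does *not* emulate: scavenger
behavior (visit processes, species), carcass-mass effects, inter-annual
variation, check-day jitter, or correlation between the two bird types'
removal processes at a site. Passing tests therefore demonstrate that the
inference chain recovers known truth under its own assumptions — not that
those assumptions hold in any particular field dataset.

## Numerical and design notes

- All stochastic operations take explicit integer seeds; there is no
  hidden global state carried between calls.
- Treatment coding uses only observed factor levels (canonical order), so
  unbalanced meta-data stay full rank; a design-matrix column that is
  all zero (an unsampled level combination) makes that candidate
  inadmissible, and predictions are refused for unobserved levels by
  name. Estimate tables are emitted only for sampled strata.
- Interactions in the survival candidate grid are limited to two-way;
  three-way grids explode combinatorially and published winning models
  report only two-way terms.
- The ≥ 8 carcass threshold is enforced where the procedure uses it
  (group construction, season admissibility, the meta pipelines);
  `fit_icsurv()` itself only refuses all-censored input and `n < k + 2`,
  so small camera-precise cells remain fittable directly.
- Quadrature tolerance 1e-8 (absolute); median closed forms verified
  against numeric root-finding to 1e-6; logit/inverse-logit round-trip to
  1e-12 away from the clipped boundary.
- Test problem sizes: family recovery uses 100 cells of n = 500 per
  family; bootstrap calibration uses 1000 coverage trials (the coverage
  estimate's binomial noise is then ~1%); the end-to-end scaling recovery
  runs 3 replicates of 30 groups × 20 carcasses per bird type at B = 200.
  These sizes were chosen so that Monte-Carlo noise is small relative to
  the tolerances being asserted.

## Known limitations

- No semiparametric (Cox) alternative, left-truncation, or frailty terms;
  no continuous covariates such as carcass mass or temperature.
- The Stage-2 response treats bootstrap replicates as observations, as
  the two-stage procedure prescribes; AICc computed on those rows is
  liberal about including fixed effects, which is why the parsimony rule
  and the validation step matter. Offsets much smaller than the
  group-level dispersion (the published season offsets, for instance) are
  not reliably detectable at realistic group counts.
- Predictions for a Region or habitat absent from the fitted data are
  refused rather than extrapolated.
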