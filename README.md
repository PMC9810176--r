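# cptscale

Carcass persistence trial analysis and game bird → raptor persistence
scaling for post-construction fatality monitoring (PCFM) at wind energy
facilities.

## The problem

Fatality rates at wind facilities are estimated from carcass searches
corrected for imperfect detection. One detection component is carcass
persistence: a carcass can be scavenged or otherwise removed before the
next search. Persistence is measured with carcass persistence trials
(CPT) — fresh carcasses are placed in the field and checked on a schedule,
so the removal time of each carcass is known only to an interval
`[last_present, first_absent)`, or exceeds the trial length
(right-censored). Most monitoring programmes run CPT with pen-raised game
birds (pheasants, ducks), but raptor carcasses persist substantially
longer than game bird carcasses, so raptor fatality estimates built on
game bird persistence are biased high. `cptscale` implements the full
inference chain that quantifies this bias and corrects for it:

1. **Interval-censored survival regression.** Removal times follow a
   log-location-scale family — exponential, Weibull, log-logistic, or
   lognormal, `T = exp(mu + sigma * W)` — with categorical covariates
   (season, habitat, USFWS Region) on the location `mu` and on
   `log(sigma)`. The likelihood is `prod_i [S(L_i) - S(R_i)]` over the
   removal intervals. Candidates are ranked by small-sample-corrected AIC,
   and the most parsimonious model within 2 AICc points of the best is
   selected.

2. **Persistence metrics.** For a search interval of `t` days, the average
   probability of persistence is the time-average of the survival
   function,

   r̂ = (1/t) ∫₀ᵗ S(u) du,

   the persistence component of detection probability. Median persistence
   time is `S(t) = 0.5`. Uncertainty comes from a parametric bootstrap:
   multivariate-normal draws of the coefficient vector, percentile 90%
   intervals on the derived quantities.

3. **Two-stage scaling.** Studies with both bird types are aggregated into
   *analysis groups* (≥ 8 carcasses per bird type; same site, else same
   state and habitat). Stage 1 fits each group's survival models and draws
   bootstrap pairs of (game bird r̂, raptor r̂) at 14/30/60/90-day
   intervals. Stage 2 fits a logit-linear mixed-effects model

   logit(r̂_raptor) = β₀ + β₁ · r̂_gamebird + season + Region + habitat
   + (b₀ + b₁ · r̂_gamebird | analysis group),

   selected by the same AICc parsimony rule, giving a predictive bridge
   from site-specific game bird persistence to raptor persistence.

4. **Validation.** Random stratified cross-validation (singleton
   Region × habitat cells always train) with four out-of-sample metrics:
   RMSE, Pearson correlation, proportion of predictions exceeding the
   hold-out estimates, and mean absolute error.

A synthetic-data generator (`simulate_meta_dataset()`) produces trial
records with known ground truth — including a known logit-linear scaling
relation with group-level random effects — so every stage is testable
without any field data.

## Worked example

Predict raptor persistence for a facility in Region 3 cropland with only
game bird trial data, using the published national-scale scaling model
shipped with the package:

```r
library(cptscale)

model <- reference_scaling_model()
predict_raptor(model, gamebird_r = 0.31,
               season = "fall", region = "R3", habitat = "cropland")
#> [1] 0.7249002
```

A 30-day game bird average probability of persistence of 0.31 scales up to
a raptor average probability of persistence of 0.72: the raptor carcass is
far more likely than the game bird surrogate to still be present when the
next search happens, so using 0.31 directly would overstate raptor
fatalities.

Fitting your own trial data:

```r
trials <- read_trials("trials.csv")          # one row per carcass
obs    <- make_intervals(trials)             # [L, R) removal intervals
fit    <- select_model(lapply(
  candidate_grid("habitat", allow_interactions = FALSE),
  function(spec) fit_icsurv(spec, obs[obs$bird_type == "gamebird", ])))
persistence_estimate(fit, cell = list(habitat = "shrub_scrub"),
                     intervals = c(30, 60, 90), n_boot = 1000)
```

and the full two-stage pipeline on a multi-study dataset:

```r
groups <- build_analysis_groups(summarize_studies(trials))
pairs  <- stage1_pairs(groups, trials, B = 1000, seed = 1)
scale  <- fit_scaling(pairs)
cv     <- cross_validate(pairs, groups, scale$fixed_terms, n_sets = 10, seed = 1)
```

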