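---
title: "The metabolic dysbiosis score: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The metabolic dysbiosis score: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdscore)
```

## The model

The metabolic dysbiosis score (MDS) summarizes a panel of fecal
metabolite concentrations into one integer per patient. Let $x_{ij}$ be
the concentration of metabolite $j$ in patient $i$, and let $y_i \in
\{0,1\}$ indicate 30-day nonsurvival. Each metabolite gets a cutpoint
$(c_j, d_j)$ — a threshold and a direction — chosen on the training
cohort to maximize the Youden index

$$J = \mathrm{sens} + \mathrm{spec} - 1$$

over candidate thresholds placed at midpoints between consecutive
distinct observed values, with the *point side* oriented toward
nonsurvivors. The binary point matrix is $p_{ij} = 1$ iff $x_{ij}$ lies
on the nonsurvivor side of $(c_j, d_j)$, and the score at model size $k$
is $S_i^{(k)} = \sum_{j \in \text{top-}k} p_{ij}$, where the inclusion
order is by decreasing $|\beta_j|$ from a cross-validated logistic ridge
regression of $y$ on the standardized point matrix. Each iteration
re-optimizes a Youden threshold on the integer scores (candidate
thresholds are therefore half-integers), and the final model is the
smallest $k$ whose objective is within a tolerance of the best.
*Dysbiosis* is declared when $S_i >$ threshold, and evaluated against
30-day mortality with Kaplan-Meier curves, log-rank tests, RMST
differences at $\tau = 30$ days, and Cox proportional-hazards models
adjusted for comorbidity (CCI) and organ failure (SOFA), with
likelihood-ratio p-values and Schoenfeld diagnostics.

## Assumptions

- **Administrative 30-day horizon.** Survivors are censored exactly at
  day 30 and the mortality label coincides with the event indicator;
  RMST always uses $\tau = 30$ days (the study horizon), so all group
  contrasts are interpretable as days of survival gained within the
  first month.
- **Thresholdable signal.** The score presumes each informative
  metabolite's association with outcome is reasonably monotone on one
  side of a threshold; smooth nonmonotone relationships are not
  representable.
- **Proportional hazards** for the Cox summaries, checked (not assumed)
  via the scaled-Schoenfeld test.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `train_fraction` | 0.75 | — | reproduces a 147/49 split of 196 patients under largest-remainder stratified rounding |
| `max_missing_frac` | 0.20 | fraction | metabolites missing in *more than* 20% of patients are dropped (strict inequality: exactly 20% is retained) |
| `donors` (PMM) | 5 | patients | common predictive-mean-matching default; single imputation |
| `n_boot` | 10 | replicates | stratified bootstrap for cutpoint *stability reporting only*; the deployed threshold is always the full-sample optimum |
| `tolerance` | 0.01 | objective units | parsimony margin for "simplest but best-performing" |
| `objective` | `"auc"` | — | see design choices |
| `tau` | 30 | days | study horizon |
| `ties` (Cox) | `"efron"` | — | standard default for tied event days |

## The synthetic-data generator

`generate_cohort()` produces the world the analysis assumes: integer
CCI (Poisson, mean 4.5, capped at 15) and SOFA (Poisson, mean 8, capped
at 24); a 30-day mortality label from a logistic model on centred
CCI/SOFA whose intercept is calibrated so the marginal rate equals
`mortality_rate` (default 0.306, the cohort rate the score was built
for); death days uniform on $\{1,\dots,30\}$ (the event-time
distribution is otherwise unspecified; an exponential option with a
planted hazard ratio on a latent risk group exists for Cox-recovery
checks); log-normal concentrations (log-sd 1.0 — strictly positive and
right-skewed like real panels) in which `n_informative` metabolites have
group log-medians separated by `effect_log2fc` log2 units, alternating
direction (some metabolites high in nonsurvivors, some low);
missing-completely-at-random gaps (the source analysis states only a
missing-fraction rule, not a mechanism); and symmetric Dirichlet(1) taxa
profiles on the 100% simplex, with the first lineage (an *Enterococcus*)
forced above 50% with probability `domination_prob`.

What a green test on this generator does **not** establish: robustness
to informative missingness, inter-metabolite correlation (independence
by default; an equicorrelation knob `rho` exists but the real
correlation structure is unreported), batch effects, non-log-normal
concentration shapes, or event-time distributions other than the two
implemented. Conclusions from synthetic recovery experiments are about
the machinery, not about any clinical cohort.

## Numerical choices, tie-breaks, degenerate inputs

- **Cutpoint candidates** are midpoints between consecutive distinct
  values. Midpoints are scale-respecting and explain half-integer
  score thresholds; whether published per-metabolite thresholds were
  midpoints or observed values is unknowable from summary tables.
- **Youden ties** break toward higher specificity, then the lower
  threshold (deterministic; favours fewer false positives). Both
  directions are scanned — on midpoint candidates
  $J_{\text{low}}(t) = -J_{\text{high}}(t)$, so this equals exhaustive
  search — and an exact cross-direction tie resolves toward the
  direction with oriented AUC ≥ 0.5.
- **Constant metabolites** yield a degenerate cutpoint ($J = 0$, no
  threshold) and score no points; constant point-matrix columns are
  dropped from the ridge fit with a warning and ranked last with zero
  importance.
- **log2 fold changes** use per-group medians (survivors over
  nonsurvivors); a pooled median would yield no contrast. When a group
  median is zero, half the smallest positive observed value of that
  metabolite is added to both medians.
- **Exact equality at a threshold** (possible only for user-supplied
  thresholds) lands on the point side (`>=` for high direction, `<=`
  for low).
- **Rank-sum tests** are exact (Mann-Whitney distribution; full
  permutation enumeration under ties when feasible) below 50 per group,
  else tie-corrected normal approximation with continuity correction.
- **2x2 tables** always get the Yates continuity correction: the
  published small-count rows (e.g. a carbapenem row reproducing
  p = 0.968) recompute correctly only under correction.
- **Cox fits** center covariates, iterate Newton steps with
  step-halving to a gradient norm below 1e-9 (max 100 iterations), and
  flag |coef| > 15 as probable separation. Per-covariate p-values are
  likelihood-ratio refits, not Wald.
- **PH testing** follows the classic Grambsch-Therneau score form:
  Efron-adjusted Schoenfeld residuals, scaled by the fit covariance,
  correlated with the left-continuous KM transform of event time.
  Recent `survival::cox.zph` uses a refined curvature computation, so
  the two agree in calibration and power but not to machine precision;
  tests assert the distributional properties.
- **Shannon index** uses the natural log (ecology default; base is an
  argument), after renormalizing each profile to proportions.
- **Domination** is a strict `>` comparison, matching the published
  "(>19.9%)" / "(>2.5%)" notation.

## Design choices made where the design was open

- **Inclusion order** is by *decreasing* |β| (most important first):
  descriptions of the assembly order conflict in the source material,
  and importance-first produces the monotone early improvement that
  iterative panels display.
- **Selection objective** defaults to AUC with tolerance 0.01, not
  accuracy. On the generator's planted-recovery world (50 seeds,
  n = 1000, five planted metabolites, effect 2 log2 units) the
  acceptance suite asserts that AUC-based selection recovers the full
  planted set in at least 90% of replicates; accuracy-based selection
  was measured to fall well short of that bar. The reason: accuracy is
  evaluated at a re-optimized Youden threshold, and under ~30%
  prevalence it is nearly flat across neighbouring model sizes, so the
  last planted metabolite's contribution regularly falls inside the
  tolerance. AUC is threshold-free and orders models reliably;
  `objective = "accuracy"` remains available.
- **Ridge regression is logistic** (binomial deviance), since the
  outcome is binary; a `"gaussian"` switch exists. Penalty strength is
  the CV-deviance minimum over a 30-point logarithmic grid with
  seed-deterministic folds; the point columns are standardized first so
  |β| is comparable across prevalence.
- **Per-iteration thresholds are re-optimized** (rather than fixing one
  threshold for all k): each iteration is a complete candidate model.
- **Single imputation** (not multiple-imputation pooling): downstream
  analyses are single tables, not pooled estimates.
- **Wilson intervals** for the binomial performance CIs: the
  alternative normal-approximation interval can exceed 1, a pathology
  visible in some published performance tables we deliberately do not
  replicate.
- **Train/validation imputation is separated**: each side is imputed
  from its own complete cases, so no validation value can influence any
  training-side estimate (the test suite asserts this hygiene by
  perturbing validation rows and checking the fitted model is
  byte-identical).

## Known limitations

- The iterative assembly inherits ridge's behaviour under correlated
  predictors: coefficient sharing can split importance across covarying
  metabolites and admit a covarying proxy into the model.
- Training-cohort Cox hazard ratios for the dichotomized score are
  optimistic (the threshold was optimized on the same patients) and can
  be infinite under complete separation; validation-cohort estimates
  are the honest ones.
- The exact two-sided permutation p-value under ties uses the
  |U − E[U]| ordering; other defensible orderings (e.g. doubling the
  smaller tail) differ in the third decimal on tiny samples.
- No competing risks, time-varying covariates, or multiple-imputation
  variance propagation.
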