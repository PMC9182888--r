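---
title: "From dietary patterns to frailty through the plasma metabolome: methods"
author: "dietmetab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From dietary patterns to frailty through the plasma metabolome: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietmetab)
```

## The analysis chain

`dietmetab` implements a complete observational-nutrition analysis chain for
older-adult cohorts: food-frequency-questionnaire-derived intake tables are
scored against three a priori dietary patterns (MDS, MIND, AHEI-2010); a
44-item deficit-accumulation frailty index (FI) summarizes health status; a
targeted plasma metabolomics panel is quality-controlled and standardized;
per-metabolite covariate-adjusted regressions with false-discovery-rate
control screen for diet-associated metabolites; a cross-validated
elastic-net ensemble with permutation-null feature significance distills a
*metabolomic diet score* (metDS); and a nonparametric-bootstrap mediation
decomposition asks how much of the diet-frailty association travels through
the metabolome.

Every stage is exercised end to end on a seeded synthetic cohort generator
with planted ground truth, so the whole chain is testable without access to
any restricted cohort data.

## Diet scores

Three adherence scores with different constructions are supported, each
driven by an editable YAML rubric (`load_rubric()`); serving cutoffs and
anchors are data, not code, because published implementations differ in
their appendix-level details.

* **MDS** (0-9): nine components scored 0/1 against *within-sample medians*
  of visit-averaged intake. Beneficial components (vegetables, legumes,
  fruits/nuts, whole grains, fish, MUFA:SFA ratio) score 1 at or above the
  median — ties at the median count as "at or above"; detrimental
  components (meat, dairy) score 1 below it; alcohol scores 1 inside a
  moderate window (defaults 5-25 g/day for women, 10-50 g/day for men,
  exposed in the rubric because the source instruments differ).
* **MIND** (0-15): fifteen food groups scored 0 / 0.5 / 1 against fixed
  weekly (or daily) serving cutoffs; wine is window-scored with full credit
  near one glass per day. Potatoes are excluded from the other-vegetables
  group.
* **AHEI-2010** (0-110): eleven components scored proportionally 0-10 by
  linear interpolation between anchors, clamped outside them; sodium uses
  fixed anchors approximating intake deciles; alcohol is window-scored with
  a nonzero abstainer score (2.5) and sex-specific windows.

Visit handling follows the instrument semantics: energy-implausible visits
(outside the closed interval 600-4800 kcal/day) are removed first; MIND and
AHEI are scored per visit and averaged within participant; MDS is scored
once on visit-averaged intake so that the median cutoffs are defined on one
row per participant. The energy bounds are read as inclusive — a
conservative retention choice at the boundary.

`extreme_profile()` builds full-credit and zero-credit intake rows from any
rubric, which is how the package audits attainable score ranges (9, 15 and
110 with the shipped rubrics).

## Frailty index

The FI is the mean of 44 deficits, each mapped to [0, 1] by an editable
`deficit_map`: 15 ADL/IADL difficulty items and self-rated health on an
ordinal five-level grid {0, 0.25, 0.5, 0.75, 1}; five depression-scale
items, four cognition items and fifteen condition indicators as binaries;
and four within-sample threshold deficits — slowness (lowest walking-speed
quintile, stratified by sex and a sex-specific height median split),
weakness (lowest grip quintile, stratified by sex and sex-specific BMI
quartiles), low physical activity (lowest cohort quartile) and weight loss
of at least 5% of prior-year weight (boundary inclusive). Percentile ties
flag the deficit (the "lowest quintile" reading); strata smaller than five
fall back to a pooled cutoff with a warning. The ordinal codings are
declared approximations: the instruments' exact appendix-level schemes are
cohort-specific, so the map ships as editable configuration.

The index is reported only when fewer than 20% of items are missing, and
the denominator is always the count of items actually present — a
participant with 8 of 44 items missing and 9 deficits among the 36 present
has FI = 0.25, while 9 missing items (20.45%) suppress the index.

## Metabolite preparation

Quality control runs in a fixed order: values strictly below the
per-metabolite limit of detection become missing (values equal to the LOD
are kept); metabolites with more than 30% missingness are removed (exactly
30% is kept); remaining gaps are imputed at half the minimum *observed*
value of the metabolite — the standard below-LOD convention; concentrations
are then log-transformed (default on, since lipid panels are right-skewed;
a pseudo-count of half the smallest positive value is added only when zeros
are present) and z-scored per metabolite with the sample (n-1) standard
deviation. Zero-variance metabolites are dropped with a warning. Whether
the original analyses log-transformed concentrations is not documented, so
the transform is a flag (`log_transform`) rather than a constant.

## Association scan

Each metabolite is screened with ordinary least squares using the diet
score as the dependent variable and the standardized metabolite as the
independent variable, adjusted for age, sex (coded female = 0, male = 1),
eGFR and visit-averaged energy intake. The scan residualizes the scores
and all metabolites on the covariate block once (Frisch-Waugh), which is
algebraically identical to refitting the full model per metabolite and is
what makes metabolome-wide scans cheap. Missing covariates are handled by
complete-case deletion with counts retained. Benjamini-Hochberg adjustment
is applied within each diet score by default (`fdr_scope = "pooled"` is
available; which scope the original analysis used is not documented), and
significance is declared at q <= 0.05. The scan reports per-score
significant counts and the all-score intersection.

## Elastic-net signature and the metabolomic diet score

For each diet score, `enet_signature()` fits the penalized regression

$$\frac{1}{2n}\lVert y - \beta_0 - X\beta\rVert_2^2 +
  \lambda\left(\alpha\lVert\beta\rVert_1 +
  \frac{1-\alpha}{2}\lVert\beta\rVert_2^2\right)$$

along a 100-value log-spaced penalty path (down to 1% of the all-zero
penalty — enough depth for model selection without the numerical cost of
deeper paths). The path solver is glmnet; because glmnet internally
rescales the response by its root-mean-square — which silently divides the
effective ridge penalty by sd(y) while leaving the lasso penalty untouched
— every call is reparameterized so that the objective above holds exactly
on the stated scale (the package's solver tests check the Karush-Kuhn-Tucker
conditions of this objective to 1e-6 and the ridge and orthonormal-lasso
closed forms to 1e-6/1e-8).

The penalty is chosen by an ensemble: each of `n_runs` runs randomly
assigns observations to `n_folds` folds, fits the path on each training
complement, pools the held-out predictions within the run, and scores each
penalty by the Pearson correlation (quality function, QF) between pooled
out-of-bag predictions and the observed response; the per-run QF values
are averaged across runs and the penalty maximizing the mean QF wins. The
mixing parameter is scanned over a grid (default 0 to 1 in steps of 0.1,
ties broken toward the more ridge-like value, with automatic refinement at
0.01-0.09 when the winner is at or below 0.1), and the best alpha is the
one whose best mean QF is largest.

Feature significance comes from a permutation-null ensemble: `n_null`
models are trained on randomly permuted responses (identity permutations
excluded), and each feature's mean coefficient magnitude and nonzero
frequency across run-by-fold models are compared against their null
distributions with add-one empirical p-values, p = (1 + #{null >= observed})
/ (1 + n_null). Two deliberate design choices here:

* **Null statistics are taken at the observed model's optimal penalty**
  (`freeze_lambda_null = TRUE`). Re-optimizing the penalty inside each null
  model drives every null to the dense end of the path — on a permuted
  response the mean out-of-bag QF rises monotonically toward weak
  regularization, because sparse out-of-bag predictions are training-fold
  means, which correlate *negatively* with held-out values — and a dense
  null saturates every frequency at 1. Freezing compares observed and null
  ensembles at matched sparsity. Re-optimization remains available as a
  flag.
* **Selection is decided by the coefficient p-value** (`significance_rule =
  "coef"`); the frequency p-value is always reported but not required. At
  the ridge end of the mixing grid every feature is active in every model,
  so observed and null frequencies are identically 1 and a conjunction rule
  can never select anything there — and a ridge-optimal mixing value is a
  realistic outcome for dense metabolomic signal. `"both"` and `"either"`
  are available for sensitivity analyses.

The metabolomic diet score is then the coefficient-weighted sum of the
selected standardized metabolites, metDS_i = sum_j w_j X_ij, with weights
equal to the mean ensemble coefficients at the optimal (alpha, lambda).
`variance_explained()` reports the squared (optionally covariate-partial)
correlation between metDS and the observed score. If no metabolite is
selected the metDS is undefined and the pipeline halts with an explicit
message rather than emitting a zero score.

## Mediation

`mediate_metds()` decomposes the diet-frailty association with the
product-of-coefficients estimator under linear models without a
treatment-mediator interaction: the mediator model M = i1 + aD and the
outcome model Y = i2 + c'D + bM give ACME = ab, ADE = c', TE = ab + c'
(which equals the slope of Y on D alone — an exact algebraic identity that
the package asserts per draw at 1e-12), and PM = ACME/TE. Uncertainty is
nonparametric: rows are resampled with replacement `n_boot` times (default
500), point estimates are bootstrap means (full-sample fits are also
emitted), intervals are 2.5/97.5 percentiles, and two-sided p-values use
the add-one sign-count estimator. PM is reported both as the ratio of the
bootstrap-mean ACME and TE (the primary value — stable when TE is small)
and as the mean of per-draw ratios; the PM is flagged undefined when |TE|
is below tolerance. Covariate adjustment of both models is available but
off by default, since the core mediation concerns diet, metDS and FI; which
convention the original analysis used is not documented, so both are one
flag apart. Rank-deficient bootstrap designs are redrawn with a count.

## Synthetic cohorts and what they do (and do not) show

The generator (`generate_cohort()`) is the package's test bed, not a model
of biology; no generative model for such a cohort is documented anywhere,
so all of its choices are explicit stand-ins:

* A standard-normal latent diet-quality trait h shifts each food group's
  log-normal intake by ±0.4 log-SD (beneficial up, detrimental down). The
  per-group noise scales are calibrated once so the three downstream diet
  scores correlate near 0.6 at n = 800, the band reported for real cohorts;
  with that calibration the default cohort reproduces realistic score
  means (MDS ≈ 4.3, MIND ≈ 8, AHEI ≈ 56-60) without any tuning to outputs.
* Metabolites are block-correlated through 10 shared cluster factors
  (within-block correlation 0.6); 30 planted metabolites add 0.3·h.
  Concentrations are log-normal; LODs sit at each metabolite's 2nd
  percentile (35th for a 5% subset engineered to fail the missingness
  filter), mimicking detection limits without modelling instrument physics.
* Frailty items are generated item-wise — 44 Bernoulli/ordinal draws from a
  logistic propensity α_j + θ_D·h + θ_M·m̄, where m̄ is the mean of the
  standardized planted metabolites — so the frailty-index module is
  exercised on realistic inputs rather than on a pre-made index. The
  threshold items (walking speed, grip, activity, weight change) are
  continuous measures shifted along the same propensity. Defaults θ_D =
  −0.30 and θ_M = −0.40 put the baseline FI near 0.1 with a maximum around
  0.4, matching an ambulatory research cohort of adults 65 and older.
* Visits (1-3 per participant) carry independent noise; 3% of visits are
  forced outside the energy-validity window; energy is normal(2000, 500)
  truncated to [300, 5500] so both filter tails occur.

`oracle_proportion_mediated()` regenerates the mediation-relevant pieces at
n = 100,000 and fits the two mediation regressions by exact least squares;
because the outcome-model coefficients are proportional to θ_D and θ_M
through a common logistic-slope factor, the analytic value
a·θ_M / (a·θ_M + θ_D) with a = γ/√(1+γ²) agrees with the empirical oracle
to ~0.01, and both are exposed (the analytic value in the cohort's truth
record, the empirical one on demand).

Passing tests on these cohorts demonstrate internal correctness and
statistical calibration (type-I control, effect recovery, interval
coverage) — they do not demonstrate that any particular real-world cohort
satisfies the generator's assumptions of log-normal intakes, a
single-factor diet trait, or exchangeable block-correlated metabolites.
Batch effects, longitudinal trajectories and instrument drift are
explicitly out of scope.

## Numerical choices and problem sizes

Desk-scale defaults used by the package's own test suite: cross-validation
ensembles are reduced (tens of runs, tens of nulls, a handful of runs per
null) and synthetic cohorts span 150-800 participants and 40-466
metabolites; the calibration suites use 20-500 replicates depending on the
cost per replicate. Full-cohort analyses use the published-scale defaults
(500 runs, 125 nulls, the 0-1 alpha grid with refinement). Other fixed
choices: solver tolerance 1e-12 for the reference path and glmnet's default
for ensemble fits; QF values undefined at a penalty (constant predictions)
are excluded with a count; alpha ties break toward ridge; percentile
bootstrap intervals; add-one empirical p-values everywhere a permutation or
bootstrap null is compared.

## Known limitations

* Rubric and deficit-map defaults are transcriptions of the cited
  instruments, not byte-exact replicas of any cohort's implementation;
  both are editable configuration for that reason.
* The mediation estimator is associational: without sequential
  ignorability its causal reading is not identified, and no sensitivity
  analysis is provided.
* A data-driven mediator composite optimized to predict the treatment
  (the metDS) partially absorbs the direct path in the outcome model, so
  its proportion mediated tends to read high relative to the mediated
  share of any planted ground truth; the synthetic oracle makes this
  visible, and the same caution applies on real data.
* The elastic-net engine is linear/Gaussian only.
* The synthetic generator draws independent visit noise and therefore does
  not emulate within-person longitudinal trajectories.
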