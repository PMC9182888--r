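# dietmetab

Tools for asking how habitual diet relates to frailty in older adults
through the plasma metabolome. The package is aimed at nutritional
epidemiologists and biostatisticians working with food-frequency-derived
intake tables, targeted metabolomics panels (e.g. Biocrates-style
concentration matrices with limits of detection), and deficit-accumulation
frailty phenotypes.

## What it computes

* **Dietary pattern scores** — Mediterranean diet score (MDS, 0–9,
  within-sample median splits), MIND (0–15, three-level serving cutoffs)
  and AHEI-2010 (0–110, proportional 0–10 anchors), from editable YAML
  rubrics, with energy-validity filtering (600–4800 kcal/day) and
  multi-visit averaging.
* **Frailty index** — the 44-item deficit-accumulation index
  FI = (sum of deficit scores) / (items present), with within-sample
  threshold deficits (slowness, weakness, low activity, ≥5% weight loss)
  and the <20% missing-items validity rule.
* **Metabolite QC** — below-LOD censoring, removal of metabolites with
  >30% missingness, half-minimum imputation, log transform and z-scoring.
* **Association scan** — per-metabolite OLS of each diet score on the
  standardized metabolite, adjusted for age, sex, eGFR and energy, with
  Benjamini–Hochberg FDR within score (significant at q ≤ 0.05).
* **Metabolomic diet score (metDS)** — a cross-validated elastic-net
  ensemble minimizing
  `(1/2n)‖y − β₀ − Xβ‖² + λ(α‖β‖₁ + (1−α)/2‖β‖²)`
  over a 100-value penalty path; the penalty maximizes the mean
  out-of-bag Pearson correlation over repeated random 5-fold runs, the
  mixing parameter α is scanned over a grid, features are kept when their
  ensemble coefficients beat a permutation-null ensemble (add-one
  empirical p-values), and metDS_i = Σ_j w_j X_ij over the selected
  metabolites.
* **Mediation** — the product-of-coefficients decomposition of the
  diet→FI association through the metDS (ACME = ab, ADE = c′,
  TE = ab + c′, PM = ACME/TE) with nonparametric bootstrap intervals and
  p-values.
* **Synthetic cohorts** — a seeded generator with a latent diet-quality
  trait, block-correlated metabolites with planted diet effects, and
  item-wise frailty deficits carrying both a direct and a
  metabolite-mediated diet path, plus a large-sample oracle for the true
  proportion mediated.

## Worked example

```r
library(dietmetab)

cohort <- generate_cohort(synth_config(n_participants = 300, seed = 11))
ds   <- diet_scores(cohort$intake, cohort$phenotypes)
fi   <- compute_fi(derive_threshold_deficits(cohort$phenotypes))
prep <- prepare_metabolome(cohort$metabolome)

common <- intersect(prep$participant_id, ds$participant_id)
X <- prep$values[match(common, prep$participant_id), ]
y <- ds$mds[match(common, ds$participant_id)]

sig <- enet_signature(X, y, enet_config(alpha_grid = c(0, 0.5, 1),
                                        n_runs = 20, n_null = 20,
                                        n_runs_null = 5, seed = 3))
print(sig)
#> <enet_signature> n = 296, 443 features
#>   alpha* = 0.5, lambda* = 0.2077, OOB QF = 0.449
#>   selected features: 25; metDS ~ response r^2 = 0.361

fi_v <- fi$fi[match(common, fi$participant_id)]
med <- mediate_metds(y, sig$metds, fi_v, n_boot = 500, seed = 5)
print(med)
#> <mediation_fit> n = 296, 500 bootstrap draws
#>  quantity  estimate    ci_low   ci_high           p
#>      ACME -0.010270 -0.013180 -0.007859 0.003992016
#>       ADE -0.004691 -0.008161 -0.001126 0.019960080
#>        TE -0.014960 -0.018060 -0.011660 0.003992016
#>        PM  0.686600  0.520900  0.907900 0.003992016
```

Reading the output: the ensemble picked mixing parameter α = 0.5 with an
out-of-bag correlation of 0.45 between predicted and observed MDS; 25
metabolites beat the permutation null at the 0.05 level — 9 of the 30
metabolites this synthetic cohort plants, plus a false-positive share in
line with the nominal level across the 413 null metabolites. The
mediation table says a one-point higher MDS is associated with a 0.0150
lower frailty index in total (TE), of which 0.0103 flows through the
metabolomic diet score (ACME), a proportion mediated (PM) of 0.69. The
generator's large-sample oracle for the *planted* mediated share is 0.276
(`oracle_proportion_mediated()`): a signature optimized to predict the
diet score absorbs part of the direct path too, so its PM reads as an
upper estimate — the same caution that applies to any data-driven
mediator composite.

The whole chain, with all artifacts written as TSV/JSON, is one call:

```r
run_pipeline(pipeline_config(out_dir = "out", seed = 7))
```

or from a shell via the thin wrapper
`inst/scripts/dietmetab-pipeline.R` (subcommands `synth`, `validate`,
`run-all`).

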