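test_that("identical configurations generate bit-identical cohorts", {
  cfg <- synth_config(n_participants = 60, n_metabolites = 40,
                      n_planted = 5, seed = 1)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$intake, b$intake)
  expect_identical(a$metabolome$values, b$metabolome$values)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$truth, b$truth)
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(n_participants = -5), "integer")
  expect_error(synth_config(n_participants = 10.5), "integer")
  expect_error(synth_config(n_planted = 50, n_metabolites = 40),
               "n_planted")
  expect_error(synth_config(intra_cluster_rho = 1), "intra_cluster_rho")
  expect_error(synth_config(lod_fraction = 1.2), "lod_fraction")
})

test_that("truth record reflects the planted structure", {
  cfg <- synth_config(n_participants = 50, n_metabolites = 40,
                      n_planted = 6, seed = 2)
  co <- generate_cohort(cfg)
  expect_length(co$truth$planted, 6L)
  expect_true(all(co$truth$planted %in% colnames(co$metabolome$values)))
  expect_true(co$truth$oracle_pm >= 0 && co$truth$oracle_pm <= 1)
  # no mediated path -> proportion mediated exactly zero
  co0 <- generate_cohort(synth_config(n_participants = 50,
                                      n_metabolites = 40, n_planted = 0,
                                      path_mediated = 0, seed = 3))
  expect_identical(co0$truth$oracle_pm, 0)
  expect_identical(oracle_proportion_mediated(
    synth_config(n_planted = 0, path_mediated = 0, seed = 3)), 0)
})

test_that("default cohorts yield positively correlated diet scores in the calibration band", {
  co <- generate_cohort(synth_config(seed = 7))
  ds <- suppressWarnings(diet_scores(co$intake, co$phenotypes))
  cors <- c(cor(ds$mds, ds$mind), cor(ds$mds, ds$ahei),
            cor(ds$mind, ds$ahei))
  expect_true(all(cors > 0.3))
  expect_true(all(cors < 0.8))
})

test_that("generated tables respect the configured injection rates", {
  cfg <- synth_config(n_participants = 400, n_metabolites = 60,
                      invalid_energy_fraction = 0.1, seed = 5)
  co <- generate_cohort(cfg)
  bad <- co$intake$energy_kcal < 600 | co$intake$energy_kcal > 4800
  expect_gt(mean(bad), 0.08)
  expect_lt(mean(bad), 0.15)
  co2 <- generate_cohort(synth_config(n_participants = 400,
                                      n_metabolites = 60,
                                      drop_fraction = 0.1, seed = 6))
  expect_length(co2$truth$dropped_by_design, round(0.1 * 60))
  # metabolites engineered to exceed the missingness threshold do get
  # dropped downstream, and planted metabolites survive
  prep <- prepare_metabolome(co2$metabolome)
  expect_true(all(co2$truth$dropped_by_design %in%
                    prep$dropped$metabolite))
  expect_true(all(co2$truth$planted %in% colnames(prep$values)))
})

test_that("large-sample mediation oracle matches analytic product of coefficients", {
  # theta_D chosen so that ab/(ab + c') = 0.5 analytically:
  # a = gamma/sqrt(1+gamma^2), and b, c' are proportional to the path
  # coefficients through a common logistic slope factor
  gamma <- 0.3
  a <- gamma / sqrt(1 + gamma^2)
  th_m <- -0.4
  cfg <- synth_config(path_direct = a * th_m, path_mediated = th_m,
                      seed = 4)
  pm <- oracle_proportion_mediated(cfg, n_large = 1e5)
  expect_equal(pm, 0.5, tolerance = 0.02)
})

test_that("oracle proportion mediated hits the fully mediated limit and is monotone", {
  cfg1 <- synth_config(path_direct = 0, path_mediated = -0.4, seed = 8)
  expect_equal(oracle_proportion_mediated(cfg1, 1e5), 1, tolerance = 0.02)

  pms <- vapply(c(-0.1, -0.2, -0.4, -0.8, -1.6), function(th) {
    oracle_proportion_mediated(
      synth_config(path_mediated = th, seed = 9), 1e5)
  }, numeric(1L))
  expect_true(all(diff(pms) > -0.02))  # non-decreasing up to MC noise

  expect_error(oracle_proportion_mediated(synth_config(seed = 1), 1e4),
               "n_large")
})

test_that("null cohorts do not inflate the association scan discovery rate", {
  # no planted metabolites: the fraction declared significant at FDR 0.05
  # stays near or below the nominal level across replicate cohorts
  reps <- 20
  frac <- numeric(reps)
  for (r in seq_len(reps)) {
    co <- generate_cohort(synth_config(n_participants = 150,
                                       n_metabolites = 80, n_planted = 0,
                                       path_mediated = 0, seed = 100 + r))
    ds <- suppressWarnings(diet_scores(co$intake, co$phenotypes))
    prep <- prepare_metabolome(co$metabolome)
    res <- scan_associations(prep, ds, covars = NULL)
    frac[r] <- mean(res$significant)
  }
  mc_se <- sd(frac) / sqrt(reps)
  expect_lte(mean(frac), 0.05 + 3 * mc_se)
})
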