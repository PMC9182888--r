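#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure of a generated cohort: a latent
#' diet-quality trait shifts food-group intakes (so the three diet scores
#' computed downstream are mutually positively correlated), metabolites are
#' block-correlated with a subset "planted" on the diet trait, and frailty
#' deficits follow a logistic propensity with a direct diet path and a path
#' mediated through the planted-metabolite composite.  All generator choices
#' are stand-ins for a real cohort and are documented as such.
#'
#' @param n_participants cohort size (default 800).
#' @param n_metabolites number of metabolites (default 466).
#' @param n_planted number of diet-associated metabolites (default 30).
#' @param effect_planted standardized slope of a planted metabolite on the
#'   latent diet trait (default 0.3).
#' @param n_clusters number of correlated metabolite blocks (default 10).
#' @param intra_cluster_rho within-block correlation in \[0, 1) (default 0.6).
#' @param path_direct coefficient of the diet trait on deficit propensity
#'   (logit scale; default -0.30, i.e. better diet, fewer deficits).
#' @param path_mediated coefficient of the planted-metabolite composite on
#'   deficit propensity (default -0.40).
#' @param lod_fraction fraction of values censored below the limit of
#'   detection for ordinary metabolites (default 0.02).
#' @param drop_fraction fraction of metabolites engineered to exceed the 30%
#'   missingness threshold (default 0.05).
#' @param invalid_energy_fraction fraction of visits forced outside the
#'   600-4800 kcal validity window (default 0.03).
#' @param n_visits_range inclusive range of visits per participant
#'   (default `c(1, 3)`).
#' @param kappa intake log-scale shift per unit of the diet trait
#'   (default 0.4).
#' @param item_missing_rate missingness rate for frailty item columns
#'   (default 0.02).
#' @param seed integer random seed.
#' @return a validated `synth_config` object.
#' @export
synth_config <- function(n_participants = 800L, n_metabolites = 466L,
                         n_planted = 30L, effect_planted = 0.3,
                         n_clusters = 10L, intra_cluster_rho = 0.6,
                         path_direct = -0.30, path_mediated = -0.40,
                         lod_fraction = 0.02, drop_fraction = 0.05,
                         invalid_energy_fraction = 0.03,
                         n_visits_range = c(1L, 3L), kappa = 0.4,
                         item_missing_rate = 0.02, seed = 1L) {
  cfg <- list(
    n_participants = check_count(n_participants, "n_participants", 1L),
    n_metabolites = check_count(n_metabolites, "n_metabolites", 1L),
    n_planted = check_count(n_planted, "n_planted", 0L),
    effect_planted = as.numeric(effect_planted),
    n_clusters = check_count(n_clusters, "n_clusters", 1L),
    intra_cluster_rho = as.numeric(intra_cluster_rho),
    path_direct = as.numeric(path_direct),
    path_mediated = as.numeric(path_mediated),
    lod_fraction = check_fraction(lod_fraction, "lod_fraction"),
    drop_fraction = check_fraction(drop_fraction, "drop_fraction"),
    invalid_energy_fraction = check_fraction(invalid_energy_fraction,
                                             "invalid_energy_fraction"),
    n_visits_range = c(check_count(n_visits_range[1], "n_visits_range", 1L),
                       check_count(n_visits_range[2], "n_visits_range", 1L)),
    kappa = as.numeric(kappa),
    item_missing_rate = check_fraction(item_missing_rate,
                                       "item_missing_rate"),
    seed = check_count(seed, "seed", 0L))
  if (cfg$n_planted > cfg$n_metabolites) {
    stop_dm("n_planted must not exceed n_metabolites")
  }
  if (cfg$intra_cluster_rho < 0 || cfg$intra_cluster_rho >= 1) {
    stop_dm("intra_cluster_rho must be in [0, 1)")
  }
  if (cfg$n_visits_range[1] > cfg$n_visits_range[2]) {
    stop_dm("n_visits_range must be non-decreasing")
  }
  class(cfg) <- "synth_config"
  cfg
}

# intake column layout: log-normal baselines, log-scale shift direction per
# unit of the latent diet trait (beneficial +, detrimental -, window 0)
intake_spec <- function() {
  # log-sd values calibrated so the three downstream diet scores correlate
  # in the band reported for real cohorts (~0.6) at the default kappa
  spec <- rbind(
    c("veg_srv_d",           log(2.0),  1.0,  1),
    c("legume_srv_d",        log(0.3),  1.0,  1),
    c("fruit_srv_d",         log(1.5),  1.0,  1),
    c("wholegrain_srv_d",    log(1.2),  1.0,  1),
    c("wholegrain_g_d",      log(40),   1.0,  1),
    c("fish_srv_wk",         log(1.5),  1.2,  1),
    c("mufa_g_d",            log(25),   0.6,  0.5),
    c("sfa_g_d",             log(22),   0.6, -0.5),
    c("meat_srv_d",          log(0.8),  1.0, -1),
    c("dairy_srv_d",         log(1.5),  1.0, -1),
    c("alcohol_g_d",         log(6),    1.0,  0),
    c("green_leafy_srv_wk",  log(4),    1.2,  1),
    c("other_veg_srv_wk",    log(6),    1.0,  1),
    c("berries_srv_wk",      log(1.2),  1.4,  1),
    c("nuts_srv_wk",         log(3),    1.4,  1),
    c("oliveoil_srv_d",      log(0.8),  1.2,  1),
    c("butter_marg_srv_d",   log(1.0),  1.2, -1),
    c("cheese_srv_wk",       log(4),    1.2, -1),
    c("beans_srv_wk",        log(1.5),  1.2,  1),
    c("poultry_srv_wk",      log(1.5),  1.0,  1),
    c("redmeat_srv_wk",      log(4),    1.0, -1),
    c("fastfried_srv_wk",    log(1.5),  1.2, -1),
    c("pastries_srv_wk",     log(4),    1.2, -1),
    c("wine_srv_wk",         log(2),    1.0,  0),
    c("ssb_juice_srv_d",     log(0.5),  1.4, -1),
    c("nut_legume_srv_d",    log(0.5),  1.2,  1),
    c("red_proc_meat_srv_d", log(0.7),  1.0, -1),
    c("trans_pct_energy",    log(1.2),  0.7, -1),
    c("longchain_n3_mg_d",   log(100),  1.2,  1),
    c("pufa_pct_energy",     log(6),    0.5,  1),
    c("sodium_mg_d",         log(3000), 0.44, -1))
  data.frame(column = spec[, 1],
             log_mean = as.numeric(spec[, 2]),
             log_sd = as.numeric(spec[, 3]),
             dir = as.numeric(spec[, 4]),
             stringsAsFactors = FALSE)
}

fi_ordinal_items <- function() {
  c("adl_walk_steps", "adl_lift_carry", "adl_bed_chair", "adl_bathing",
    "adl_dressing", "adl_eating", "adl_toileting", "adl_walk_room",
    "iadl_heavy_house", "iadl_prepare_meals", "iadl_shopping",
    "iadl_telephone", "iadl_medication", "iadl_finances", "incontinence",
    "self_rated_health")
}

fi_binary_items <- function() {
  c("cesd_depressed", "cesd_effort", "cesd_get_going", "cesd_lonely",
    "cesd_not_happy", "mmse_orient_time", "mmse_orient_place",
    "mmse_attention", "mmse_recall", "cond_cancer", "cond_anemia",
    "cond_hypertension", "cond_diabetes", "cond_heart_disease", "cond_chf",
    "cond_stroke", "cond_pad", "cond_copd", "cond_ckd", "cond_hip_replace",
    "cond_joint_pain", "cond_depression", "cond_parkinsons",
    "cond_cognitive")
}

# truncated-normal draw by rejection (deterministic under the active RNG)
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

# metabolite latent scores: block factors + planted diet effect
gen_metabolome_latent <- function(n, h, config) {
  p <- config$n_metabolites
  cluster <- rep_len(seq_len(config$n_clusters), p)
  rho <- config$intra_cluster_rho
  f <- matrix(rnorm(n * config$n_clusters), n)
  x <- sqrt(rho) * f[, cluster, drop = FALSE] +
    sqrt(1 - rho) * matrix(rnorm(n * p), n)
  planted <- if (config$n_planted > 0L) {
    # evenly spread planted metabolites across blocks
    seq.int(1L, by = max(1L, p %/% max(config$n_planted, 1L)),
            length.out = config$n_planted)
  } else {
    integer()
  }
  if (length(planted)) {
    x[, planted] <- x[, planted] + config$effect_planted * h
  }
  composite <- if (length(planted)) {
    rowMeans(scale(x[, planted, drop = FALSE]))
  } else {
    numeric(n)
  }
  list(x = x, cluster = cluster, planted = planted, composite = composite)
}

metabolite_classes <- function(p) {
  vocab <- c("triglyceride", "phosphatidylcholine", "acylcarnitine",
             "amino_acid", "ceramide", "cholesterol_ester", "sphingomyelin",
             "bile_acid", "indole", "other")
  weights <- c(0.41, 0.16, 0.09, 0.10, 0.06, 0.05, 0.03, 0.03, 0.02, 0.05)
  rep(vocab, times = round(weights * p))[seq_len(p)]
}

# frailty item columns from a logistic deficit propensity
gen_fi_phenotypes <- function(n, lp, config, with_missing = TRUE) {
  sexes <- sample(c("female", "male"), n, replace = TRUE)
  is_f <- sexes == "female"
  height <- ifelse(is_f, rnorm(n, 1.62, 0.065), rnorm(n, 1.76, 0.07))
  bmi <- rnorm_trunc(n, 27, 4.5, 16, 45)
  weight <- bmi * height^2
  pheno <- data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    age = round(65 + rgamma(n, shape = 2, scale = 4), 1),
    sex = sexes,
    height_m = round(height, 3),
    weight_kg = round(weight, 1),
    bmi = weight / height^2,
    egfr = round(clamp(rnorm(n, 69.1, 15.4), 10, 130), 1),
    stringsAsFactors = FALSE)
  pheno$walk_speed_m_s <- pmax(
    ifelse(is_f, 0.95, 1.05) + 0.6 * (height - ifelse(is_f, 1.62, 1.76)) -
      0.25 * lp + rnorm(n, 0, 0.15), 0.1)
  pheno$grip_kg <- pmax(
    ifelse(is_f, 24, 38) + 0.25 * (bmi - 27) - 4 * lp + rnorm(n, 0, 4), 2)
  pheno$phys_activity <- exp(-0.8 * lp + rnorm(n, 0, 0.7))
  pheno$weight_change_frac <- -0.004 - 0.02 * lp + rnorm(n, 0, 0.03)

  ord <- fi_ordinal_items()
  p_ord <- plogis(qlogis(0.05) + lp)
  for (it in ord) pheno[[it]] <- rbinom(n, 4L, p_ord)
  bin <- fi_binary_items()
  p_bin <- plogis(qlogis(0.12) + lp)
  for (it in bin) pheno[[it]] <- rbinom(n, 1L, p_bin)

  if (with_missing && config$item_missing_rate > 0) {
    for (it in c(ord, bin)) {
      miss <- runif(n) < config$item_missing_rate
      pheno[[it]][miss] <- NA_integer_
    }
  }
  pheno
}

#' Generate a seeded synthetic cohort
#'
#' Draws a latent diet-quality trait per participant, log-normal food-group
#' intakes shifted along it, a block-correlated metabolite matrix with
#' planted diet-associated metabolites, and frailty items whose logistic
#' propensity combines a direct diet path with a path through the planted
#' metabolite composite.  Limit-of-detection censoring metadata and
#' invalid-energy visits are injected at the configured rates.  Identical
#' configurations (including the seed) produce bit-identical cohorts.
#'
#' @param config a [synth_config()].
#' @return a `synth_cohort` list: `intake` (per-visit table), `metabolome`
#'   (a [metabolite_matrix()]), `phenotypes`, and `truth` (planted
#'   metabolite ids, effect sizes, path coefficients, and the analytic
#'   product-of-coefficients proportion mediated).
#' @export
#' @examples
#' cohort <- generate_cohort(synth_config(n_participants = 50, seed = 7))
#' cohort$truth$oracle_pm
generate_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_participants
  h <- rnorm(n)

  # metabolome
  lat <- gen_metabolome_latent(n, h, config)
  p <- config$n_metabolites
  met_ids <- sprintf("met_%04d", seq_len(p))
  mu <- rnorm(p, 1, 0.8)
  conc <- exp(sweep(0.5 * lat$x, 2L, mu, `+`))
  colnames(conc) <- met_ids

  # LOD metadata: ordinary metabolites censored at the lod_fraction
  # quantile; a drop_fraction subset gets an LOD high enough to exceed the
  # 30% missingness threshold downstream (planted metabolites are exempt)
  n_drop <- round(config$drop_fraction * p)
  droppable <- setdiff(seq_len(p), lat$planted)
  drop_idx <- if (n_drop > 0L) sample(droppable, min(n_drop,
                                                     length(droppable)))
  else integer()
  lod <- vapply(seq_len(p), function(j) {
    prob <- if (j %in% drop_idx) 0.35 else config$lod_fraction
    quantile(conc[, j], prob, names = FALSE, type = 7)
  }, numeric(1L))
  names(lod) <- met_ids
  classes <- setNames(metabolite_classes(p), met_ids)

  # phenotypes and frailty items
  lp <- config$path_direct * h + config$path_mediated * lat$composite
  pheno <- gen_fi_phenotypes(n, lp, config)
  metab <- metabolite_matrix(conc, lod, classes,
                             participant_id = pheno$participant_id)

  # intake visits
  nv <- sample(seq(config$n_visits_range[1], config$n_visits_range[2]),
               n, replace = TRUE)
  row_part <- rep(seq_len(n), nv)
  n_rows <- length(row_part)
  spec <- intake_spec()
  intake <- data.frame(
    participant_id = pheno$participant_id[row_part],
    visit_id = unlist(lapply(nv, seq_len), use.names = FALSE),
    stringsAsFactors = FALSE)
  intake$energy_kcal <- round(rnorm_trunc(n_rows, 2000, 500, 300, 5500), 1)
  n_bad <- round(config$invalid_energy_fraction * n_rows)
  if (n_bad > 0L) {
    bad <- sample(n_rows, n_bad)
    lo_half <- seq_along(bad) <= ceiling(n_bad / 2)
    intake$energy_kcal[bad[lo_half]] <-
      round(runif(sum(lo_half), 300, 599), 1)
    intake$energy_kcal[bad[!lo_half]] <-
      round(runif(sum(!lo_half), 4801, 5500), 1)
  }
  h_row <- h[row_part]
  for (k in seq_len(nrow(spec))) {
    intake[[spec$column[k]]] <- round(exp(
      spec$log_mean[k] + spec$dir[k] * config$kappa * h_row +
        spec$log_sd[k] * rnorm(n_rows)), 4)
  }
  # a share of abstainers makes the moderate-alcohol windows informative
  abstainer <- runif(n) < 0.25
  intake$alcohol_g_d[abstainer[row_part]] <- 0
  intake$wine_srv_wk[abstainer[row_part]] <- 0

  # analytic product-of-coefficients proportion mediated: slope of the
  # planted composite on the diet trait is gamma / sqrt(1 + gamma^2), and
  # the outcome-model coefficients are proportional to the path
  # coefficients through the common logistic slope factor
  a_slope <- if (config$n_planted > 0L) {
    config$effect_planted / sqrt(1 + config$effect_planted^2)
  } else {
    0
  }
  num <- a_slope * config$path_mediated
  den <- num + config$path_direct
  oracle_pm <- if (config$n_planted == 0L || config$path_mediated == 0) {
    0
  } else if (abs(den) < 1e-12) {
    NA_real_
  } else {
    num / den
  }

  structure(list(
    intake = intake,
    metabolome = metab,
    phenotypes = pheno,
    truth = list(planted = met_ids[lat$planted],
                 gamma = rep(config$effect_planted,
                             length(lat$planted)),
                 path_direct = config$path_direct,
                 path_mediated = config$path_mediated,
                 oracle_pm = oracle_pm,
                 dropped_by_design = met_ids[drop_idx],
                 latent_diet = h,
                 planted_composite = lat$composite),
    config = config), class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf(paste0("<synth_cohort> %d participants, %d visits, ",
                     "%d metabolites (%d planted)\n"),
              nrow(x$phenotypes), nrow(x$intake),
              ncol(x$metabolome$values), length(x$truth$planted)))
  invisible(x)
}

#' Large-sample oracle for the proportion mediated
#'
#' Regenerates the mediation-relevant parts of the synthetic model (latent
#' diet trait, planted-metabolite composite, frailty index) at a large
#' sample size and fits the two mediation regressions by exact least
#' squares, returning the product-of-coefficients proportion mediated
#' ab / (ab + c').  This is the ground truth against which desk-scale
#' mediation estimates are judged.
#'
#' @param config a [synth_config()].
#' @param n_large oracle sample size (>= 1e5).
#' @return proportion mediated in \[0, 1\].
#' @export
oracle_proportion_mediated <- function(config, n_large = 1e5) {
  stopifnot(inherits(config, "synth_config"))
  if (n_large < 1e5) stop_dm("n_large must be at least 1e5")
  if (config$n_planted == 0L || config$path_mediated == 0) {
    return(0)
  }
  set.seed(spawn_seed(config$seed, "oracle_pm"))
  n <- as.integer(n_large)
  h <- rnorm(n)
  lat <- gen_metabolome_latent(n, h, config)
  m <- lat$composite
  lp <- config$path_direct * h + config$path_mediated * m
  cfg0 <- config
  cfg0$item_missing_rate <- 0
  pheno <- gen_fi_phenotypes(n, lp, cfg0, with_missing = FALSE)
  pheno <- derive_threshold_deficits(pheno)
  fi <- compute_fi(pheno)$fi

  a <- coef(lm.fit(cbind(1, h), m))[2L]
  out <- coef(lm.fit(cbind(1, h, m), fi))
  cprime <- out[2L]
  b <- out[3L]
  acme <- a * b
  te <- acme + cprime
  if (abs(te) < 1e-8) {
    stop_dm("degenerate configuration: total effect is zero")
  }
  unname(acme / te)
}
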