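write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a synthetic cohort to delimited text
#'
#' Emits the three standard input tables (`intake.tsv`, `metabolome.tsv`,
#' `phenotypes.tsv`), the metabolite metadata (`metabolite_meta.tsv`: LOD
#' and class per metabolite) and the planted-parameter record
#' (`truth.json`).
#'
#' @param cohort a `synth_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("intake.tsv", "metabolome.tsv",
                            "metabolite_meta.tsv", "phenotypes.tsv",
                            "truth.json"))
  write_tsv(cohort$intake, paths[1])
  met <- data.frame(participant_id = cohort$metabolome$participant_id,
                    cohort$metabolome$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_tsv(met, paths[2])
  write_tsv(data.frame(metabolite = names(cohort$metabolome$lod),
                       lod = unname(cohort$metabolome$lod),
                       class = unname(cohort$metabolome$class),
                       stringsAsFactors = FALSE), paths[3])
  write_tsv(cohort$phenotypes, paths[4])
  truth <- cohort$truth
  truth$latent_diet <- NULL
  truth$planted_composite <- NULL
  jsonlite::write_json(truth, paths[5], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read cohort tables from a directory
#'
#' Counterpart of [write_cohort()]; also accepts user-provided tables with
#' the same layout.
#'
#' @param dir directory containing `intake.tsv`, `metabolome.tsv`,
#'   `metabolite_meta.tsv` and `phenotypes.tsv`.
#' @return list with `intake`, `metabolome` (a [metabolite_matrix()]) and
#'   `phenotypes`.
#' @export
read_cohort <- function(dir) {
  intake <- read.delim(file.path(dir, "intake.tsv"),
                       stringsAsFactors = FALSE)
  met <- read.delim(file.path(dir, "metabolome.tsv"), check.names = FALSE,
                    stringsAsFactors = FALSE)
  meta <- read.delim(file.path(dir, "metabolite_meta.tsv"),
                     stringsAsFactors = FALSE)
  pheno <- read.delim(file.path(dir, "phenotypes.tsv"),
                      stringsAsFactors = FALSE)
  values <- as.matrix(met[setdiff(names(met), "participant_id")])
  metab <- metabolite_matrix(values,
                             setNames(meta$lod, meta$metabolite),
                             setNames(meta$class, meta$metabolite),
                             participant_id = met$participant_id)
  list(intake = intake, metabolome = metab, phenotypes = pheno)
}

#' Validate input tables against the expected schemas
#'
#' Checks column presence and types for the intake, metabolome and
#' phenotype tables, and reports participant-id overlap.  All violations
#' are collected and returned, not just the first.
#'
#' @param paths named list/vector with elements `intake`, `metabolome`,
#'   `metabolite_meta`, `phenotypes` (file paths).
#' @return list with a `violations` data.frame (possibly empty), and an
#'   `overlap` report of participant-id counts.
#' @export
validate_inputs <- function(paths) {
  paths <- as.list(paths)
  violations <- list()
  note <- function(file, problem) {
    violations[[length(violations) + 1L]] <<- data.frame(
      file = file, problem = problem, stringsAsFactors = FALSE)
  }
  tables <- list()
  for (nm in c("intake", "metabolome", "metabolite_meta", "phenotypes")) {
    if (is.null(paths[[nm]]) || !file.exists(paths[[nm]])) {
      note(nm, "file missing")
    } else {
      tables[[nm]] <- read.delim(paths[[nm]], check.names = FALSE,
                                 stringsAsFactors = FALSE)
    }
  }
  req <- list(
    intake = c("participant_id", "visit_id", "energy_kcal",
               intake_spec()$column),
    metabolome = "participant_id",
    metabolite_meta = c("metabolite", "lod", "class"),
    phenotypes = c("participant_id", "age", "sex", "height_m", "weight_kg",
                   "egfr", "walk_speed_m_s", "grip_kg", "phys_activity",
                   "weight_change_frac", fi_ordinal_items(),
                   fi_binary_items()))
  for (nm in names(req)) {
    if (is.null(tables[[nm]])) next
    for (col in setdiff(req[[nm]], names(tables[[nm]]))) {
      note(nm, sprintf("missing column '%s'", col))
    }
  }
  if (!is.null(tables$intake) && "energy_kcal" %in% names(tables$intake) &&
      !is.numeric(tables$intake$energy_kcal)) {
    note("intake", "energy_kcal is not numeric")
  }
  overlap <- NULL
  if (!is.null(tables$intake) && !is.null(tables$phenotypes) &&
      all(c("participant_id") %in% names(tables$intake)) &&
      all(c("participant_id") %in% names(tables$phenotypes))) {
    ids_i <- unique(as.character(tables$intake$participant_id))
    ids_p <- unique(as.character(tables$phenotypes$participant_id))
    ids_m <- if (!is.null(tables$metabolome) &&
                 "participant_id" %in% names(tables$metabolome)) {
      unique(as.character(tables$metabolome$participant_id))
    } else {
      character()
    }
    overlap <- list(n_intake = length(ids_i), n_phenotypes = length(ids_p),
                    n_metabolome = length(ids_m),
                    n_overlap = length(Reduce(intersect,
                                              list(ids_i, ids_p, ids_m))))
    if (overlap$n_overlap == 0L) note("all", "participant ids do not overlap")
  }
  list(violations = if (length(violations)) do.call(rbind, violations) else
    data.frame(file = character(), problem = character(),
               stringsAsFactors = FALSE),
    overlap = overlap)
}

#' Pipeline configuration
#'
#' @param out_dir output directory for all stage artifacts.
#' @param synth a [synth_config()] for generated cohorts (its seed is
#'   re-derived from `seed` so one global seed controls the whole run).
#' @param input_dir optional directory of user tables (as written by
#'   [write_cohort()]); when given, no cohort is generated.
#' @param enet an [enet_config()] (its seed is likewise re-derived).
#' @param scores which diet scores to carry through the signature and
#'   mediation stages.
#' @param n_boot mediation bootstrap draws.
#' @param adjust_covariates adjust the mediation models for age, sex, eGFR
#'   and energy (off by default; the core mediation uses diet, metDS and
#'   frailty only).
#' @param log_transform log-transform metabolite concentrations before
#'   standardization.
#' @param seed single global seed; per-stage seeds are derived from it.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(out_dir, synth = synth_config(),
                            input_dir = NULL, enet = enet_config(),
                            scores = c("mds", "mind", "ahei"),
                            n_boot = 500L, adjust_covariates = FALSE,
                            log_transform = TRUE, seed = 1L) {
  cfg <- list(out_dir = out_dir, synth = synth, input_dir = input_dir,
              enet = enet, scores = match.arg(scores, several.ok = TRUE),
              n_boot = check_count(n_boot, "n_boot", 1L),
              adjust_covariates = isTRUE(adjust_covariates),
              log_transform = isTRUE(log_transform),
              seed = check_count(seed, "seed", 0L))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort generation (or ingest), diet scoring, frailty
#' index construction, metabolite preparation, the association scan, the
#' elastic-net signature per diet score, and the mediation decomposition,
#' writing every stage's artifact to `out_dir` as delimited text or JSON
#' plus a `manifest.json` capturing seeds, sizes and wall-clock times.  Any
#' stage error aborts the run with the stage name; artifacts of completed
#' stages persist.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("dietmetab")),
                   seed = config$seed, stages = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop_dm(sprintf("pipeline stage '%s' failed: %s", name,
                      conditionMessage(e)))
    })
    if (!quiet) message(sprintf("stage %s done", name))
    attr(res, "elapsed") <- proc.time()[["elapsed"]] - t0
    res
  }
  record <- function(name, elapsed, ...) {
    manifest$stages[[name]] <<- c(list(elapsed_s = round(elapsed, 3)),
                                  list(...))
  }

  # stage 1: synth / ingest
  cohort <- t_stage("synth", {
    if (!is.null(config$input_dir)) {
      rep <- validate_inputs(list(
        intake = file.path(config$input_dir, "intake.tsv"),
        metabolome = file.path(config$input_dir, "metabolome.tsv"),
        metabolite_meta = file.path(config$input_dir,
                                    "metabolite_meta.tsv"),
        phenotypes = file.path(config$input_dir, "phenotypes.tsv")))
      if (nrow(rep$violations)) {
        stop_dm("input validation failed: ",
                paste(rep$violations$problem, collapse = "; "))
      }
      read_cohort(config$input_dir)
    } else {
      syn <- config$synth
      syn$seed <- spawn_seed(config$seed, "synth")
      cohort <- generate_cohort(syn)
      write_cohort(cohort, config$out_dir)
      cohort
    }
  })
  record("synth", attr(cohort, "elapsed"),
         n_participants = nrow(cohort$phenotypes),
         n_visits = nrow(cohort$intake),
         n_metabolites = ncol(cohort$metabolome$values))

  # stage 2: diet scores
  ds <- t_stage("score_diet",
                diet_scores(cohort$intake, cohort$phenotypes))
  write_tsv(ds, file.path(config$out_dir, "diet_scores.tsv"))
  record("score_diet", attr(ds, "elapsed"), n_scored = nrow(ds))

  # stage 3: frailty index
  fi <- t_stage("frailty", {
    ph <- derive_threshold_deficits(cohort$phenotypes)
    compute_fi(ph)
  })
  write_tsv(fi, file.path(config$out_dir, "frailty.tsv"))
  record("frailty", attr(fi, "elapsed"), n_valid = sum(fi$valid))

  # stage 4: metabolite preparation
  prep <- t_stage("prep_metab",
                  prepare_metabolome(cohort$metabolome,
                                     log_transform = config$log_transform))
  prep_df <- data.frame(participant_id = prep$participant_id, prep$values,
                        check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(prep_df, file.path(config$out_dir, "prepared_metabolome.tsv"))
  qc <- prep$dropped
  if (!is.null(prep$n_imputed)) {
    qc <- list(dropped = prep$dropped,
               imputed = data.frame(metabolite = names(prep$n_imputed),
                                    n_imputed = unname(prep$n_imputed)))
    write_tsv(qc$imputed, file.path(config$out_dir, "qc_imputed.tsv"))
    qc <- qc$dropped
  }
  write_tsv(qc, file.path(config$out_dir, "qc_report.tsv"))
  record("prep_metab", attr(prep, "elapsed"),
         n_metabolites = ncol(prep$values), n_dropped = nrow(prep$dropped))

  # stage 5: association scan + diet-FI regressions
  covars <- scan_covariates(cohort, ds)
  assoc <- t_stage("scan", scan_associations(prep, ds, covars))
  write_tsv(assoc, file.path(config$out_dir, "associations.tsv"))
  dfi <- diet_fi_regression(ds, fi, covars)
  write_tsv(dfi, file.path(config$out_dir, "diet_fi.tsv"))
  record("scan", attr(assoc, "elapsed"),
         n_significant = as.list(attr(assoc, "summary")$n_significant),
         n_common = attr(assoc, "summary")$n_common)

  # stage 6: elastic-net signatures and metDS
  common <- intersect(as.character(prep$participant_id),
                      as.character(ds$participant_id))
  X <- prep$values[match(common, as.character(prep$participant_id)), ,
                   drop = FALSE]
  sigs <- list()
  metds_tab <- data.frame(participant_id = common,
                          stringsAsFactors = FALSE)
  t0 <- proc.time()[["elapsed"]]
  for (s in config$scores) {
    y <- ds[[s]][match(common, as.character(ds$participant_id))]
    ecfg <- config$enet
    ecfg$seed <- spawn_seed(config$seed, paste0("enet_", s))
    sigs[[s]] <- t_stage(paste0("signature_", s),
                         enet_signature(X, y, ecfg))
    write_tsv(sigs[[s]]$significance,
              file.path(config$out_dir, sprintf("signature_%s.tsv", s)))
    metds_tab[[paste0("metds_", s)]] <- sigs[[s]]$metds %||%
      rep(NA_real_, length(common))
  }
  write_tsv(metds_tab, file.path(config$out_dir, "metds.tsv"))
  jsonlite::write_json(
    lapply(sigs, function(z) list(alpha_star = z$alpha_star,
                                  lambda_star = z$lambda_star,
                                  qf = z$qf, r2_raw = z$r2_raw,
                                  n_selected = sum(z$significance$selected),
                                  grid = z$grid)),
    file.path(config$out_dir, "ensemble_summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns")
  record("signature", proc.time()[["elapsed"]] - t0,
         n_selected = lapply(sigs, function(z)
           sum(z$significance$selected)))

  # stage 7: mediation
  med <- t_stage("mediate", {
    fi_v <- fi$fi[match(common, as.character(fi$participant_id))]
    cw <- if (config$adjust_covariates) {
      cc <- covars[match(common, as.character(covars$participant_id)), ,
                   drop = FALSE]
      as.matrix(cc[setdiff(names(cc), "participant_id")])
    }
    res <- list()
    for (s in config$scores) {
      if (is.null(sigs[[s]]$metds)) next
      y <- ds[[s]][match(common, as.character(ds$participant_id))]
      res[[s]] <- mediate_metds(y, sigs[[s]]$metds, fi_v, covars = cw,
                                n_boot = config$n_boot,
                                seed = spawn_seed(config$seed,
                                                  paste0("med_", s)))
    }
    res
  })
  med_tab <- mediation_table(med)
  write_tsv(med_tab, file.path(config$out_dir, "mediation.tsv"))
  record("mediate", attr(med, "elapsed"),
         pm = lapply(med, function(z)
           z$estimates$estimate[z$estimates$quantity == "PM"]))

  manifest$n_stages <- length(manifest$stages)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, scores = ds, frailty = fi,
                 prepared = prep, associations = assoc,
                 signatures = sigs, mediation = med,
                 diet_fi = dfi, cohort = cohort))
}
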