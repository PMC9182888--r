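#' Filter intake visits by energy validity
#'
#' Keeps visits whose reported daily energy intake lies inside the validity
#' window (default 600-4800 kcal/day, bounds inclusive).  Implausibly low or
#' high energy reports are the standard marker of invalid food-frequency
#' questionnaire administrations.
#'
#' @param intake per-visit intake table with an `energy_kcal` column.
#' @param bounds length-2 numeric, inclusive kcal/day validity window.
#' @param quiet suppress the removed-visit message.
#' @return the filtered table; attribute `n_removed` carries the count of
#'   dropped visits.
#' @export
filter_valid_visits <- function(intake, bounds = c(600, 4800), quiet = TRUE) {
  check_columns(intake, "energy_kcal", "intake table")
  if (any(!is.finite(intake$energy_kcal)) || any(intake$energy_kcal <= 0)) {
    stop_dm("energy_kcal must be positive and finite for every visit")
  }
  keep <- intake$energy_kcal >= bounds[1] & intake$energy_kcal <= bounds[2]
  out <- intake[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop_dm("no visits remain after the energy-validity filter")
  }
  if (!quiet) {
    message(sprintf("energy filter removed %d of %d visits",
                    sum(!keep), length(keep)))
  }
  attr(out, "n_removed") <- sum(!keep)
  rownames(out) <- NULL
  out
}

#' Average intake columns over a participant's valid visits
#'
#' Arithmetic mean of every numeric intake column across visits, producing
#' one row per participant, plus an `n_valid_visits` count.
#'
#' @param intake per-visit intake table with `participant_id`.
#' @return one-row-per-participant table (visit identifiers dropped).
#' @export
average_visits <- function(intake) {
  check_columns(intake, "participant_id", "intake table")
  num_cols <- setdiff(names(intake)[vapply(intake, is.numeric, logical(1L))],
                      c("visit_id"))
  ids <- intake$participant_id
  g <- factor(ids, levels = unique(ids))
  n <- as.vector(table(g))
  sums <- rowsum(as.matrix(intake[num_cols]), group = g, reorder = FALSE)
  out <- data.frame(participant_id = levels(g),
                    sums / n,
                    n_valid_visits = n,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

# add nutrient ratios the rubrics reference when their source columns exist
add_derived_intake <- function(intake) {
  if (!"mufa_sfa_ratio" %in% names(intake) &&
      all(c("mufa_g_d", "sfa_g_d") %in% names(intake))) {
    intake$mufa_sfa_ratio <- intake$mufa_g_d / pmax(intake$sfa_g_d, 1e-12)
  }
  if (!"alcohol_drinks_d" %in% names(intake) &&
      "alcohol_g_d" %in% names(intake)) {
    # 14 g ethanol per standard drink
    intake$alcohol_drinks_d <- intake$alcohol_g_d / 14
  }
  intake
}

# ---- component scoring rules -----------------------------------------------

score_three_level <- function(x, comp) {
  if (identical(comp$direction, "detrimental")) {
    ifelse(x < comp$full_cutoff, 1, ifelse(x < comp$half_cutoff, 0.5, 0))
  } else {
    ifelse(x >= comp$full_cutoff, 1, ifelse(x >= comp$half_cutoff, 0.5, 0))
  }
}

score_three_level_window <- function(x, comp) {
  full <- x >= comp$full_range[1] & x <= comp$full_range[2]
  half <- !full & x >= comp$half_range[1] & x <= comp$half_range[2]
  ifelse(full, 1, ifelse(half, 0.5, 0))
}

score_proportional <- function(x, comp, sex) {
  az <- resolve_by_sex(comp$anchor_zero, sex %||% rep(NA, length(x)),
                       comp$name)
  af <- resolve_by_sex(comp$anchor_full, sex %||% rep(NA, length(x)),
                       comp$name)
  10 * clamp((x - az) / (af - az), 0, 1)
}

score_ahei_alcohol <- function(x, comp, sex) {
  sex <- sex %||% rep(NA, length(x))
  lo <- resolve_by_sex(lapply(comp$window, `[[`, 1L), sex, "alcohol window")
  hi <- resolve_by_sex(lapply(comp$window, `[[`, 2L), sex, "alcohol window")
  z <- resolve_by_sex(comp$zero_anchor, sex, "alcohol zero anchor")
  ab <- as.numeric(comp$abstainer_score %||% 2.5)
  score <- numeric(length(x))
  score[x == 0] <- ab
  low <- x > 0 & x < lo
  score[low] <- ab + (10 - ab) * (x[low] / lo[low])
  inwin <- x >= lo & x <= hi
  score[inwin] <- 10
  taper <- x > hi & x < z
  score[taper] <- 10 * (z[taper] - x[taper]) / (z[taper] - hi[taper])
  score[x >= z] <- 0
  score
}

rubric_columns <- function(rubric) {
  vapply(rubric$components, `[[`, character(1L), "column")
}

# ---- instrument scorers ----------------------------------------------------

#' Mediterranean diet score (0-9)
#'
#' Nine components scored 0/1 against within-sample medians of
#' visit-averaged intake: beneficial components (vegetables, legumes,
#' fruits/nuts, whole grains, fish, MUFA:SFA ratio) score 1 at or above the
#' sample median, detrimental components (meat, dairy) score 1 below it, and
#' alcohol scores 1 inside a sex-specific moderate window.  Because the
#' cutoffs are sample medians, the score is defined relative to the cohort
#' being scored.
#'
#' @param intake one row per participant (visit-averaged) intake table.
#' @param rubric an MDS `diet_rubric`.
#' @param sex character/factor vector aligned with `intake` rows (needed for
#'   the sex-specific alcohol window; levels must match the rubric keys,
#'   default `"female"`/`"male"`).
#' @return data.frame with `participant_id`, `mds`, and per-component 0/1
#'   audit columns prefixed `mds_`.
#' @export
score_mds <- function(intake, rubric = load_rubric("MDS"), sex = NULL) {
  intake <- add_derived_intake(intake)
  check_columns(intake, c("participant_id", rubric_columns(rubric)),
                "MDS intake table")
  if (anyDuplicated(intake$participant_id)) {
    stop_dm("score_mds expects one (visit-averaged) row per participant; ",
            "call average_visits() first")
  }
  if (nrow(intake) < 2L) {
    stop_dm("MDS median cutoffs need a cohort of at least 2 participants")
  }
  comp_scores <- matrix(NA_real_, nrow(intake), length(rubric$components))
  colnames(comp_scores) <- vapply(rubric$components, `[[`, character(1L),
                                  "name")
  for (k in seq_along(rubric$components)) {
    comp <- rubric$components[[k]]
    x <- intake[[comp$column]]
    comp_scores[, k] <- switch(
      comp$rule,
      median_split = {
        med <- median(x)
        if (identical(comp$direction, "detrimental")) {
          as.numeric(x < med)          # ties at the median score 0
        } else {
          as.numeric(x >= med)         # ties at the median score 1
        }
      },
      moderate_window = {
        lo <- resolve_by_sex(lapply(comp$window, `[[`, 1L), sex, comp$name)
        hi <- resolve_by_sex(lapply(comp$window, `[[`, 2L), sex, comp$name)
        as.numeric(x >= lo & x <= hi)
      },
      stop_dm(sprintf("unknown MDS rule '%s'", comp$rule)))
  }
  out <- data.frame(participant_id = intake$participant_id,
                    mds = rowSums(comp_scores),
                    stringsAsFactors = FALSE)
  audit <- as.data.frame(comp_scores)
  names(audit) <- paste0("mds_", names(audit))
  cbind(out, audit)
}

#' MIND diet score (0-15)
#'
#' Fifteen food groups each scored 0, 0.5 or 1 from weekly (or daily)
#' servings against fixed cutoffs; wine is scored by a moderate window with
#' full credit near one glass per day.  Scores rows independently, so it can
#' be applied per visit and averaged afterwards.
#'
#' @param intake intake table (per visit or averaged).
#' @param rubric a MIND `diet_rubric`.
#' @return data.frame with `participant_id` (if present), `mind`, and
#'   per-component audit columns prefixed `mind_`.
#' @export
score_mind <- function(intake, rubric = load_rubric("MIND")) {
  intake <- add_derived_intake(intake)
  check_columns(intake, rubric_columns(rubric), "MIND intake table")
  comp_scores <- matrix(NA_real_, nrow(intake), length(rubric$components))
  colnames(comp_scores) <- vapply(rubric$components, `[[`, character(1L),
                                  "name")
  for (k in seq_along(rubric$components)) {
    comp <- rubric$components[[k]]
    x <- intake[[comp$column]]
    comp_scores[, k] <- switch(
      comp$rule,
      three_level = score_three_level(x, comp),
      three_level_window = score_three_level_window(x, comp),
      stop_dm(sprintf("unknown MIND rule '%s'", comp$rule)))
  }
  out <- data.frame(mind = rowSums(comp_scores))
  if ("participant_id" %in% names(intake)) {
    out <- cbind(participant_id = intake$participant_id, out)
  }
  audit <- as.data.frame(comp_scores)
  names(audit) <- paste0("mind_", names(audit))
  cbind(out, audit)
}

#' AHEI-2010 score (0-110)
#'
#' Eleven components scored proportionally 0-10 by linear interpolation
#' between anchors (clamped), with alcohol scored by a sex-specific moderate
#' window.  Scores rows independently (apply per visit, then average).
#'
#' @param intake intake table (per visit or averaged).
#' @param rubric an AHEI `diet_rubric`.
#' @param sex character/factor vector aligned with rows (sex-specific whole
#'   grain anchors and alcohol window).
#' @return data.frame with `participant_id` (if present), `ahei`, and
#'   per-component audit columns prefixed `ahei_`.
#' @export
score_ahei <- function(intake, rubric = load_rubric("AHEI"), sex = NULL) {
  intake <- add_derived_intake(intake)
  check_columns(intake, rubric_columns(rubric), "AHEI intake table")
  comp_scores <- matrix(NA_real_, nrow(intake), length(rubric$components))
  colnames(comp_scores) <- vapply(rubric$components, `[[`, character(1L),
                                  "name")
  for (k in seq_along(rubric$components)) {
    comp <- rubric$components[[k]]
    x <- intake[[comp$column]]
    comp_scores[, k] <- switch(
      comp$rule,
      proportional = score_proportional(x, comp, sex),
      moderate_window = score_ahei_alcohol(x, comp, sex),
      stop_dm(sprintf("unknown AHEI rule '%s'", comp$rule)))
  }
  out <- data.frame(ahei = rowSums(comp_scores))
  if ("participant_id" %in% names(intake)) {
    out <- cbind(participant_id = intake$participant_id, out)
  }
  audit <- as.data.frame(comp_scores)
  names(audit) <- paste0("ahei_", names(audit))
  cbind(out, audit)
}

#' Compute all three diet scores for a cohort
#'
#' Applies the energy-validity filter, scores MIND and AHEI per valid visit
#' and averages them within participant, and scores MDS once on
#' visit-averaged intake with within-sample median cutoffs.
#'
#' @param intake per-visit intake table (`participant_id`, `visit_id`,
#'   `energy_kcal`, food-group and nutrient columns).
#' @param pheno phenotype table with `participant_id` and `sex`; required by
#'   the default rubrics (sex-specific alcohol windows and grain anchors).
#' @param rubrics named list of rubrics as from [default_rubrics()].
#' @param energy_bounds inclusive kcal/day validity window.
#' @param quiet suppress messages.
#' @return data.frame with one row per retained participant:
#'   `participant_id`, `mds`, `mind`, `ahei`, `n_valid_visits`; the
#'   per-component audit tables are attached as attribute `audit`.
#' @export
#' @examples
#' cohort <- generate_cohort(synth_config(n_participants = 60, seed = 1))
#' ds <- diet_scores(cohort$intake, cohort$phenotypes)
#' head(ds)
diet_scores <- function(intake, pheno, rubrics = default_rubrics(),
                        energy_bounds = c(600, 4800), quiet = TRUE) {
  check_columns(intake, c("participant_id", "visit_id", "energy_kcal"),
                "intake table")
  check_columns(pheno, c("participant_id", "sex"), "phenotype table")
  ids_before <- unique(intake$participant_id)
  valid <- filter_valid_visits(intake, bounds = energy_bounds, quiet = quiet)
  dropped <- setdiff(ids_before, unique(valid$participant_id))
  if (length(dropped)) {
    warning(sprintf("%d participant(s) had no valid visit and were dropped",
                    length(dropped)), call. = FALSE)
  }
  sex_by_id <- setNames(as.character(pheno$sex), pheno$participant_id)
  sex_visit <- unname(sex_by_id[as.character(valid$participant_id)])
  if (anyNA(sex_visit)) {
    stop_dm("some intake participants are missing from the phenotype table")
  }

  # MIND / AHEI: score each valid visit, then average within participant
  mind_v <- score_mind(valid, rubrics$MIND)
  ahei_v <- score_ahei(valid, rubrics$AHEI, sex = sex_visit)
  per_visit <- data.frame(participant_id = valid$participant_id,
                          mind = mind_v$mind, ahei = ahei_v$ahei)
  avg_scores <- average_visits(per_visit)

  # MDS: average intake first, then median-split scoring on the cohort
  avg_intake <- average_visits(valid)
  sex_part <- unname(sex_by_id[as.character(avg_intake$participant_id)])
  mds <- score_mds(avg_intake, rubrics$MDS, sex = sex_part)

  out <- data.frame(participant_id = avg_intake$participant_id,
                    mds = mds$mds,
                    mind = avg_scores$mind,
                    ahei = avg_scores$ahei,
                    n_valid_visits = avg_scores$n_valid_visits,
                    stringsAsFactors = FALSE)
  attr(out, "audit") <- list(mds = mds, mind_per_visit = mind_v,
                             ahei_per_visit = ahei_v)
  out
}
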