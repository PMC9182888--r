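#' Load a deficit map
#'
#' The deficit map declares the 44 items of the deficit-accumulation frailty
#' index: for each item, its source column and mapping rule (`binary`,
#' `ordinal5` for 5-level codes mapped onto \{0, 0.25, 0.5, 0.75, 1\}, or
#' `threshold` for within-sample derived indicators).  The shipped map
#' follows the deficit-accumulation procedure of Searle and colleagues with
#' declared approximations where instrument codings are cohort-specific.
#'
#' @param path optional path to a YAML deficit map; default is the map
#'   shipped with the package.
#' @return a `deficit_map` object.
#' @export
load_deficit_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "deficit_map.yaml", package = "dietmetab",
                        mustWork = TRUE)
  }
  map <- yaml::read_yaml(path)
  if (length(map$items) != 44L) {
    stop_dm(sprintf("deficit map must have exactly 44 items, found %d",
                    length(map$items)))
  }
  rules <- vapply(map$items, `[[`, character(1L), "rule")
  bad <- setdiff(rules, c("binary", "ordinal5", "threshold"))
  if (length(bad)) {
    stop_dm("unknown deficit rule(s): ", paste(unique(bad), collapse = ", "))
  }
  class(map) <- "deficit_map"
  map
}

#' @export
print.deficit_map <- function(x, ...) {
  rules <- vapply(x$items, `[[`, character(1L), "rule")
  cat(sprintf("<deficit_map> %d items (%s)\n", length(x$items),
              paste(sprintf("%s: %d", names(table(rules)), table(rules)),
                    collapse = ", ")))
  invisible(x)
}

stratum_quantile_flag <- function(value, strata, prob) {
  flag <- rep(NA_real_, length(value))
  for (s in split(seq_along(value), strata, drop = TRUE)) {
    v <- value[s]
    ok <- !is.na(v)
    if (sum(ok) == 0L) next
    if (sum(ok) < 5L) {
      warning("stratum with fewer than 5 observations; using pooled cutoff",
              call. = FALSE)
      cut <- quantile(value, prob, na.rm = TRUE, names = FALSE, type = 7)
    } else {
      cut <- quantile(v[ok], prob, names = FALSE, type = 7)
    }
    flag[s] <- as.numeric(v <= cut)   # ties at the cutoff flag the deficit
  }
  flag
}

#' Derive within-sample threshold deficits
#'
#' Adds the four frailty-index items that are defined relative to the cohort
#' rather than by fixed cutoffs: slowness (walking speed in the lowest
#' quintile, stratified by sex and a sex-specific height median split),
#' weakness (grip strength in the lowest quintile, stratified by sex and
#' sex-specific BMI quartiles), low physical activity (lowest cohort
#' quartile) and weight loss of at least 5% of prior-year body weight
#' (boundary inclusive).
#'
#' @param pheno phenotype table with `sex`, `height_m`, `weight_kg` (or
#'   `bmi`), `walk_speed_m_s`, `grip_kg`, `phys_activity`,
#'   `weight_change_frac` (signed fraction of prior-year weight; -0.05 means
#'   a 5% loss).
#' @return `pheno` with columns `slowness`, `weakness`, `low_activity`,
#'   `weight_loss` appended (values 0/1, NA where inputs are missing).
#' @export
derive_threshold_deficits <- function(pheno) {
  check_columns(pheno, c("sex", "walk_speed_m_s", "grip_kg", "phys_activity",
                         "weight_change_frac"), "phenotype table")
  if (!"bmi" %in% names(pheno)) {
    check_columns(pheno, c("height_m", "weight_kg"), "phenotype table")
    pheno$bmi <- pheno$weight_kg / pheno$height_m^2
  }
  sex <- as.character(pheno$sex)
  if (length(unique(sex[!is.na(sex)])) < 1L || !"height_m" %in% names(pheno)) {
    stop_dm("stratification variables missing or degenerate")
  }
  if (length(unique(pheno$height_m[!is.na(pheno$height_m)])) < 2L) {
    stop_dm("height is constant; cannot stratify walking speed")
  }

  # sex-specific height median split
  height_grp <- rep(NA_character_, nrow(pheno))
  for (s in unique(sex)) {
    i <- which(sex == s)
    med <- median(pheno$height_m[i], na.rm = TRUE)
    height_grp[i] <- ifelse(pheno$height_m[i] >= med, "tall", "short")
  }
  pheno$slowness <- stratum_quantile_flag(
    pheno$walk_speed_m_s, interaction(sex, height_grp), 0.20)

  # sex-specific BMI quartiles
  bmi_grp <- rep(NA_character_, nrow(pheno))
  for (s in unique(sex)) {
    i <- which(sex == s)
    qs <- quantile(pheno$bmi[i], c(0.25, 0.5, 0.75), na.rm = TRUE,
                   names = FALSE)
    bmi_grp[i] <- paste0("q", findInterval(pheno$bmi[i], qs) + 1L)
  }
  pheno$weakness <- stratum_quantile_flag(
    pheno$grip_kg, interaction(sex, bmi_grp), 0.20)

  act_cut <- quantile(pheno$phys_activity, 0.25, na.rm = TRUE, names = FALSE)
  pheno$low_activity <- as.numeric(pheno$phys_activity <= act_cut)

  pheno$weight_loss <- as.numeric(pheno$weight_change_frac <= -0.05)
  pheno
}

#' Deficit-accumulation frailty index
#'
#' Maps each of the 44 items of the deficit map onto \[0, 1\] and returns
#' their mean over non-missing items.  The index is reported only for
#' participants with less than 20% missing items; above that the value is
#' `NA` and `valid` is `FALSE`.  The denominator is always the number of
#' items actually present, never 44.
#'
#' @param pheno phenotype table containing the mapped item columns
#'   (including the threshold deficits from [derive_threshold_deficits()]).
#' @param map a `deficit_map`.
#' @param max_missing maximum tolerated missing-item fraction (exclusive;
#'   default 0.20).
#' @return data.frame `participant_id`, `fi`, `n_missing_items`, `valid`.
#' @export
#' @examples
#' cohort <- generate_cohort(synth_config(n_participants = 50, seed = 2))
#' ph <- derive_threshold_deficits(cohort$phenotypes)
#' head(compute_fi(ph))
compute_fi <- function(pheno, map = load_deficit_map(), max_missing = 0.20) {
  cols <- vapply(map$items, `[[`, character(1L), "column")
  rules <- vapply(map$items, `[[`, character(1L), "rule")
  unknown <- setdiff(cols, names(pheno))
  if (length(unknown)) {
    stop_dm("deficit map item column(s) not in phenotype table: ",
            paste(unknown, collapse = ", "))
  }
  n <- nrow(pheno)
  deficits <- matrix(NA_real_, n, length(cols),
                     dimnames = list(NULL, vapply(map$items, `[[`,
                                                  character(1L), "name")))
  for (k in seq_along(cols)) {
    x <- pheno[[cols[k]]]
    d <- switch(rules[k],
                binary = as.numeric(x),
                ordinal5 = as.numeric(x) / 4,
                threshold = as.numeric(x))
    if (any(d < 0 - 1e-12 | d > 1 + 1e-12, na.rm = TRUE)) {
      stop_dm(sprintf("item '%s' maps outside [0, 1]", cols[k]))
    }
    deficits[, k] <- d
  }
  n_missing <- rowSums(is.na(deficits))
  n_present <- ncol(deficits) - n_missing
  fi <- rowSums(deficits, na.rm = TRUE) / pmax(n_present, 1L)
  valid <- n_missing / ncol(deficits) < max_missing
  fi[!valid] <- NA_real_
  out <- data.frame(
    participant_id = pheno$participant_id %||% seq_len(n),
    fi = fi, n_missing_items = n_missing, valid = valid,
    stringsAsFactors = FALSE)
  attr(out, "deficits") <- deficits
  out
}
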