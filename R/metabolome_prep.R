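#' Construct a metabolite matrix container
#'
#' @param values numeric matrix, participants in rows, metabolites in
#'   columns (column names = metabolite ids); `NA` marks missing.
#' @param lod named numeric vector of per-metabolite limits of detection.
#' @param class named character vector of metabolite class labels.
#' @param participant_id optional row identifier vector.
#' @return a `metabolite_matrix` object.
#' @export
metabolite_matrix <- function(values, lod, class = NULL,
                              participant_id = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    stop_dm("metabolite matrix needs column names (metabolite ids)")
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop_dm("metabolite concentrations must be >= 0 or missing")
  }
  lod <- lod[colnames(values)]
  if (anyNA(lod)) stop_dm("every metabolite needs an LOD value")
  if (any(lod < 0)) stop_dm("negative LOD is invalid")
  structure(list(values = values, lod = lod,
                 class = if (!is.null(class)) class[colnames(values)],
                 participant_id = participant_id %||% rownames(values) %||%
                   seq_len(nrow(values))),
            class = "metabolite_matrix")
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  cat(sprintf("<metabolite_matrix> %d participants x %d metabolites, %.1f%% missing\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Censor concentrations below the limit of detection
#'
#' Values strictly below the metabolite's LOD become missing (values equal
#' to the LOD are retained).
#'
#' @param m a `metabolite_matrix`.
#' @return the matrix with sub-LOD values set to `NA`.
#' @export
censor_below_lod <- function(m) {
  stopifnot(inherits(m, "metabolite_matrix"))
  below <- sweep(m$values, 2L, m$lod, `<`)
  m$values[which(below)] <- NA_real_
  m
}

#' Remove metabolites with excessive missingness
#'
#' Metabolites whose missing fraction strictly exceeds `threshold` (default
#' 30%) are removed; a metabolite at exactly the threshold is kept.
#'
#' @param m a `metabolite_matrix`.
#' @param threshold maximum tolerated missing fraction.
#' @return the filtered matrix; attribute `dropped` records removed
#'   metabolites and their missing fractions.
#' @export
drop_high_missing <- function(m, threshold = 0.30) {
  stopifnot(inherits(m, "metabolite_matrix"))
  frac <- colMeans(is.na(m$values))
  drop <- frac > threshold
  dropped <- data.frame(metabolite = colnames(m$values)[drop],
                        missing_frac = unname(frac[drop]),
                        reason = rep("missingness above threshold",
                                     sum(drop)),
                        stringsAsFactors = FALSE)
  if (all(drop)) warning("all metabolites removed by missingness filter",
                         call. = FALSE)
  m$values <- m$values[, !drop, drop = FALSE]
  m$lod <- m$lod[!drop]
  if (!is.null(m$class)) m$class <- m$class[!drop]
  attr(m, "dropped") <- dropped
  m
}

#' Impute missing values at half the minimum observed value
#'
#' Each remaining missing entry is replaced by 0.5 times the minimum
#' observed (post-censoring) value of its metabolite — the standard
#' convention for values below the detection limit.
#'
#' @param m a `metabolite_matrix` (after [drop_high_missing()]).
#' @return the matrix with no missing values; attribute `n_imputed` counts
#'   imputations per metabolite.
#' @export
impute_half_min <- function(m) {
  stopifnot(inherits(m, "metabolite_matrix"))
  n_imp <- integer(ncol(m$values))
  names(n_imp) <- colnames(m$values)
  for (j in seq_len(ncol(m$values))) {
    miss <- is.na(m$values[, j])
    if (!any(miss)) next
    if (all(miss)) {
      stop_dm(sprintf("metabolite '%s' has no observed values at imputation",
                      colnames(m$values)[j]))
    }
    m$values[miss, j] <- 0.5 * min(m$values[!miss, j])
    n_imp[j] <- sum(miss)
  }
  attr(m, "n_imputed") <- n_imp
  m
}

#' Standardize a complete metabolite matrix
#'
#' Optionally natural-log transforms concentrations (with a pseudo-count
#' only when a zero is present) and z-scores each metabolite to mean 0 and
#' sample (n-1) standard deviation 1.  Zero-variance metabolites are dropped
#' with a warning.
#'
#' @param m a complete `metabolite_matrix`.
#' @param log_transform apply `log(value + pseudo)` first (default `TRUE`;
#'   concentrations are right-skewed).
#' @param pseudo_count added before the log only if some value is zero
#'   (default: half the smallest positive value).
#' @return a `prepared_matrix`: list with standardized `values`, `class`,
#'   `participant_id`, `dropped` and `n_imputed` provenance.
#' @export
standardize_metabolome <- function(m, log_transform = TRUE,
                                   pseudo_count = NULL) {
  stopifnot(inherits(m, "metabolite_matrix"))
  v <- m$values
  if (anyNA(v)) stop_dm("standardize_metabolome requires a complete matrix")
  if (log_transform) {
    pc <- if (any(v == 0)) {
      pseudo_count %||% (0.5 * min(v[v > 0]))
    } else {
      pseudo_count %||% 0
    }
    v <- log(v + pc)
  }
  mu <- colMeans(v)
  s <- apply(v, 2L, sd)
  zero_var <- s < 1e-12
  if (any(zero_var)) {
    warning(sprintf("dropping %d zero-variance metabolite(s): %s",
                    sum(zero_var),
                    paste(colnames(v)[zero_var], collapse = ", ")),
            call. = FALSE)
  }
  v <- sweep(sweep(v[, !zero_var, drop = FALSE], 2L, mu[!zero_var], `-`),
             2L, s[!zero_var], `/`)
  dropped <- attr(m, "dropped") %||%
    data.frame(metabolite = character(), missing_frac = numeric(),
               reason = character(), stringsAsFactors = FALSE)
  if (any(zero_var)) {
    dropped <- rbind(dropped,
                     data.frame(metabolite = colnames(m$values)[zero_var],
                                missing_frac = 0,
                                reason = "zero variance",
                                stringsAsFactors = FALSE))
  }
  structure(list(values = v,
                 class = if (!is.null(m$class)) m$class[!zero_var],
                 participant_id = m$participant_id,
                 dropped = dropped,
                 n_imputed = attr(m, "n_imputed"),
                 log_transform = log_transform),
            class = "prepared_matrix")
}

#' @export
print.prepared_matrix <- function(x, ...) {
  cat(sprintf("<prepared_matrix> %d participants x %d metabolites (log=%s), %d dropped\n",
              nrow(x$values), ncol(x$values), x$log_transform,
              nrow(x$dropped)))
  invisible(x)
}

#' Full metabolite quality-control pipeline
#'
#' Fixed stage order: LOD censoring, removal of metabolites with >30%
#' missingness, half-minimum imputation, then log transform and
#' standardization.
#'
#' @inheritParams censor_below_lod
#' @inheritParams drop_high_missing
#' @inheritParams standardize_metabolome
#' @return a `prepared_matrix`.
#' @export
#' @examples
#' cohort <- generate_cohort(synth_config(n_participants = 40, seed = 3))
#' prep <- prepare_metabolome(cohort$metabolome)
#' prep
prepare_metabolome <- function(m, threshold = 0.30, log_transform = TRUE) {
  m <- censor_below_lod(m)
  m <- drop_high_missing(m, threshold = threshold)
  dropped <- attr(m, "dropped")
  m <- impute_half_min(m)
  attr(m, "dropped") <- dropped
  standardize_metabolome(m, log_transform = log_transform)
}
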