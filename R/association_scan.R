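# exact OLS on a prebuilt design via QR; returns the coefficient table row
# for column `which` plus fit diagnostics
ols_coef <- function(y, X, which = 2L) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    return(list(beta = NA_real_, se = NA_real_, t = NA_real_, p = NA_real_,
                n = length(y), flagged = TRUE))
  }
  beta_all <- qr.coef(qrx, y)
  res <- y - X %*% beta_all
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  xtxi <- chol2inv(qr.R(qrx))
  se <- sqrt(sigma2 * diag(xtxi))
  tval <- beta_all / se
  pval <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  list(beta = unname(beta_all[which]), se = unname(se[which]),
       t = unname(tval[which]), p = unname(pval[which]), n = length(y),
       flagged = FALSE)
}

#' Covariate-adjusted association of one metabolite with one diet score
#'
#' Ordinary least squares with the diet score as the dependent variable and
#' the standardized metabolite as the independent variable, adjusted for any
#' covariates supplied.  Rows with missing values are deleted (complete-case
#' analysis) and the count is recorded.
#'
#' @param y numeric diet-score vector.
#' @param x numeric standardized metabolite vector.
#' @param covariates optional numeric matrix / data.frame of covariates
#'   (e.g. age, sex, eGFR, energy).
#' @return one-row data.frame: `beta`, `se`, `t`, `p`, `n`, `n_dropped`,
#'   `flagged` (rank-deficient design).
#' @export
fit_single <- function(y, x, covariates = NULL) {
  W <- if (is.null(covariates)) NULL else as.matrix(covariates)
  keep <- complete.cases(y, x, W)
  y <- y[keep]
  x <- x[keep]
  X <- cbind(`(Intercept)` = 1, metabolite = x,
             if (!is.null(W)) W[keep, , drop = FALSE])
  if (length(y) <= ncol(X) + 1L) {
    stop_dm("too few complete cases for the adjusted model")
  }
  fit <- ols_coef(y, X, which = 2L)
  data.frame(beta = fit$beta, se = fit$se, t = fit$t, p = fit$p, n = fit$n,
             n_dropped = sum(!keep), flagged = fit$flagged)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values `q_(i) = min_(j>=i) m p_(j) / j`, clipped at 1
#' and returned in the input order.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return vector of adjusted values (q-values).
#' @export
bh_fdr <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop_dm("p-values must lie in [0, 1] with no missing values")
  }
  stats::p.adjust(p, method = "BH")
}

#' Metabolome-wide association scan
#'
#' Fits one covariate-adjusted linear model per (metabolite, diet score)
#' pair — diet score as outcome, standardized metabolite as predictor — and
#' applies Benjamini-Hochberg FDR control within each diet score (or pooled
#' across scores via `fdr_scope`).  Significance is declared at
#' `q <= level`.
#'
#' @param prepared a `prepared_matrix` from [prepare_metabolome()].
#' @param scores diet-score table from [diet_scores()] (columns `mds`,
#'   `mind`, `ahei` or any numeric subset).
#' @param covars data.frame with `participant_id` and covariate columns
#'   (default all of `age`, `sex01`, `egfr`, `energy_kcal` that are
#'   present); pass `NULL` for unadjusted models.
#' @param level FDR significance level (default 0.05).
#' @param fdr_scope `"per_score"` (default) or `"pooled"`.
#' @return long data.frame (`score`, `metabolite`, `class`, `beta`, `se`,
#'   `t`, `p`, `q`, `significant`, `n`); attribute `summary` holds
#'   per-score significant counts and the all-score intersection count.
#' @export
#' @examples
#' cohort <- generate_cohort(synth_config(n_participants = 120, seed = 5))
#' prep <- prepare_metabolome(cohort$metabolome)
#' ds <- diet_scores(cohort$intake, cohort$phenotypes)
#' cv <- scan_covariates(cohort, ds)
#' res <- scan_associations(prep, ds, cv)
#' attr(res, "summary")
scan_associations <- function(prepared, scores, covars = NULL, level = 0.05,
                              fdr_scope = c("per_score", "pooled")) {
  fdr_scope <- match.arg(fdr_scope)
  stopifnot(inherits(prepared, "prepared_matrix"))
  score_cols <- intersect(c("mds", "mind", "ahei"), names(scores))
  if (!length(score_cols)) {
    score_cols <- names(scores)[vapply(scores, is.numeric, logical(1L)) &
                                  names(scores) != "n_valid_visits"]
  }
  ids_x <- as.character(prepared$participant_id)
  ids_y <- as.character(scores$participant_id)
  common <- intersect(ids_x, ids_y)
  if (length(common) < 10L) {
    stop_dm(sprintf(paste0("participant ids misaligned: %d metabolome ids, ",
                           "%d score ids, %d in common"),
                    length(ids_x), length(ids_y), length(common)))
  }
  X <- prepared$values[match(common, ids_x), , drop = FALSE]
  Y <- as.matrix(scores[match(common, ids_y), score_cols, drop = FALSE])
  W <- cbind(`(Intercept)` = rep(1, length(common)))
  if (!is.null(covars)) {
    check_columns(covars, "participant_id", "covariate table")
    cw <- covars[match(common, as.character(covars$participant_id)), ,
                 drop = FALSE]
    num <- setdiff(names(cw)[vapply(cw, is.numeric, logical(1L))],
                   "participant_id")
    if (anyNA(cw[num])) {
      keep <- complete.cases(cw[num])
      X <- X[keep, , drop = FALSE]
      Y <- Y[keep, , drop = FALSE]
      cw <- cw[keep, , drop = FALSE]
      common <- common[keep]
    }
    W <- cbind(W, as.matrix(cw[num]))
  }

  # Frisch-Waugh residualization: one QR of the covariate block serves
  # every metabolite and every score
  qw <- qr(W)
  RX <- X - qr.fitted(qw, X)
  RY <- Y - qr.fitted(qw, Y)
  df <- nrow(X) - ncol(W) - 1L
  if (df < 2L) stop_dm("too few participants for the adjusted scan")
  sxx <- colSums(RX^2)

  res_list <- vector("list", length(score_cols))
  for (s in seq_along(score_cols)) {
    ry <- RY[, s]
    sxy <- colSums(RX * ry)
    beta <- sxy / sxx
    rss <- sum(ry^2) - beta^2 * sxx
    se <- sqrt((rss / df) / sxx)
    tval <- beta / se
    pval <- 2 * pt(abs(tval), df, lower.tail = FALSE)
    res_list[[s]] <- data.frame(
      score = score_cols[s],
      metabolite = colnames(X),
      class = if (!is.null(prepared$class)) unname(prepared$class) else
        NA_character_,
      beta = beta, se = se, t = tval, p = pval,
      n = nrow(X), stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, res_list)
  if (fdr_scope == "per_score") {
    out$q <- NA_real_
    for (s in score_cols) {
      i <- out$score == s
      out$q[i] <- bh_fdr(out$p[i])
    }
  } else {
    out$q <- bh_fdr(out$p)
  }
  out$significant <- out$q <= level
  sig_sets <- lapply(split(out, out$score),
                     function(d) d$metabolite[d$significant])
  attr(out, "summary") <- list(
    n_significant = vapply(sig_sets[score_cols], length, integer(1L)),
    n_common = length(Reduce(intersect, sig_sets)),
    level = level, fdr_scope = fdr_scope)
  out
}

#' Assemble the standard covariate table for adjusted models
#'
#' Pulls age, 0/1-coded sex, eGFR and visit-averaged energy intake for the
#' participants of a cohort.  Sex coding: female = 0, male = 1.
#'
#' @param cohort a `synth_cohort` (or any list with `phenotypes` and
#'   `intake` tables of the same layout).
#' @param scores optional diet-score table; when given, energy is averaged
#'   over the same valid visits used for scoring.
#' @return data.frame `participant_id`, `age`, `sex01`, `egfr`,
#'   `energy_kcal`.
#' @export
scan_covariates <- function(cohort, scores = NULL) {
  ph <- cohort$phenotypes
  valid <- filter_valid_visits(cohort$intake)
  energy <- average_visits(valid[c("participant_id", "energy_kcal")])
  out <- data.frame(participant_id = ph$participant_id,
                    age = ph$age,
                    sex01 = as.numeric(ph$sex == "male"),
                    egfr = ph$egfr,
                    stringsAsFactors = FALSE)
  out$energy_kcal <- energy$energy_kcal[
    match(out$participant_id, energy$participant_id)]
  out
}

#' Diet-score / frailty-index regressions
#'
#' OLS of the frailty index on each diet score with covariate adjustment —
#' the summary regressions reported before any metabolomics.  Slopes can be
#' reported per raw score point (default) or per SD of the diet score.
#'
#' @param scores diet-score table (`participant_id`, `mds`, `mind`, `ahei`).
#' @param fi frailty-index table from [compute_fi()].
#' @param covars covariate table as in [scan_associations()] (or `NULL`).
#' @param per_sd report slopes per SD of the diet score.
#' @return data.frame with one row per score: `beta`, `se`, `t`, `p`, `n`,
#'   `flagged`.
#' @export
diet_fi_regression <- function(scores, fi, covars = NULL, per_sd = FALSE) {
  ids <- intersect(as.character(scores$participant_id),
                   as.character(fi$participant_id[fi$valid]))
  if (length(ids) < 10L) stop_dm("too few participants with valid FI")
  score_cols <- intersect(c("mds", "mind", "ahei"), names(scores))
  y <- fi$fi[match(ids, as.character(fi$participant_id))]
  W <- NULL
  if (!is.null(covars)) {
    cw <- covars[match(ids, as.character(covars$participant_id)), , drop = FALSE]
    num <- setdiff(names(cw)[vapply(cw, is.numeric, logical(1L))],
                   "participant_id")
    W <- as.matrix(cw[num])
  }
  out <- lapply(score_cols, function(s) {
    x <- scores[[s]][match(ids, as.character(scores$participant_id))]
    if (sd(x, na.rm = TRUE) < 1e-12) {
      return(data.frame(score = s, beta = NA_real_, se = NA_real_,
                        t = NA_real_, p = NA_real_, n = length(ids),
                        flagged = TRUE))
    }
    if (per_sd) x <- x / sd(x, na.rm = TRUE)
    if (sd(y, na.rm = TRUE) < 1e-12) {
      return(data.frame(score = s, beta = 0, se = NA_real_, t = NA_real_,
                        p = NA_real_, n = length(ids), flagged = TRUE))
    }
    f <- fit_single(y, x, W)
    data.frame(score = s, beta = f$beta, se = f$se, t = f$t, p = f$p,
               n = f$n, flagged = f$flagged)
  })
  do.call(rbind, out)
}
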