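#' Configuration for the elastic-net signature ensemble
#'
#' Controls the cross-validated elastic-net ensemble: the mixing-parameter
#' grid, the penalty path length, the number of fold-randomization runs,
#' and the permutation-null ensemble used to judge feature significance.
#' Defaults mirror a full cohort analysis (500 runs of 5 folds over a
#' 100-value penalty path, 125 permutation nulls); desk-scale studies
#' reduce `n_runs`, `n_null` and `n_runs_null`.
#'
#' @param alpha_grid elastic-net mixing parameters in \[0, 1\]
#'   (0 = ridge, 1 = lasso); default 0 to 1 in steps of 0.1.
#' @param n_lambda penalty path length (default 100).
#' @param n_runs cross-validation runs, each with a fresh random fold
#'   assignment (default 500).
#' @param n_folds folds per run (default 5).
#' @param n_null permutation null models (default 125).
#' @param n_runs_null cross-validation runs per null model (default:
#'   `n_runs`; reduce for desk-scale work).
#' @param level significance level for feature selection (default 0.05).
#' @param significance_rule how the coefficient- and frequency-based
#'   empirical p-values combine into selection: `"coef"` (default; the
#'   coefficient p-value decides, frequencies are reported), `"both"`
#'   (conjunction) or `"either"`.  The coefficient statistic is the
#'   discriminating criterion across the whole mixing range: at the ridge
#'   end every feature is active in every model, so observed and null
#'   frequencies saturate at 1, and at matched sparsity the frequency
#'   null is bounded below by the active-set fraction.
#' @param alpha_refine when the best alpha is <= 0.1, refine the grid with
#'   0.01..0.09 (default `TRUE`).
#' @param freeze_lambda_null evaluate null-model feature statistics at the
#'   observed model's optimal penalty rather than re-optimizing the penalty
#'   within each null model (default `TRUE`).  Re-optimization drives null
#'   models to the dense end of the path — on a permuted response the
#'   out-of-bag quality function rises monotonically toward weak
#'   regularization — which saturates the frequency null at 1 and destroys
#'   its resolution; freezing compares null and observed models at matched
#'   sparsity.
#' @param seed integer seed for fold assignments and permutations.
#' @return an `enet_config` object.
#' @export
enet_config <- function(alpha_grid = seq(0, 1, by = 0.1), n_lambda = 100L,
                        n_runs = 500L, n_folds = 5L, n_null = 125L,
                        n_runs_null = NULL, level = 0.05,
                        significance_rule = c("coef", "both", "either"),
                        alpha_refine = TRUE, freeze_lambda_null = TRUE,
                        seed = 1L) {
  if (any(alpha_grid < 0 | alpha_grid > 1)) {
    stop_dm("alpha_grid values must lie in [0, 1]")
  }
  cfg <- list(alpha_grid = sort(unique(as.numeric(alpha_grid))),
              n_lambda = check_count(n_lambda, "n_lambda", 2L),
              n_runs = check_count(n_runs, "n_runs", 1L),
              n_folds = check_count(n_folds, "n_folds", 2L),
              n_null = check_count(n_null, "n_null", 20L),
              n_runs_null = if (is.null(n_runs_null)) NULL else
                check_count(n_runs_null, "n_runs_null", 1L),
              level = check_fraction(level, "level"),
              significance_rule = match.arg(significance_rule),
              alpha_refine = isTRUE(alpha_refine),
              freeze_lambda_null = isTRUE(freeze_lambda_null),
              seed = check_count(seed, "seed", 0L))
  class(cfg) <- "enet_config"
  cfg
}

#' Elastic-net coefficient path
#'
#' Solves `(1/2n) ||y - b0 - X b||^2 + lambda (alpha ||b||_1 +
#' (1-alpha)/2 ||b||^2)` along a decreasing log-spaced penalty path (from
#' the smallest penalty with an all-zero lasso solution down `n_lambda`
#' steps), at high solver precision.  The predictor matrix is used as
#' given — standardize it first.
#'
#' @param X numeric predictor matrix (participants x features),
#'   column-standardized.
#' @param y numeric response.
#' @param alpha elastic-net mixing parameter in \[0, 1\].
#' @param lambda_path optional decreasing penalty sequence; computed from
#'   the data when `NULL`.
#' @param n_lambda path length when computing the path.
#' @return list with `lambda`, coefficient matrix `beta` (features x
#'   lambda), and intercepts `a0`.
#' @export
fit_enet_path <- function(X, y, alpha, lambda_path = NULL, n_lambda = 100L) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop_dm("X and y must be finite")
  }
  enet_glmnet(X, y, alpha, lambda_path = lambda_path, n_lambda = n_lambda,
              thresh = 1e-12)
}

# glmnet call solving exactly (1/2n)||y - a0 - Xb||^2 +
# lambda (alpha |b|_1 + (1-alpha)/2 |b|^2).  glmnet internally rescales the
# response by its root-mean-square, which multiplies the effective ridge
# penalty by 1/s while leaving the lasso penalty alone; the mixing
# parameter and penalty are reparameterized to undo that
# (alpha' = alpha / (alpha + s (1 - alpha)), lambda' = lambda * (alpha +
# s (1 - alpha)), s = sd_n(y)), so the reported lambda values are on the
# stated objective's scale.
enet_glmnet <- function(X, y, alpha, lambda_path = NULL, n_lambda = 100L,
                        thresh = 1e-7) {
  s <- sqrt(mean((y - mean(y))^2))
  if (s < 1e-12) stop_dm("response is constant; elastic net undefined")
  mult <- alpha + s * (1 - alpha)
  alpha_eff <- alpha / mult
  fit <- glmnet::glmnet(X, y, alpha = alpha_eff,
                        lambda = if (!is.null(lambda_path))
                          lambda_path * mult,
                        nlambda = n_lambda, standardize = FALSE,
                        intercept = TRUE, thresh = thresh,
                        lambda.min.ratio = if (is.null(lambda_path))
                          0.01 else NULL)
  list(lambda = fit$lambda / mult,
       beta = as.matrix(fit$beta),
       a0 = as.numeric(fit$a0),
       fit = fit)
}

# one cross-validation ensemble at a fixed alpha: per-lambda mean
# out-of-bag quality function plus per-feature statistics at the best lambda
#' Cross-validation ensemble at a fixed mixing parameter
#'
#' Runs `n_runs` random `n_folds`-fold partitions; in each run every
#' training fold-complement is fitted along the shared penalty path and the
#' held-out predictions are pooled within the run.  The run-level quality
#' function (QF) is the Pearson correlation between pooled out-of-bag
#' predictions and the observed response; the penalty is chosen by
#' maximizing the mean QF across runs.  Per-feature mean coefficients and
#' nonzero frequencies over all run x fold models are recorded at the best
#' penalty.
#'
#' @inheritParams fit_enet_path
#' @param config an [enet_config()].
#' @param n_runs override of `config$n_runs` (used for null models).
#' @param seed seed for the fold assignments of this ensemble.
#' @param lambda_path optional fixed penalty path (computed from the data
#'   when `NULL`).
#' @param stat_idx optional path index at which to record the per-feature
#'   statistics (default: the best-QF index).
#' @return list: `lambda`, `mean_qf`, `best_lambda`, `best_qf`,
#'   `coef_mean`, `freq`, `n_models`, `n_qf_excluded`.
#' @export
cv_ensemble <- function(X, y, alpha, config, n_runs = NULL, seed = NULL,
                        lambda_path = NULL, stat_idx = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  k <- config$n_folds
  if (n < 2L * k) stop_dm("need at least 2 observations per fold")
  n_runs <- n_runs %||% config$n_runs
  if (!is.null(seed)) set.seed(seed)

  lam <- lambda_path %||%
    fit_enet_path(X, y, alpha, n_lambda = config$n_lambda)$lambda
  nl <- length(lam)
  qf_runs <- matrix(NA_real_, n_runs, nl)
  sum_coef <- matrix(0, p, nl)
  sum_nz <- matrix(0, p, nl)
  n_models <- 0L

  for (r in seq_len(n_runs)) {
    fold <- sample(rep_len(seq_len(k), n))
    pred <- matrix(NA_real_, n, nl)
    for (f in seq_len(k)) {
      test <- fold == f
      fit <- tryCatch(
        enet_glmnet(X[!test, , drop = FALSE], y[!test], alpha,
                    lambda_path = lam),
        error = function(e) NULL)    # e.g. constant training response
      if (is.null(fit)) next
      b <- fit$beta
      # glmnet may return a shorter path on degenerate folds; align by value
      idx <- match(signif(lam, 10), signif(fit$lambda, 10))
      ok <- !is.na(idx)
      pred[test, ok] <- X[test, , drop = FALSE] %*% b[, idx[ok]] +
        rep(fit$a0[idx[ok]], each = sum(test))
      sum_coef[, ok] <- sum_coef[, ok] + b[, idx[ok]]
      sum_nz[, ok] <- sum_nz[, ok] + (b[, idx[ok]] != 0)
      n_models <- n_models + 1L
    }
    sdp <- apply(pred, 2L, sd)
    ok_l <- is.finite(sdp) & sdp > 0 & colSums(is.na(pred)) == 0L
    if (any(ok_l)) qf_runs[r, ok_l] <- suppressWarnings(
      cor(pred[, ok_l, drop = FALSE], y))
  }
  mean_qf <- colMeans(qf_runs, na.rm = TRUE)
  mean_qf[!is.finite(mean_qf)] <- NA_real_
  if (all(is.na(mean_qf))) {
    stop_dm("quality function undefined at every penalty value")
  }
  best <- which.max(ifelse(is.na(mean_qf), -Inf, mean_qf))
  at <- stat_idx %||% best
  list(alpha = alpha, lambda = lam, mean_qf = mean_qf,
       best_lambda = lam[best], best_idx = best,
       best_qf = mean_qf[best],
       stat_lambda = lam[at],
       coef_mean = sum_coef[, at] / n_models,
       freq = sum_nz[, at] / n_models,
       n_models = n_models,
       n_qf_excluded = sum(is.na(qf_runs)))
}

#' Scan the elastic-net mixing parameter
#'
#' Runs a [cv_ensemble()] at every alpha on the grid and picks the alpha
#' whose best mean out-of-bag QF is largest (ties go to the smaller, more
#' ridge-like alpha).  When the winner is <= 0.1 and `alpha_refine` is set,
#' the grid is refined with 0.01..0.09 and the scan repeated over the new
#' values.
#'
#' @inheritParams cv_ensemble
#' @return list: `alpha_star`, `lambda_star`, `best`, (the winning
#'   ensemble), `grid` (data.frame alpha / best_qf / best_lambda).
#' @export
scan_alpha <- function(X, y, config) {
  run_grid <- function(alphas) {
    lapply(alphas, function(a) {
      cv_ensemble(X, y, a, config,
                  seed = spawn_seed(config$seed,
                                    sprintf("alpha_%0.4f", a)))
    })
  }
  ens <- run_grid(config$alpha_grid)
  grid <- config$alpha_grid
  pick <- function(ens, grid) {
    qf <- vapply(ens, `[[`, numeric(1L), "best_qf")
    best_q <- max(qf)
    which(qf >= best_q - 1e-12)[1L]   # ties -> smallest alpha
  }
  i <- pick(ens, grid)
  if (config$alpha_refine && grid[i] <= 0.1 + 1e-12) {
    extra <- setdiff(seq(0.01, 0.09, by = 0.01), grid)
    if (length(extra)) {
      ens2 <- run_grid(extra)
      ens <- c(ens, ens2)
      grid <- c(grid, extra)
      ord <- order(grid)
      grid <- grid[ord]
      ens <- ens[ord]
      i <- pick(ens, grid)
    }
  }
  list(alpha_star = grid[i], lambda_star = ens[[i]]$best_lambda,
       best = ens[[i]],
       grid = data.frame(
         alpha = grid,
         best_qf = vapply(ens, `[[`, numeric(1L), "best_qf"),
         best_lambda = vapply(ens, `[[`, numeric(1L), "best_lambda")))
}

#' Permutation null ensemble
#'
#' Repeats the cross-validation ensemble on randomly permuted responses
#' (identity permutations are excluded) at the chosen alpha and collects
#' the per-feature mean absolute coefficient and nonzero frequency under
#' the null.  By default (`freeze_lambda_null`) the statistics are taken
#' at the observed model's optimal penalty, comparing null and observed
#' ensembles at matched sparsity; with re-optimization each null model
#' uses its own best penalty.
#'
#' @inheritParams cv_ensemble
#' @param alpha the mixing parameter chosen on the observed response.
#' @param lambda_path the observed model's penalty path (required when
#'   freezing).
#' @param stat_idx the observed model's best path index (used when
#'   freezing).
#' @return list with matrices `null_abs_coef` and `null_freq`
#'   (`n_null` x features).
#' @export
null_ensemble <- function(X, y, alpha, config, lambda_path = NULL,
                          stat_idx = NULL) {
  n <- length(y)
  n_runs_null <- config$n_runs_null %||% config$n_runs
  freeze <- config$freeze_lambda_null %||% TRUE
  if (freeze && (is.null(lambda_path) || is.null(stat_idx))) {
    stop_dm("freezing the null penalty needs lambda_path and stat_idx")
  }
  null_coef <- matrix(NA_real_, config$n_null, ncol(X))
  null_freq <- matrix(NA_real_, config$n_null, ncol(X))
  for (b in seq_len(config$n_null)) {
    set.seed(spawn_seed(config$seed, sprintf("null_perm_%d", b)))
    repeat {
      perm <- sample(n)
      if (!identical(perm, seq_len(n))) break
    }
    ens <- cv_ensemble(X, y[perm], alpha, config, n_runs = n_runs_null,
                       seed = spawn_seed(config$seed,
                                         sprintf("null_cv_%d", b)),
                       lambda_path = if (freeze) lambda_path,
                       stat_idx = if (freeze) stat_idx)
    null_coef[b, ] <- abs(ens$coef_mean)
    null_freq[b, ] <- ens$freq
  }
  list(null_abs_coef = null_coef, null_freq = null_freq)
}

#' Feature significance against the permutation null
#'
#' Add-one empirical p-values comparing each feature's observed mean
#' absolute coefficient and nonzero frequency with their permutation-null
#' distributions.  Selection follows `rule`: by default the coefficient
#' p-value decides (see [enet_config()] for why frequencies are reported
#' but not required); `"both"` demands both p-values at or below `level`,
#' `"either"` accepts one.  Features never active in the observed ensemble
#' (frequency 0) get p = 1 and are never selected.
#'
#' @param model a [cv_ensemble()] result on the observed response.
#' @param null a [null_ensemble()] result.
#' @param level significance level.
#' @param rule `"coef"`, `"both"` or `"either"`.
#' @return data.frame `feature`, `coef_mean`, `freq`, `p_coef`, `p_freq`,
#'   `selected`.
#' @export
feature_significance <- function(model, null, level = 0.05,
                                 rule = c("coef", "both", "either")) {
  rule <- match.arg(rule)
  n_null <- nrow(null$null_abs_coef)
  if (!n_null) stop_dm("null ensemble is empty")
  obs_coef <- abs(model$coef_mean)
  obs_freq <- model$freq
  p_coef <- (1 + colSums(null$null_abs_coef >=
                           rep(obs_coef, each = n_null))) / (1 + n_null)
  p_freq <- (1 + colSums(null$null_freq >=
                           rep(obs_freq, each = n_null))) / (1 + n_null)
  never <- obs_freq <= 0
  p_coef[never] <- 1
  p_freq[never] <- 1
  selected <- switch(rule,
                     coef = p_coef <= level,
                     both = p_coef <= level & p_freq <= level,
                     either = p_coef <= level | p_freq <= level)
  data.frame(feature = names(model$coef_mean) %||%
               sprintf("feature_%d", seq_along(obs_coef)),
             coef_mean = model$coef_mean,
             freq = obs_freq, p_coef = p_coef, p_freq = p_freq,
             selected = selected & !never,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Metabolomic diet score from selected features
#'
#' The coefficient-weighted sum of the selected standardized metabolites:
#' `score_i = sum_j w_j X_ij` over selected features `j`.
#'
#' @param X standardized metabolite matrix.
#' @param selection logical vector (or feature names) of selected columns.
#' @param weights numeric weights for the selected columns (mean ensemble
#'   coefficients at the optimal penalty).
#' @return numeric score vector, one per row of `X`.
#' @export
compute_metds <- function(X, selection, weights) {
  X <- as.matrix(X)
  cols <- if (is.logical(selection)) which(selection) else
    match(selection, colnames(X))
  if (!length(cols)) {
    stop_dm("no metabolites selected; the metabolomic diet score is undefined")
  }
  if (length(weights) != length(cols)) {
    stop_dm("weights must match the selected features")
  }
  drop(X[, cols, drop = FALSE] %*% weights)
}

#' Fit a metabolomic diet signature
#'
#' The full signature workflow: scan the elastic-net mixing parameter by
#' cross-validated out-of-bag correlation, build a permutation null
#' ensemble at the chosen alpha, select features whose coefficient and
#' selection-frequency statistics beat the null, and form the metabolomic
#' diet score (metDS) as the coefficient-weighted sum of the selected
#' standardized metabolites.
#'
#' @param X standardized metabolite matrix (participants x metabolites)
#'   or a `prepared_matrix`.
#' @param y numeric diet-score vector aligned with the rows of `X`.
#' @param config an [enet_config()].
#' @return an object of class `enet_signature` with components
#'   `alpha_star`, `lambda_star`, `grid`, `ensemble`, `significance`,
#'   `weights`, `metds`, `qf`, `r2_raw`, `n`, `config`.
#' @export
#' @examples
#' \donttest{
#' set.seed(1)
#' X <- scale(matrix(rnorm(150 * 20), 150))
#' colnames(X) <- sprintf("met_%02d", 1:20)
#' y <- X[, 1:3] %*% rep(0.5, 3) + rnorm(150)
#' cfg <- enet_config(alpha_grid = c(0.5), n_runs = 20, n_null = 20,
#'                    n_runs_null = 5, seed = 1)
#' sig <- enet_signature(X, y, cfg)
#' print(sig)
#' }
enet_signature <- function(X, y, config = enet_config()) {
  if (inherits(X, "prepared_matrix")) X <- X$values
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop_dm("X and y sizes differ")
  scan <- scan_alpha(X, y, config)
  model <- scan$best
  names(model$coef_mean) <- colnames(X)
  names(model$freq) <- colnames(X)
  null <- null_ensemble(X, y, scan$alpha_star, config,
                        lambda_path = model$lambda,
                        stat_idx = model$best_idx)
  sig <- feature_significance(model, null, level = config$level,
                              rule = config$significance_rule %||% "coef")
  sel <- sig$selected
  metds <- if (any(sel)) {
    compute_metds(X, sel, model$coef_mean[sel])
  } else {
    NULL
  }
  out <- list(alpha_star = scan$alpha_star,
              lambda_star = scan$lambda_star,
              grid = scan$grid,
              ensemble = model,
              null = null,
              significance = sig,
              weights = if (any(sel))
                setNames(model$coef_mean[sel], sig$feature[sel]) else
                  numeric(0),
              metds = metds,
              qf = model$best_qf,
              r2_raw = if (!is.null(metds) && sd(metds) > 0)
                cor(metds, y)^2 else NA_real_,
              n = nrow(X),
              y = y,
              config = config)
  class(out) <- "enet_signature"
  out
}

#' @export
print.enet_signature <- function(x, ...) {
  cat(sprintf("<enet_signature> n = %d, %d features\n", x$n,
              nrow(x$significance)))
  cat(sprintf("  alpha* = %g, lambda* = %.4g, OOB QF = %.3f\n",
              x$alpha_star, x$lambda_star, x$qf))
  cat(sprintf("  selected features: %d; metDS ~ response r^2 = %.3f\n",
              sum(x$significance$selected), x$r2_raw))
  invisible(x)
}

#' @export
summary.enet_signature <- function(object, ...) {
  sel <- object$significance[object$significance$selected, , drop = FALSE]
  structure(list(alpha_star = object$alpha_star,
                 lambda_star = object$lambda_star,
                 qf = object$qf, r2_raw = object$r2_raw,
                 n_selected = nrow(sel),
                 selected = sel[order(-abs(sel$coef_mean)), ],
                 grid = object$grid),
            class = "summary.enet_signature")
}

#' @export
print.summary.enet_signature <- function(x, ...) {
  cat(sprintf("alpha* = %g, lambda* = %.4g, OOB QF = %.3f, r^2 = %.3f\n",
              x$alpha_star, x$lambda_star, x$qf, x$r2_raw))
  cat(sprintf("%d selected features:\n", x$n_selected))
  print(head(x$selected, 20), row.names = FALSE)
  invisible(x)
}

#' @export
coef.enet_signature <- function(object, all = FALSE, ...) {
  if (all) object$ensemble$coef_mean else object$weights
}

#' @export
predict.enet_signature <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$metds)
  if (inherits(newdata, "prepared_matrix")) newdata <- newdata$values
  compute_metds(newdata, names(object$weights), object$weights)
}

#' Variance in a response explained by the metabolomic diet score
#'
#' Squared correlation between the metDS and the response, either raw or
#' partial given covariates (both the response and the metDS are
#' residualized on the covariates first).
#'
#' @param object an `enet_signature` fit.
#' @param covars optional numeric covariate matrix/data.frame aligned with
#'   the fitting rows.
#' @return proportion of variance explained in \[0, 1\].
#' @export
variance_explained <- function(object, covars = NULL) {
  stopifnot(inherits(object, "enet_signature"))
  if (is.null(object$metds)) return(NA_real_)
  if (is.null(covars)) return(object$r2_raw)
  W <- cbind(1, as.matrix(covars))
  qw <- qr(W)
  ry <- object$y - qr.fitted(qw, object$y)
  rm_ <- object$metds - qr.fitted(qw, object$metds)
  cor(ry, rm_)^2
}
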