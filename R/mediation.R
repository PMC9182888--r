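# exact least-squares coefficients; NULL when the design is rank-deficient
ls_coef <- function(X, y) {
  fit <- lm.fit(X, y)
  if (fit$rank < ncol(X)) return(NULL)
  fit$coefficients
}

#' Bootstrap mediation of a diet-frailty association through a metabolite
#' signature
#'
#' Product-of-coefficients mediation with linear models and no
#' treatment-mediator interaction: the mediator is regressed on the
#' treatment (`M = i1 + a D`), the outcome on both (`Y = i2 + c' D + b M`),
#' and the effects are decomposed as ACME `= a b` (average causal mediation
#' effect), ADE `= c'` (average direct effect) and TE `= a b + c'` (total
#' effect, identical to the slope of `Y` on `D` alone), with PM `= ACME/TE`
#' the proportion mediated.  Uncertainty comes from nonparametric bootstrap
#' resampling of rows: point estimates are bootstrap means, intervals are
#' 2.5/97.5 percentiles, and two-sided p-values use the add-one sign-count
#' estimator.  Covariates may be added to both models.
#'
#' @param treatment numeric diet-score vector.
#' @param mediator numeric metabolomic-diet-score vector.
#' @param outcome numeric frailty-index vector.
#' @param covars optional numeric covariate matrix/data.frame added to both
#'   models (off by default).
#' @param n_boot bootstrap resamples (default 500).
#' @param seed integer seed.
#' @return a `mediation_fit` object: `estimates` table (quantity, estimate,
#'   full-sample estimate, CI, p), bootstrap `draws`, the maximum per-draw
#'   deviation of `TE - (ACME + ADE)` (`identity_dev`), `pm_mean_ratio`,
#'   and bookkeeping (`n`, `n_boot`, `seed`, `n_redrawn`).
#' @export
#' @examples
#' set.seed(2)
#' d <- rnorm(200)
#' m <- 0.6 * d + rnorm(200)
#' y <- 0.3 * d + 0.5 * m + rnorm(200)
#' fit <- mediate_metds(d, m, y, n_boot = 100, seed = 1)
#' fit
mediate_metds <- function(treatment, mediator, outcome, covars = NULL,
                          n_boot = 500L, seed = 1L) {
  n_boot <- check_count(n_boot, "n_boot", 1L)
  W <- if (is.null(covars)) NULL else as.matrix(covars)
  keep <- complete.cases(treatment, mediator, outcome, W)
  d <- treatment[keep]
  m <- mediator[keep]
  y <- outcome[keep]
  W <- if (!is.null(W)) W[keep, , drop = FALSE]
  n <- length(d)
  if (n < 30L) stop_dm("mediation needs at least 30 complete cases")
  if (sd(d) < 1e-12) stop_dm("treatment has zero variance")
  if (sd(m) < 1e-12) stop_dm("mediator has zero variance")

  fit_once <- function(idx) {
    dd <- d[idx]; mm <- m[idx]; yy <- y[idx]
    ww <- if (!is.null(W)) W[idx, , drop = FALSE]
    Xm <- cbind(1, dd, ww)
    cm <- ls_coef(Xm, mm)
    if (is.null(cm)) return(NULL)
    Xy <- cbind(1, dd, mm, ww)
    cy <- ls_coef(Xy, yy)
    if (is.null(cy)) return(NULL)
    ct <- ls_coef(Xm, yy)          # total-effect regression, same design
    a <- cm[2L]; cprime <- cy[2L]; b <- cy[3L]
    c(acme = unname(a * b), ade = unname(cprime),
      te = unname(ct[2L]), a = unname(a), b = unname(b))
  }

  full <- fit_once(seq_len(n))
  if (is.null(full)) stop_dm("rank-deficient design on the full sample")

  set.seed(spawn_seed(seed, "mediation_boot"))
  draws <- matrix(NA_real_, n_boot, 5L,
                  dimnames = list(NULL, c("acme", "ade", "te", "a", "b")))
  n_redrawn <- 0L
  for (bb in seq_len(n_boot)) {
    repeat {
      res <- fit_once(sample.int(n, n, replace = TRUE))
      if (!is.null(res)) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 100L * n_boot) {
        stop_dm("bootstrap designs persistently rank-deficient")
      }
    }
    draws[bb, ] <- res
  }
  identity_dev <- max(abs(draws[, "te"] - (draws[, "acme"] + draws[, "ade"])))

  pval <- function(x) {
    min(1, 2 * min((1 + sum(x <= 0)) / (1 + length(x)),
                   (1 + sum(x >= 0)) / (1 + length(x))))
  }
  est <- colMeans(draws[, c("acme", "ade", "te"), drop = FALSE])
  pm_draws <- draws[, "acme"] / draws[, "te"]
  te_ok <- abs(est["te"]) > 1e-10
  pm_point <- if (te_ok) unname(est["acme"] / est["te"]) else NA_real_
  qs <- apply(draws[, c("acme", "ade", "te"), drop = FALSE], 2L, quantile,
              probs = c(0.025, 0.975), names = FALSE)
  pm_ci <- quantile(pm_draws, c(0.025, 0.975), names = FALSE, na.rm = TRUE)

  estimates <- data.frame(
    quantity = c("ACME", "ADE", "TE", "PM"),
    estimate = c(unname(est), pm_point),
    full_sample = c(unname(full[c("acme", "ade", "te")]),
                    if (abs(full["te"]) > 1e-10)
                      unname(full["acme"] / full["te"]) else NA_real_),
    ci_low = c(qs[1L, ], pm_ci[1L]),
    ci_high = c(qs[2L, ], pm_ci[2L]),
    p = c(pval(draws[, "acme"]), pval(draws[, "ade"]), pval(draws[, "te"]),
          pval(pm_draws)),
    stringsAsFactors = FALSE)
  estimates$significant <- estimates$p <= 0.05

  structure(list(estimates = estimates, draws = draws,
                 identity_dev = identity_dev,
                 pm_mean_ratio = mean(pm_draws[is.finite(pm_draws)]),
                 pm_undefined = !te_ok,
                 n = n, n_boot = n_boot, seed = seed,
                 n_redrawn = n_redrawn, adjusted = !is.null(W)),
            class = "mediation_fit")
}

#' @export
print.mediation_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<mediation_fit> n = %d, %d bootstrap draws%s\n", x$n,
              x$n_boot, if (x$adjusted) " (covariate-adjusted)" else ""))
  est <- x$estimates
  est$estimate <- signif(est$estimate, digits)
  est$ci_low <- signif(est$ci_low, digits)
  est$ci_high <- signif(est$ci_high, digits)
  print(est[c("quantity", "estimate", "ci_low", "ci_high", "p")],
        row.names = FALSE)
  if (x$pm_undefined) cat("  (PM undefined: total effect near zero)\n")
  invisible(x)
}

#' @export
summary.mediation_fit <- function(object, ...) object$estimates

#' Combine mediation fits into a report table
#'
#' Long-format table with one row per quantity (ACME, ADE, TE, PM) per diet
#' score, in fixed column order, with significance flagged at p <= 0.05.
#'
#' @param results named list of `mediation_fit` objects (names = diet
#'   scores).
#' @return data.frame `score`, `quantity`, `estimate`, `ci_low`,
#'   `ci_high`, `p`, `significant`.
#' @export
mediation_table <- function(results) {
  if (!length(results)) stop_dm("no mediation results supplied")
  rows <- lapply(names(results), function(nm) {
    est <- results[[nm]]$estimates
    cbind(score = nm,
          est[c("quantity", "estimate", "ci_low", "ci_high", "p",
                "significant")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
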