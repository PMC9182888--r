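test_that("lasso on an orthonormal design matches the soft-threshold closed form", {
  set.seed(11)
  n <- 60; p <- 8
  X <- orthonormal_design(n, p)
  beta_true <- c(2, -1.5, 1, 0.5, rep(0, 4))
  y <- drop(X %*% beta_true + rnorm(n, 0, 0.5))
  y <- y - mean(y)
  path <- fit_enet_path(X, y, alpha = 1)
  z <- drop(crossprod(X, y)) / n
  for (l in c(2, 10, 25, 50)) {
    expect_equal(unname(path$beta[, l]), unname(soft(z, path$lambda[l])),
                 tolerance = 1e-8)
  }
  # the path starts at the smallest all-zero penalty
  expect_true(all(path$beta[, 1] == 0))
  expect_equal(path$lambda[1], max(abs(z)), tolerance = 1e-6)
})

test_that("ridge solutions match the closed form", {
  set.seed(12)
  n <- 50; p <- 6
  X <- scale(matrix(rnorm(n * p), n))
  y <- drop(X %*% rnorm(p) + rnorm(n))
  y <- y - mean(y)
  path <- fit_enet_path(X, y, alpha = 0)
  for (l in c(5, 20, 60)) {
    lam <- path$lambda[l]
    closed <- solve(crossprod(X) / n + lam * diag(p), crossprod(X, y) / n)
    expect_equal(unname(path$beta[, l]), drop(closed), tolerance = 1e-6)
  }
  expect_error(fit_enet_path(X, c(y[-1], NA), 0.5), "finite")
})

test_that("path solutions satisfy the KKT conditions of the stated objective", {
  set.seed(13)
  for (alpha in c(0.3, 0.7, 1)) {
    X <- scale(matrix(rnorm(50 * 20), 50))
    y <- drop(X[, 1:3] %*% c(1, -1, 0.5) + rnorm(50))
    path <- fit_enet_path(X, y, alpha = alpha)
    for (l in seq(1, length(path$lambda), by = 20)) {
      dev <- kkt_residual(X, y, path$a0[l], path$beta[, l],
                          path$lambda[l], alpha)
      expect_lt(dev, 1e-6)
    }
  }
})

test_that("cross-validation ensembles are reproducible and track signal strength", {
  set.seed(14)
  X <- scale(matrix(rnorm(120 * 15), 120))
  colnames(X) <- sprintf("m%02d", 1:15)
  y <- drop(X[, 1:3] %*% rep(0.8, 3) + rnorm(120))
  cfg <- enet_config(n_runs = 10, n_folds = 5, n_null = 20, seed = 2)
  e1 <- cv_ensemble(X, y, 0.5, cfg, seed = 99)
  e2 <- cv_ensemble(X, y, 0.5, cfg, seed = 99)
  expect_identical(e1$mean_qf, e2$mean_qf)
  expect_identical(e1$coef_mean, e2$coef_mean)

  # strong signal: out-of-bag correlation is high
  expect_gt(e1$best_qf, 0.5)
  # out-of-bag quality never beats the in-sample correlation
  ins <- fit_enet_path(X, y, 0.5, lambda_path = e1$lambda)
  fitted <- X %*% ins$beta[, e1$best_idx] + ins$a0[e1$best_idx]
  expect_lte(e1$best_qf, cor(fitted, y) + 0.02)

  # pure noise: best mean QF statistically indistinguishable from zero
  set.seed(15)
  qfs <- replicate(5, {
    yn <- rnorm(120)
    cv_ensemble(X, yn, 0.5, cfg, seed = sample.int(1e6, 1))$best_qf
  })
  expect_lt(mean(qfs), 3 / sqrt(120))
})

test_that("alpha scan picks ridge for dense correlated signal and refines small alphas", {
  set.seed(16)
  n <- 150; p <- 40
  f <- rnorm(n)
  X <- scale(sqrt(0.7) * matrix(f, n, p) +
               sqrt(0.3) * matrix(rnorm(n * p), n))
  colnames(X) <- sprintf("m%02d", 1:p)
  y <- drop(X %*% rep(0.15, p) + rnorm(n))
  cfg <- enet_config(alpha_grid = c(0, 1), n_runs = 5, n_null = 20,
                     alpha_refine = FALSE, seed = 3)
  sc <- scan_alpha(X, y, cfg)
  expect_equal(sc$alpha_star, 0)

  cfg_ref <- enet_config(alpha_grid = c(0, 1), n_runs = 5, n_null = 20,
                         alpha_refine = TRUE, seed = 3)
  sc_ref <- scan_alpha(X, y, cfg_ref)
  expect_true(all(seq(0.01, 0.09, by = 0.01) %in% sc_ref$grid$alpha))

  # single-alpha grid returns that alpha
  cfg1 <- enet_config(alpha_grid = 0.4, n_runs = 5, n_null = 20, seed = 3)
  expect_equal(scan_alpha(X, y, cfg1)$alpha_star, 0.4)
})

test_that("empirical feature p-values follow the add-one formula", {
  p <- 4
  model <- list(coef_mean = setNames(c(0.9, 0.0, 0.1, 0.5),
                                     paste0("f", 1:4)),
                freq = setNames(c(1, 0, 0.4, 0.9), paste0("f", 1:4)))
  n_null <- 125
  set.seed(17)
  null <- list(null_abs_coef = matrix(runif(n_null * p, 0, 0.4), n_null),
               null_freq = matrix(runif(n_null * p, 0, 0.8), n_null))
  sig <- feature_significance(model, null, level = 0.05)
  # f1 beats all 125 nulls on both criteria
  expect_equal(sig$p_coef[1], 1 / 126)
  expect_equal(sig$p_freq[1], 1 / 126)
  expect_true(sig$selected[1])
  # a feature never selected in the observed ensemble gets p = 1
  expect_equal(sig$p_coef[2], 1)
  expect_false(sig$selected[2])
  # a feature at the null median sits near p = 0.5
  null$null_abs_coef[, 3] <- seq(0, 0.2, length.out = n_null)
  sig3 <- feature_significance(model, null)
  expect_equal(sig3$p_coef[3], (1 + sum(null$null_abs_coef[, 3] >= 0.1)) /
                 126)
  expect_gt(sig3$p_coef[3], 0.4)
  expect_lt(sig3$p_coef[3], 0.6)
})

test_that("the metabolomic diet score is the weighted sum of selected columns", {
  set.seed(18)
  X <- scale(matrix(rnorm(40 * 6), 40))
  colnames(X) <- paste0("m", 1:6)
  # a single selected feature with unit weight reproduces that column
  expect_equal(compute_metds(X, c(TRUE, rep(FALSE, 5)), 1), X[, 1])
  # permutation equivariance
  w <- c(0.5, -0.2)
  sel <- c("m2", "m5")
  s <- compute_metds(X, sel, w)
  perm <- sample(40)
  expect_equal(compute_metds(X[perm, ], sel, w), s[perm])
  expect_error(compute_metds(X, rep(FALSE, 6), numeric(0)), "undefined")
})

test_that("the full signature fit recovers planted features and exposes methods", {
  set.seed(19)
  n <- 150; p <- 25
  X <- scale(matrix(rnorm(n * p), n))
  colnames(X) <- sprintf("met_%02d", 1:p)
  y <- drop(X[, 1:4] %*% rep(0.6, 4) + rnorm(n))
  cfg <- enet_config(alpha_grid = 0.5, n_runs = 10, n_null = 25,
                     n_runs_null = 4, seed = 4)
  sig <- enet_signature(X, y, cfg)
  sel <- sig$significance$feature[sig$significance$selected]
  expect_gte(sum(sprintf("met_%02d", 1:4) %in% sel), 3)
  expect_s3_class(sig, "enet_signature")
  expect_named(coef(sig), sel, ignore.order = TRUE)
  expect_equal(predict(sig, X), sig$metds)
  expect_output(print(sig), "enet_signature")
  expect_true(variance_explained(sig) > 0.2)
  # covariate-adjusted variance explained is a valid proportion
  z <- rnorm(n)
  expect_true(variance_explained(sig, covars = cbind(z)) >= 0 &&
                variance_explained(sig, covars = cbind(z)) <= 1)
})
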