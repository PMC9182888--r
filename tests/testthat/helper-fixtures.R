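# fixtures shared across test files; everything is built in code

# two-participant cohort where A strictly dominates B on every beneficial
# MDS component, is strictly lower on both detrimental ones, and both have
# the stated alcohol intake (g/day)
mds_dominance_pair <- function(alcohol_a = 10, alcohol_b = 10) {
  a <- data.frame(participant_id = "A", veg_srv_d = 5, legume_srv_d = 2,
                  fruit_srv_d = 4, wholegrain_srv_d = 3, fish_srv_wk = 5,
                  mufa_g_d = 40, sfa_g_d = 10, meat_srv_d = 0.1,
                  dairy_srv_d = 0.2, alcohol_g_d = alcohol_a,
                  stringsAsFactors = FALSE)
  b <- data.frame(participant_id = "B", veg_srv_d = 1, legume_srv_d = 0.2,
                  fruit_srv_d = 1, wholegrain_srv_d = 0.5, fish_srv_wk = 1,
                  mufa_g_d = 15, sfa_g_d = 25, meat_srv_d = 2,
                  dairy_srv_d = 3, alcohol_g_d = alcohol_b,
                  stringsAsFactors = FALSE)
  rbind(a, b)
}

# minimal prepared_matrix wrapper for matrices built directly in tests
as_prepared <- function(X, ids = NULL) {
  structure(list(values = X, class = NULL,
                 participant_id = ids %||% sprintf("P%04d", seq_len(nrow(X))),
                 dropped = data.frame(), n_imputed = NULL,
                 log_transform = FALSE),
            class = "prepared_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force step-up FDR oracle, straight from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, m * p[o] / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# closed-form OLS via normal equations (independent of the package's QR path)
normal_eq_fit <- function(y, X) {
  xtx <- crossprod(X)
  beta <- solve(xtx, crossprod(X, y))
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(solve(xtx)))
  list(beta = unname(drop(beta)), se = unname(se))
}

# standardized matrix whose columns are orthonormal in the 1/n inner
# product (X'X = n I), for soft-thresholding oracles
orthonormal_design <- function(n, p) {
  q <- qr.Q(qr(matrix(rnorm(n * p), n)))
  q <- scale(q, center = TRUE, scale = FALSE)
  q <- qr.Q(qr(q))[, seq_len(p), drop = FALSE]
  q * sqrt(n)
}

# soft-threshold operator
soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

# KKT subgradient residual of the elastic-net objective
# (1/2n)||y - a0 - Xb||^2 + lambda (alpha |b|_1 + (1-alpha)/2 |b|^2)
kkt_residual <- function(X, y, a0, beta, lambda, alpha) {
  r <- y - a0 - X %*% beta
  g <- crossprod(X, r) / nrow(X) - lambda * (1 - alpha) * beta
  nz <- beta != 0
  dev_nz <- if (any(nz)) max(abs(g[nz] - lambda * alpha * sign(beta[nz])))
  else 0
  dev_z <- if (any(!nz)) max(0, max(abs(g[!nz])) - lambda * alpha) else 0
  max(dev_nz, dev_z)
}
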