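mk_matrix <- function(values, lod) {
  metabolite_matrix(values, lod)
}

test_that("LOD censoring is strictly below the limit", {
  v <- matrix(c(0.5, 1.0, 2.0, 1.5), 2,
              dimnames = list(NULL, c("m1", "m2")))
  m <- mk_matrix(v, c(m1 = 1.0, m2 = 1.0))
  cen <- censor_below_lod(m)
  expect_true(is.na(cen$values[1, 1]))      # 0.5 < 1.0 -> missing
  expect_equal(unname(cen$values[2, 1]), 1.0)       # equal to LOD -> retained
  expect_false(anyNA(cen$values[, 2]))

  # engineered 10% sub-LOD column reports 10% missingness
  set.seed(1)
  x <- sort(runif(100, 1, 2))
  x[1:10] <- runif(10, 0, 0.5)
  m2 <- mk_matrix(cbind(ma = x), c(ma = 0.99))
  expect_equal(mean(is.na(censor_below_lod(m2)$values)), 0.10)

  expect_error(metabolite_matrix(v, c(m1 = -1, m2 = 1)), "negative LOD")
  expect_error(metabolite_matrix(-v, c(m1 = 1, m2 = 1)), ">= 0")
})

test_that("missingness filter removes strictly above 30% and keeps 30% exactly", {
  v <- matrix(runif(200, 1, 2), 100, 2,
              dimnames = list(NULL, c("at30", "at31")))
  v[1:30, 1] <- NA
  v[1:31, 2] <- NA
  m <- mk_matrix(ifelse(is.na(v), NA, v), c(at30 = 0, at31 = 0))
  m$values <- v
  out <- drop_high_missing(m)
  expect_identical(colnames(out$values), "at30")
  expect_equal(attr(out, "dropped")$metabolite, "at31")

  # engineered set: exactly the five over-threshold columns are removed
  set.seed(2)
  v2 <- matrix(runif(1000, 1, 2), 100, 10,
               dimnames = list(NULL, sprintf("m%02d", 1:10)))
  hit <- c(2, 4, 5, 7, 9)
  for (j in hit) v2[seq_len(35), j] <- NA
  m2 <- mk_matrix(matrix(1, 100, 10,
                         dimnames = dimnames(v2)),
                  setNames(rep(0, 10), colnames(v2)))
  m2$values <- v2
  out2 <- drop_high_missing(m2)
  expect_setequal(attr(out2, "dropped")$metabolite, colnames(v2)[hit])

  # no missingness: identity, and re-running is idempotent
  m3 <- mk_matrix(matrix(runif(40, 1, 2), 10, 4,
                         dimnames = list(NULL, paste0("k", 1:4))),
                  setNames(rep(0, 4), paste0("k", 1:4)))
  out3 <- drop_high_missing(m3)
  expect_identical(out3$values, m3$values)
  expect_identical(drop_high_missing(out3)$values, out3$values)
})

test_that("half-minimum imputation fills every gap below the observed minimum", {
  v <- matrix(c(2, 4, NA, 1, 1, 1, 0, 5, NA), 3,
              dimnames = list(NULL, c("a", "b", "c")))
  m <- mk_matrix(matrix(1, 3, 3, dimnames = dimnames(v)),
                 c(a = 0, b = 0, c = 0))
  m$values <- v
  out <- impute_half_min(m)
  expect_equal(unname(out$values[3, "a"]), 1)     # half of min {2, 4}
  expect_equal(unname(out$values[, "b"]), rep(1, 3))  # untouched
  expect_equal(unname(out$values[3, "c"]), 0)     # half of a zero minimum
  expect_equal(attr(out, "n_imputed"), c(a = 1L, b = 0L, c = 1L))
  expect_false(anyNA(out$values))
  # imputed values never exceed observed values in their column
  expect_true(all(out$values[3, c("a", "c")] <=
                    apply(v[1:2, c("a", "c")], 2, min)))
  # idempotent on complete data
  expect_identical(impute_half_min(out)$values, out$values)

  m_bad <- m
  m_bad$values[, "a"] <- NA
  expect_error(impute_half_min(m_bad), "no observed values")
})

test_that("standardization centers and scales with the sample SD convention", {
  v <- matrix(c(1, 2, 3, 5, 5, 5), 3, dimnames = list(NULL, c("x", "const")))
  m <- mk_matrix(v, c(x = 0, const = 0))
  expect_warning(out <- standardize_metabolome(m, log_transform = FALSE),
                 "zero-variance")
  expect_equal(out$values[, "x"], c(-1, 0, 1))
  expect_false("const" %in% colnames(out$values))
  expect_true("const" %in% out$dropped$metabolite)

  # every retained column is mean 0, sample SD 1
  set.seed(3)
  v2 <- matrix(rlnorm(500), 50, 10,
               dimnames = list(NULL, paste0("m", 1:10)))
  m2 <- mk_matrix(v2, setNames(rep(0, 10), paste0("m", 1:10)))
  out2 <- standardize_metabolome(m2, log_transform = TRUE)
  expect_true(all(abs(colMeans(out2$values)) < 1e-9))
  expect_true(all(abs(apply(out2$values, 2, sd) - 1) < 1e-9))

  # ranks preserved (standardization is monotone per column)
  expect_equal(order(out2$values[, 1]), order(v2[, 1]))

  expect_error(standardize_metabolome(
    mk_matrix(matrix(c(1, NA), 2, 1, dimnames = list(NULL, "z")),
              c(z = 0))), "complete")
})

test_that("the full preparation pipeline runs censor -> drop -> impute -> standardize", {
  co <- generate_cohort(synth_config(n_participants = 80,
                                     n_metabolites = 50, n_planted = 5,
                                     drop_fraction = 0.1, seed = 17))
  prep <- prepare_metabolome(co$metabolome)
  expect_false(anyNA(prep$values))
  expect_true(all(abs(colMeans(prep$values)) < 1e-9))
  expect_true(all(abs(apply(prep$values, 2, sd) - 1) < 1e-9))
  expect_true(all(co$truth$dropped_by_design %in% prep$dropped$metabolite))
  expect_equal(ncol(prep$values) + length(unique(prep$dropped$metabolite)),
               50)
})
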