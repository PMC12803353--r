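# Association engine: log-space tails, OLS correctness, the
# residualization fast path, and model-level behaviours.

test_that("neglog10_p_from_t matches the arbitrary-precision oracle", {
  got <- neglog10_p_from_t(tail_oracle[, "z"], tail_oracle[, "df"])
  rel <- abs(got - tail_oracle[, "neglog10_p"]) / tail_oracle[, "neglog10_p"]
  expect_lt(max(rel), 1e-6)
})

test_that("neglog10_p_from_t handles the central case, seam and errors", {
  expect_equal(neglog10_p_from_t(0, 10), 0)
  expect_equal(neglog10_p_from_t(0, Inf), 0)
  # continuity across the normal-regime switch at |z| = 37
  lo <- neglog10_p_from_t(36.999999, Inf)
  hi <- neglog10_p_from_t(37.000001, Inf)
  expect_lt(abs(hi - lo) / lo, 1e-6)
  # symmetric in the sign of t
  expect_equal(neglog10_p_from_t(-5, 30), neglog10_p_from_t(5, 30))
  expect_error(neglog10_p_from_t(Inf, 10), "non-finite")
  expect_error(neglog10_p_from_t(1, 0), "df")
})

test_that("fit_linear_assoc has calibrated type-I error under the null", {
  set.seed(101)
  n <- 1000
  dosage <- rbinom(n, 2, 0.3)
  hits <- vapply(1:2000, function(i) {
    fit_linear_assoc(rnorm(n), dosage)$neglog10_p > -log10(0.05)
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 0.015)
})

test_that("fit_linear_assoc flags perfect fits and degenerate inputs", {
  set.seed(7)
  g <- rbinom(50, 2, 0.4)
  cov <- cbind(x = rnorm(50))
  y <- 2 * g + 0.5 * cov[, 1] + 1          # exact linear combination
  expect_warning(fit <- fit_linear_assoc(y, g, cov), "perfect fit")
  expect_true(fit$perfect_fit)
  expect_equal(fit$neglog10_p, 9999)
  expect_error(fit_linear_assoc(rnorm(50), rep(1, 50)), "constant")
  expect_error(fit_linear_assoc(rnorm(5), rbinom(5, 2, .5)), "complete cases")
  expect_error(fit_linear_assoc(rnorm(50), g, cbind(a = g, b = 2 * g)),
               "rank-deficient")
})

test_that("fit_linear_assoc recovers a planted INT-scale effect", {
  set.seed(55)
  n <- 20000
  g <- rbinom(n, 2, 0.3)
  y <- 0.08 * g + rnorm(n)
  fit <- fit_linear_assoc(y, g)
  expect_lt(abs(fit$beta - 0.08), 3 * fit$se)
  expect_equal(abs(fit$t_stat), abs(fit$beta) / fit$se, tolerance = 1e-9)
  expect_equal(fit$df, fit$n - 2)
})

test_that("flipping dosage coding flips beta and preserves the p-value", {
  co <- make_small_cohort(n = 300)
  y <- co$phenotypes[, "T1"]
  f1 <- fit_linear_assoc(y, co$geno[, "v001"], co$covariates)
  f2 <- fit_linear_assoc(y, 2 - co$geno[, "v001"], co$covariates)
  expect_equal(f1$beta, -f2$beta, tolerance = 1e-12)
  expect_equal(f1$neglog10_p, f2$neglog10_p, tolerance = 1e-9)
})

test_that("residualize matches the explicit normal-equations oracle", {
  X <- cbind(1, c(1, 2, 3, 4, 5, 6), c(0, 1, 0, 1, 1, 0))
  m <- cbind(a = c(2.2, 1.1, 3.5, 0.4, 5.0, 2.7),
             b = c(1, 0, 1, 1, 0, 2))
  # independent oracle: hat-matrix projection from the normal equations
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  expected <- (diag(6) - H) %*% m
  got <- residualize(m, X[, -1])
  expect_equal(unname(got), unname(expected), tolerance = 1e-10)
  # orthogonality and idempotence
  expect_lt(max(abs(t(got) %*% X[, -1])), 1e-8 * max(colSums(m^2)))
  expect_equal(residualize(got, X[, -1]), got, tolerance = 1e-10)
  expect_error(residualize(m, cbind(a = X[, 2], b = 2 * X[, 2])),
               "rank-deficient")
})

test_that("fast-path scan equals naive per-test OLS", {
  co <- make_small_cohort(n = 600)
  fast <- scan_associations(co$geno[, 1:5], co$phenotypes, co$covariates,
                            engine = "fast")
  naive <- scan_associations(co$geno[, 1:5], co$phenotypes, co$covariates,
                             engine = "naive")
  expect_equal(fast$test_id, naive$test_id)
  expect_lt(max(abs(fast$neglog10_p - naive$neglog10_p)), 1e-8)
  expect_lt(max(abs(fast$beta - naive$beta)), 1e-10)
  expect_equal(fast$n, naive$n)
  expect_equal(fast$df, naive$df)
})

test_that("scan_variant is invariant to sample order and guards conditionals", {
  co <- make_small_cohort(n = 300)
  perm <- sample(nrow(co$geno))
  a <- scan_variant(co$geno[, "v001"], co$phenotypes,
                    co$covariates, variant_id = "v001")
  b <- scan_variant(co$geno[perm, "v001"], co$phenotypes[perm, ],
                    as.matrix(co$covariates)[perm, ], variant_id = "v001")
  expect_equal(a$beta, b$beta, tolerance = 1e-9)
  expect_equal(a$neglog10_p, b$neglog10_p, tolerance = 1e-8)
  expect_error(
    scan_variant(co$geno[, "v001"], co$phenotypes, co$covariates,
                 conditional = co$geno[, c("v002", "v001")]),
    "conditional"
  )
})

test_that("conditional variants enter the model in both engines", {
  co <- make_small_cohort(n = 400)
  cond <- co$geno[, c("v002", "v003")]
  fast <- scan_variant(co$geno[, "v001"], co$phenotypes, co$covariates,
                       conditional = cond, engine = "fast")
  naive <- scan_variant(co$geno[, "v001"], co$phenotypes, co$covariates,
                        conditional = cond, engine = "naive")
  expect_lt(max(abs(fast$neglog10_p - naive$neglog10_p)), 1e-8)
  # conditional covariates change df by their count
  plain <- scan_variant(co$geno[, "v001"], co$phenotypes, co$covariates)
  expect_equal(plain$df - fast$df, rep(2L, nrow(fast)))
})

test_that("trait_on_ratio exposes the two-coefficient identity", {
  set.seed(77)
  n <- 2000
  ln <- rnorm(n); ld <- rnorm(n)
  out <- 1.0 * ln - 1.0 * ld + rnorm(n, sd = 0.5)
  two <- trait_on_ratio(out, ln, ld, mode = "two_coef")
  est <- two$coefficients
  expect_lt(abs(est$estimate[est$term == "log_num"] - 1),
            3 * est$se[est$term == "log_num"])
  expect_lt(abs(est$estimate[est$term == "log_den"] + 1),
            3 * est$se[est$term == "log_den"])
  ratio <- trait_on_ratio(out, ln, ld, mode = "ratio")
  # the ratio model is nested in the two-coefficient model; with a truly
  # equal-and-opposite generative effect the free extra parameter absorbs
  # only ~chi2(1)/n of the residual variance
  expect_lte(ratio$r_squared, two$r_squared)
  expect_gte(ratio$r_squared, two$r_squared - 10 * (1 - two$r_squared) / n)
  # exact copy of the ratio: R^2 = 1
  exact <- trait_on_ratio(ln - ld, ln, ld, mode = "ratio")
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)
  # independent noise: R^2 < 0.01 at n = 5000
  set.seed(78)
  noise <- trait_on_ratio(rnorm(5000), rnorm(5000), rnorm(5000),
                          mode = "two_coef")
  expect_lt(noise$r_squared, 0.01)
})

test_that("exposure_assoc returns per-trait effect profiles", {
  co <- make_small_cohort(n = 500)
  traits_int <- int_transform(co$log_traits)
  set.seed(12)
  expo <- rbinom(nrow(traits_int), 1, 0.5)
  # null exposure: betas within 3 SEs of zero
  nullres <- exposure_assoc(traits_int, expo, co$covariates)
  expect_true(all(abs(nullres$beta) < 3 * nullres$se))
  # planted shift on trait 1
  shifted <- traits_int
  shifted[, 1] <- shifted[, 1] + 0.5 * expo
  res <- exposure_assoc(shifted, expo, co$covariates)
  expect_lt(abs(res$beta[res$test_id == "T1"] - 0.5),
            3 * res$se[res$test_id == "T1"])
  # duplicating every sample: same betas, smaller SEs
  dup <- exposure_assoc(shifted[rep(1:500, 2), ], rep(expo, 2),
                        rbind(co$covariates, co$covariates))
  expect_equal(dup$beta, res$beta, tolerance = 1e-9)
  expect_true(all(dup$se < res$se))
  expect_error(exposure_assoc(traits_int, rep(1, 500), co$covariates),
               "constant")
})
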