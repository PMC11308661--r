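test_that("boundary transform is the documented affine map", {
  # frozen hand arithmetic: (Y*(N-1)+0.5)/N
  expect_equal(transform_boundaries(1, 144), 143.5 / 144)
  expect_equal(transform_boundaries(0, 144), 0.5 / 144)
  for (N in c(2, 10, 144, 1000)) {
    expect_equal(transform_boundaries(0.5, N), 0.5) # fixed point
    y <- seq(0, 1, by = 0.1)
    ty <- transform_boundaries(y, N)
    expect_true(all(ty > 0 & ty < 1))
    expect_true(all(diff(ty) > 0))                  # order-preserving
    expect_equal(range(ty), c(0.5 / N, 1 - 0.5 / N))
  }
  expect_error(transform_boundaries(0.5, 1), "N must be")
})

test_that("noiseless linear data is recovered exactly", {
  co <- generate_cohort(recovery_config(n = 200, seed = 1, noise_sd = 0))
  fit <- fit_mapping(co, mapping_spec("gaussian_identity", 1))
  expect_equal(unname(fit$coefficients[["(Intercept)"]]), 0.9881, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients[["ygtss_total"]]), -0.0035, tolerance = 1e-8)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-10)
})

test_that("gaussian model-1 equals the closed-form simple-regression oracle", {
  co <- default_cohort(n = 50, seed = 21)
  fit <- fit_mapping(co, mapping_spec("gaussian_identity", 1))
  oracle <- ols_oracle(co$ygtss_total, co$eq5dy_utility)
  expect_equal(unname(fit$coefficients[["(Intercept)"]]),
               unname(oracle["intercept"]), tolerance = 1e-10)
  expect_equal(unname(fit$coefficients[["ygtss_total"]]),
               unname(oracle["slope"]), tolerance = 1e-10)
})

test_that("gaussian coefficients recover the generating truth at n = 5000", {
  co <- generate_cohort(recovery_config(n = 5000, seed = 31))
  fit <- fit_mapping(co, mapping_spec("gaussian_identity", 1))
  for (term in c("(Intercept)", "ygtss_total")) {
    truth <- if (term == "(Intercept)") 0.9881 else -0.0035
    expect_lt(abs(fit$coefficients[[term]] - truth),
              2 * fit$standard_errors[[term]])
  }
})

test_that("beta fit matches the independent mgcv oracle", {
  co <- default_cohort(n = 300, seed = 7)
  fit <- fit_mapping(co, mapping_spec("beta_logit", 1))
  yb <- transform_boundaries(co$eq5dy_utility, nrow(co))
  oracle <- mgcv::gam(yb ~ ygtss_total, data = co,
                      family = mgcv::betar(link = "logit"), method = "REML")
  expect_equal(unname(fit$coefficients),
               unname(stats::coef(oracle)), tolerance = 5e-3)
  expect_equal(unname(fit$phi), unname(oracle$family$getTheta(TRUE)),
               tolerance = 0.02)
  # slope on the total score is negative, as in the published fits
  expect_lt(fit$coefficients[["ygtss_total"]], 0)
  expect_equal(fit$boundary_N, 300)
})

test_that("beta fit requires utilities mappable into (0, 1)", {
  co <- generate_cohort(recovery_config(n = 100, seed = 2)) # uncensored, u > 1 present
  expect_gt(max(co$eq5dy_utility), 1)
  expect_error(fit_mapping(co, mapping_spec("beta_logit", 1)), "\\(0, 1\\)")
})

test_that("fits drop incomplete rows and refuse degenerate designs", {
  co <- default_cohort(n = 100, seed = 3)
  co$sex[1:5] <- NA_integer_
  fit <- fit_mapping(co, mapping_spec("gaussian_identity", 3))
  expect_equal(fit$n_used, 95)
  expect_equal(fit$n_total, 100)

  co$sex <- 1L
  expect_error(fit_mapping(co, mapping_spec("gaussian_identity", 3)),
               "constant predictor.*sex")
  expect_error(fit_mapping(co[1:5, ], mapping_spec("gaussian_identity", 1)),
               ">= 10")
})

test_that("prediction applies the family's link and refuses missing terms", {
  pub <- published_mapping()
  expect_identical(
    predict_utility(pub, data.frame(ygtss_total = 0)), 0.9881)
  expect_equal(
    predict_utility(pub, data.frame(ygtss_total = 30.37)), 0.881805)
  expect_error(predict_utility(pub, data.frame(sex = 1)), "ygtss_total")

  # a beta fit with all coefficients zero predicts inverse-logit(0) = 0.5
  zero <- published_mapping()
  zero$coefficients[] <- 0
  zero$spec <- mapping_spec("beta_logit", 1)
  expect_equal(predict_utility(zero, data.frame(ygtss_total = 123)), 0.5)

  # gaussian predictions are deliberately unclipped
  expect_gt(predict_utility(pub, data.frame(ygtss_total = -10)), 1)
})

test_that("validation metrics match their definitions", {
  co <- default_cohort(n = 144, seed = 9)
  fit <- fit_mapping(co, mapping_spec("gaussian_identity", 1))
  vm <- validation_metrics(fit, co)
  pred <- predict_utility(fit, co)
  expect_equal(vm$mae, mean(abs(co$eq5dy_utility - pred)))
  expect_equal(vm$rmse, sqrt(mean((co$eq5dy_utility - pred)^2)))
  expect_lte(vm$mae, vm$rmse)

  # perfect predictor
  noiseless <- generate_cohort(recovery_config(n = 100, seed = 4, noise_sd = 0))
  pf <- fit_mapping(noiseless, mapping_spec("gaussian_identity", 1))
  vm0 <- validation_metrics(pf, noiseless)
  expect_equal(vm0$mae, 0, tolerance = 1e-10)
  expect_equal(vm0$rmse, 0, tolerance = 1e-10)

  # constant predictor on two observations: MAE = mean absolute deviation
  cfit <- pf
  cfit$coefficients[] <- c(0.9, 0)
  two <- noiseless[1:2, ]
  two$eq5dy_utility <- c(0.8, 1.0)
  expect_equal(validation_metrics(cfit, two)$mae, (0.1 + 0.1) / 2)

  # RMSE tracks the generator's noise scale
  big <- generate_cohort(recovery_config(n = 2000, seed = 5))
  bfit <- fit_mapping(big, mapping_spec("gaussian_identity", 1))
  expect_lt(abs(validation_metrics(bfit, big)$rmse - 0.07) / 0.07, 0.25)
})

test_that("model comparison ranks, ties and screens covariates", {
  co <- default_cohort(n = 144, seed = 13)
  f1 <- fit_mapping(co, mapping_spec("gaussian_identity", 1))
  f1b <- fit_mapping(co, mapping_spec("gaussian_identity", 1))
  f3 <- fit_mapping(co, mapping_spec("gaussian_identity", 3))
  cmp <- compare_models(list(f1, f1b, f3), co)
  # identical fits tie; both flagged, input order preserved
  expect_equal(cmp$table$model, c(1, 1, 3))
  expect_true(all(cmp$table$best_aic[cmp$table$aic == min(cmp$table$aic)]))
  expect_true(sum(cmp$table$best_aic) >= 2)
  # screening table reports per-covariate p-values
  expect_true("sex" %in% cmp$screening$term)
  expect_true(all(c("p_value", "keep") %in% names(cmp$screening)))

  other <- default_cohort(n = 144, seed = 14)
  g <- fit_mapping(other, mapping_spec("gaussian_identity", 1))
  expect_error(compare_models(list(f1, g), co), "different record sets")
})

test_that("a genuine sex effect lifts adjusted R2 of the sex model", {
  co <- generate_cohort(recovery_config(n = 2000, seed = 15,
                                        utility_sex_effect = -0.036))
  f1 <- fit_mapping(co, mapping_spec("gaussian_identity", 1))
  f3 <- fit_mapping(co, mapping_spec("gaussian_identity", 3))
  expect_gt(f3$adj_r2, f1$adj_r2)
  expect_lt(f3$p_values[["sex"]], 0.05)
})

test_that("AIC prefers the smaller model when the extra covariate is noise", {
  # sex enters the generator with zero effect, so model 3's sex term is noise
  wins <- 0L
  for (s in 1:100) {
    co <- generate_cohort(recovery_config(n = 300, seed = 1000 + s))
    f1 <- fit_mapping(co, mapping_spec("gaussian_identity", 1))
    f3 <- fit_mapping(co, mapping_spec("gaussian_identity", 3))
    wins <- wins + (f1$aic < f3$aic)
  }
  expect_gt(wins, 50)
})

test_that("adjusted R2 never exceeds 1 across families and models", {
  co <- default_cohort(n = 144, seed = 17)
  for (fam in c("gaussian_identity", "beta_logit")) {
    for (m in 1:4) {
      fit <- fit_mapping(co, mapping_spec(fam, m))
      expect_lte(fit$adj_r2, 1)
      expect_true(all(c("(Intercept)", fit$spec$predictors) %in%
                        names(fit$coefficients)))
      expect_equal(names(fit$coefficients), names(fit$standard_errors))
    }
  }
})
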