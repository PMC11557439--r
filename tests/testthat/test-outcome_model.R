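test_that("feature sets nest with fixed column order and reference coding", {
  co <- generate_cohort(cohort_spec(n_patients = 50, seed = 71))
  basic <- build_features(co, "CRASH_BASIC")
  expect_equal(ncol(basic$X), 5)
  ct <- build_features(co, "CRASH_CT")
  expect_equal(ncol(ct$X), 10)
  full <- build_features(co, "CRASH_CT_VOL_SUB")
  expect_equal(ncol(full$X), 16)
  expect_true(all(colnames(basic$X) == colnames(full$X)[1:5]))
  # reference pupils: both dummies zero
  br <- co$pupils == "both_reactive"
  expect_true(all(full$X[br, "pupils_one_reactive"] == 0))
  expect_true(all(full$X[br, "pupils_both_nonreactive"] == 0))
  expect_equal(full$X[, "nonevacuated_hematoma"],
               unname(1 - co$evacuated_hematoma))
  expect_error(build_features(co[, -2], "CRASH_BASIC"),
               class = "hemocascade_validation_error")
})

test_that("box_cox matches fixed-lambda forms and the MASS oracle", {
  x <- c(1, 2, 5, 10)
  expect_equal(box_cox(x, lambda = 1)$transformed, x - 1)
  expect_equal(box_cox(x, lambda = 0)$transformed, log(x))
  set.seed(72)
  y <- exp(rnorm(400, 1, 0.6))
  lam <- box_cox(y)$lambda
  bc <- MASS::boxcox(y ~ 1, lambda = seq(-3, 3, 0.01), plotit = FALSE)
  lam_oracle <- bc$x[which.max(bc$y)]
  expect_equal(lam, lam_oracle, tolerance = 0.011)
  expect_error(box_cox(c(1, -2)), class = "hemocascade_validation_error")
})

test_that("box_tidwell flags log-shaped effects and rejects constants", {
  set.seed(73)
  n <- 3000
  x <- runif(n, 0.5, 10)
  y_log <- rbinom(n, 1, plogis(-1.5 + 1.5 * log(x)))
  expect_lt(box_tidwell(x, y_log)$p_value, 0.05)
  expect_error(box_tidwell(rep(2, n), y_log),
               class = "hemocascade_validation_error")
})

test_that("cross-validation is deterministic, stratified and ordered", {
  co <- generate_cohort(cohort_spec(n_patients = 400, seed = 74))
  r1 <- fit_predict_cv(co, "CRASH_CT_VOL", "logistic", "A", seed = 2)
  r2 <- fit_predict_cv(co, "CRASH_CT_VOL", "logistic", "A", seed = 2)
  expect_identical(r1$folds, r2$folds)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_equal(nrow(r1$per_fold), 5)
  expect_true(all(r1$mean >= 0 & r1$mean <= 1))
  # every fold contains both classes by stratification
  for (f in 1:5)
    expect_gt(length(unique(co$death14[r1$folds == f])), 1)
  expect_error(fit_predict_cv(co[1:10, ], "CRASH_CT"),
               class = "hemocascade_validation_error")
})

test_that("scheme B scores the death-or-coma outcome", {
  co <- generate_cohort(cohort_spec(n_patients = 400, seed = 75))
  ra <- fit_predict_cv(co, "CRASH_CT", "logistic", "A", seed = 1)
  rb <- fit_predict_cv(co, "CRASH_CT", "logistic", "B", seed = 1)
  expect_false(identical(ra$per_fold$auc, rb$per_fold$auc))
  expect_gt(mean(co$death_or_coma14), mean(co$death14))
})

test_that("coefficients recover near truth on generator cohorts", {
  co <- generate_cohort(cohort_spec(n_patients = 5000, seed = 76))
  est <- recover_coefficients(co, "CRASH_CT_VOL_SUB", "A")
  truth <- default_cohort_coefficients("A")
  truth <- truth[c("intercept", setdiff(cohort_coef_names(), "intercept"))]
  covered <- est$ci_lo <= truth & truth <= est$ci_hi
  expect_gte(mean(covered), 0.8)
  # null cohort: slopes near zero
  zero <- setNames(numeric(length(cohort_coef_names())),
                   cohort_coef_names())
  co0 <- generate_cohort(cohort_spec(n_patients = 5000,
                                     coefficients = zero,
                                     coefficients_b = zero, seed = 77))
  est0 <- recover_coefficients(co0, "CRASH_CT_VOL_SUB", "A")
  expect_true(all(abs(est0$estimate[est0$term != "volume_ml"]) < 0.3))
  expect_gte(mean(est0$ci_lo <= 0 & est0$ci_hi >= 0), 0.8)
})

test_that("random-forest importance ranks a dominant volume effect first", {
  beta <- default_cohort_coefficients("A")
  beta[] <- beta / 4
  beta["volume_ml"] <- 0.12
  beta["intercept"] <- -1.5
  co <- generate_cohort(cohort_spec(n_patients = 800, coefficients = beta,
                                    seed = 78))
  rf <- fit_predict_cv(co, "CRASH_CT_VOL_SUB", "random_forest", "A",
                       seed = 3, n_trees = 300)
  imp <- feature_importance(rf)
  expect_equal(sum(imp$share), 1, tolerance = 1e-9)
  expect_equal(imp$feature[1], "volume_ml")
  lg <- fit_predict_cv(co, "CRASH_CT_VOL", "logistic", "A", seed = 3)
  expect_error(feature_importance(lg),
               class = "hemocascade_validation_error")
})
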