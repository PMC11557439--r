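test_that("phantom generation is deterministic and validates its spec", {
  g1 <- generate_phantom_series(phantom_spec(n_slices = 4, seed = 9))
  g2 <- generate_phantom_series(phantom_spec(n_slices = 4, seed = 9))
  expect_identical(g1, g2)
  expect_error(phantom_spec(image_side = 16),
               class = "hemocascade_validation_error")
  expect_error(phantom_spec(lesion_intensity_contrast = 0),
               class = "hemocascade_validation_error")
  expect_error(phantom_spec(fraction_empty_slices = 1.2),
               class = "hemocascade_validation_error")
  expect_error(phantom_spec(subtype_mix = c(edh = 0)),
               class = "hemocascade_validation_error")
})

test_that("fraction_empty_slices = 1 yields only empty masks and labels", {
  g <- generate_phantom_series(phantom_spec(n_slices = 10, seed = 2,
                                            fraction_empty_slices = 1))
  expect_true(all(vapply(g$masks, function(m) sum(m) == 0, logical(1))))
  expect_true(all(vapply(g$labels, function(l) !any(unclass(l)),
                         logical(1))))
})

test_that("EDH-only mix produces EDH-only labels at the configured area", {
  spec <- phantom_spec(n_slices = 100, seed = 3, subtype_mix = c(edh = 1),
                       fraction_empty_slices = 0, max_lesions = 1)
  g <- generate_phantom_series(spec)
  only_edh <- vapply(g$labels, function(l)
    identical(unname(unclass(l)), c(TRUE, FALSE, FALSE, FALSE, FALSE)),
    logical(1))
  expect_true(all(only_edh))
  areas <- vapply(g$masks, function(m) sum(unclass(m) > 0), numeric(1))
  expect_lt(abs(mean(areas) - spec$lesion_area_px),
            0.2 * spec$lesion_area_px)
})

test_that("lesion pixels contrast against local background by construction", {
  spec <- phantom_spec(n_slices = 20, seed = 4, noise_sd = 0,
                       fraction_empty_slices = 0)
  g <- generate_phantom_series(spec)
  for (k in seq_along(g$masks)) {
    les <- unclass(g$masks[[k]]) > 0
    if (!any(les)) next
    bg_max <- max(g$series$slices[[k]][!les & g$series$slices[[k]] < 0.5])
    expect_gte(min(g$series$slices[[k]][les]) - bg_max,
               spec$lesion_intensity_contrast / 2)
  }
})

test_that("cohort generation is deterministic with stated outcome models", {
  sp <- cohort_spec(n_patients = 100, seed = 5)
  c1 <- generate_cohort(sp)
  c2 <- generate_cohort(sp)
  expect_identical(c1, c2)
  expect_true(all(c1$gcs >= 3 & c1$gcs <= 12))
  expect_true(all(c1$age_years >= 18 & c1$age_years <= 80))
  # stored linear predictor matches the declared coefficients
  X <- hemocascade:::cohort_design(c1)
  lp <- drop(cbind(1, X) %*% sp$coefficients)
  expect_equal(lp, c1$true_lp_death14, tolerance = 1e-12)
})

test_that("null-coefficient cohort has ~50% prevalence", {
  zero <- setNames(numeric(length(cohort_coef_names())),
                   cohort_coef_names())
  co <- generate_cohort(cohort_spec(n_patients = 10000, coefficients = zero,
                                    coefficients_b = zero, seed = 6))
  expect_gte(mean(co$death14), 0.48)
  expect_lte(mean(co$death14), 0.52)
})

test_that("positive volume effect raises mortality in the top quartile", {
  co <- generate_cohort(cohort_spec(n_patients = 4000, seed = 8))
  q <- quantile(co$volume_ml, c(0.25, 0.75))
  expect_gt(mean(co$death14[co$volume_ml >= q[2]]),
            mean(co$death14[co$volume_ml <= q[1]]))
})

test_that("cohort marginals match the spec distributions (KS)", {
  sp0 <- cohort_spec(n_patients = 5000)
  lo <- pnorm(18, sp0$age_mean, sp0$age_sd)
  hi <- pnorm(80, sp0$age_mean, sp0$age_sd)
  p_age <- p_vol <- numeric(20)
  for (s in 1:20) {
    co <- generate_cohort(cohort_spec(n_patients = 5000, seed = 1000 + s))
    p_age[s] <- suppressWarnings(stats::ks.test(
      co$age_years,
      function(q) (pnorm(q, sp0$age_mean, sp0$age_sd) - lo) / (hi - lo)
    ))$p.value
    p_vol[s] <- suppressWarnings(stats::ks.test(
      co$volume_ml, stats::plnorm, sp0$volume_meanlog,
      sp0$volume_sdlog))$p.value
  }
  expect_lte(sum(p_age < 0.01), 2)
  expect_lte(sum(p_vol < 0.01), 2)
})
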