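# Phantom-scale experiments exercising each stage of the cascade under the
# package's study conditions. These back both the test suite and
# scripts/acceptance.R, so the measured quantities are always recomputed
# from scratch by the same code path.

#' Generate a per-slice phantom dataset
#'
#' Convenience wrapper around [generate_phantom_series()] returning a flat
#' list of `list(image, mask, label)` items (mask binarized).
#'
#' @param n_slices Number of slices.
#' @param seed Integer seed.
#' @param ... Passed to [phantom_spec()].
#' @return List of slice items; the full generator output is attached as
#'   attribute `"generated"`.
#' @export
phantom_slice_dataset <- function(n_slices, seed, ...) {
  gen <- generate_phantom_series(phantom_spec(n_slices = n_slices,
                                              seed = seed, ...))
  out <- lapply(seq_len(n_slices), function(k)
    list(image = gen$series$slices[[k]],
         mask = binary_view(gen$masks[[k]]),
         label = gen$labels[[k]]))
  attr(out, "generated") <- gen
  out
}

# tiny-backbone preset: higher initial learning rate than the full-scale
# recipe so the small nets converge in the short desk-scale epoch budgets
TINY_LR <- 1e-3

#' Slice-filter experiment: train and score the binary hemorrhage filter
#'
#' Trains the tiny filter on `n_train` phantom slices (half empty) and
#' reports held-out accuracy on freshly generated slices.
#'
#' @param seed Integer seed.
#' @param n_train,n_test Training and held-out set sizes.
#' @param epochs Training epochs.
#' @param side Slice side in pixels.
#' @return List with `accuracy`, `n_test`, and the trained `model`.
#' @export
run_filter_experiment <- function(seed = 1L, n_train = 200L, n_test = 60L,
                                  epochs = 20L, side = 64L) {
  train <- phantom_slice_dataset(n_train, seed = derive_seed(seed, 1L),
                                 image_side = side,
                                 fraction_empty_slices = 0.5)
  test <- phantom_slice_dataset(n_test, seed = derive_seed(seed, 2L),
                                image_side = side,
                                fraction_empty_slices = 0.5)
  to_cls <- function(d) lapply(d, function(s)
    list(image = s$image, label = as.integer(any(unclass(s$mask) > 0))))
  cfg <- cls_train_config(task = "binary", lr = TINY_LR, epochs = epochs,
                          seed = seed)
  model <- train_binary_filter(to_cls(train), cfg)
  truth <- vapply(to_cls(test), `[[`, numeric(1), "label")
  pred <- vapply(test, function(s)
    as.integer(predict_binary(model, s$image) >= 0.5), integer(1))
  list(accuracy = mean(pred == truth), n_test = length(truth),
       model = model)
}

#' Cascade experiment: Stage I vs coarse-to-fine Stage II Dice
#'
#' Trains Stage I on full phantom slices and Stage II on ground-truth ROI
#' crops, then compares mean held-out Dice of the Stage-I-only prediction
#' against the full cascade (Stage-I-derived ROI, Stage II, mean vote) on
#' hemorrhage-bearing slices, with a paired bootstrap CI on the
#' improvement.
#'
#' @param seed Integer seed.
#' @param n_train,n_test Training and held-out sizes.
#' @param epochs Training epochs per stage.
#' @param side Slice side.
#' @param margin ROI margin in pixels.
#' @param n_boot Bootstrap resamples.
#' @return List with `dice_stage1`, `dice_cascade`, `diff_ci` (95% paired
#'   bootstrap CI of cascade - stage1), and the two models.
#' @export
run_cascade_experiment <- function(seed = 1L, n_train = 200L, n_test = 50L,
                                   epochs = 30L, side = 64L, margin = 20L,
                                   n_boot = 2000L) {
  train <- phantom_slice_dataset(n_train, seed = derive_seed(seed, 3L),
                                 image_side = side,
                                 fraction_empty_slices = 0.25)
  test <- phantom_slice_dataset(n_test, seed = derive_seed(seed, 4L),
                                image_side = side,
                                fraction_empty_slices = 0)
  cfg1 <- seg_train_config(stage = "I", lr = TINY_LR, epochs = epochs,
                           seed = seed)
  stage1 <- train_stage(train, cfg1)
  s2data <- stage2_training_data(lapply(train, `[[`, "image"),
                                 lapply(train, `[[`, "mask"),
                                 margin = margin)
  cfg2 <- seg_train_config(stage = "II", lr = TINY_LR, epochs = epochs,
                           seed = seed)
  stage2 <- train_stage(s2data, cfg2)
  d1 <- d2 <- numeric(length(test))
  for (i in seq_along(test)) {
    p1 <- predict_seg(stage1, test[[i]]$image)
    m1 <- matrix(as.integer(p1 >= 0.5), side, side)
    cp <- cascade_predict(stage1, stage2, test[[i]]$image, margin = margin)
    d1[i] <- dice_score(m1, test[[i]]$mask)
    d2[i] <- dice_score(cp$mask, test[[i]]$mask)
  }
  diff <- d2 - d1
  set.seed(derive_seed(seed, 5L))
  boot <- replicate(n_boot, mean(sample(diff, replace = TRUE)))
  list(dice_stage1 = mean(d1), dice_cascade = mean(d2),
       diff_ci = quantile(boot, c(0.025, 0.975)),
       stage1 = stage1, stage2 = stage2)
}

# fusion inputs from ground-truth masks and ROIs (emulating a good
# segmenter feeding the classifier)
fusion_dataset <- function(items, margin = 20L) {
  lapply(items, function(s) {
    m <- unclass(s$mask)
    roi <- if (any(m > 0)) compute_roi(m, margin = margin) else NULL
    list(input = build_fusion_input(s$image, s$mask, roi),
         labels = s$label)
  })
}

#' Fusion experiment: global+local classifier vs global-only ablation
#'
#' Phantom inputs with shape-determined subtypes are classified by the
#' fusion model and by its global-only ablation; held-out per-label mean
#' accuracy is averaged over `n_seeds` training seeds.
#'
#' @param seed Integer base seed.
#' @param n_train,n_test Training / held-out sizes.
#' @param epochs Training epochs.
#' @param side Slice side.
#' @param n_seeds Number of training seeds averaged.
#' @return List with `fusion_accuracy`, `global_accuracy` (means over
#'   seeds), `per_seed` data frame, and the last fusion model.
#' @export
run_fusion_experiment <- function(seed = 1L, n_train = 300L, n_test = 60L,
                                  epochs = 12L, side = 64L, n_seeds = 3L) {
  train <- fusion_dataset(phantom_slice_dataset(
    n_train, seed = derive_seed(seed, 6L), image_side = side,
    fraction_empty_slices = 0))
  test <- fusion_dataset(phantom_slice_dataset(
    n_test, seed = derive_seed(seed, 7L), image_side = side,
    fraction_empty_slices = 0))
  truth <- t(vapply(test, function(d) as.numeric(unclass(d$labels)),
                    numeric(5)))
  eval_model <- function(model) {
    probs <- t(vapply(test, function(d)
      predict_subtypes(model, d$input)$probs, numeric(5)))
    multilabel_report(probs, truth)$per_label_mean_accuracy
  }
  per_seed <- NULL
  model <- NULL
  for (s in seq_len(n_seeds)) {
    cfg_f <- cls_train_config(task = "multilabel", lr = TINY_LR,
                              epochs = epochs, fusion = "both",
                              seed = derive_seed(seed, 10L + s))
    cfg_g <- cls_train_config(task = "multilabel", lr = TINY_LR,
                              epochs = epochs, fusion = "global_only",
                              seed = derive_seed(seed, 10L + s))
    model <- train_multilabel(train, cfg_f)
    gmod <- train_multilabel(train, cfg_g)
    per_seed <- rbind(per_seed, data.frame(
      seed = s, fusion = eval_model(model), global = eval_model(gmod)))
  }
  list(fusion_accuracy = mean(per_seed$fusion),
       global_accuracy = mean(per_seed$global),
       per_seed = per_seed, model = model)
}

#' Outcome-model nesting experiment
#'
#' On a synthetic cohort with informative volume and subtype effects,
#' computes mean 5-fold logistic AUC for the nested CRASH-CT, +Volume, and
#' +Volume+Subtypes feature sets (paired folds), and on a null cohort (all
#' coefficients zero) the same AUCs, which should hover near 0.5.
#'
#' @param seed Integer seed.
#' @param n_patients Cohort size.
#' @return List with `auc` (named, informative cohort), `auc_null`, and
#'   `auc_basic` for reference.
#' @export
run_outcome_experiment <- function(seed = 1L, n_patients = 2000L) {
  cohort <- generate_cohort(cohort_spec(n_patients = n_patients,
                                        seed = derive_seed(seed, 8L)))
  aucs <- vapply(c("CRASH_BASIC", "CRASH_CT", "CRASH_CT_VOL",
                   "CRASH_CT_VOL_SUB"), function(sp)
    fit_predict_cv(cohort, sp, "logistic", "A", seed = seed)$mean["auc"],
    numeric(1))
  names(aucs) <- c("CRASH_BASIC", "CRASH_CT", "CRASH_CT_VOL",
                   "CRASH_CT_VOL_SUB")
  zero <- setNames(numeric(length(cohort_coef_names())),
                   cohort_coef_names())
  null_cohort <- generate_cohort(cohort_spec(n_patients = n_patients,
                                             coefficients = zero,
                                             coefficients_b = zero,
                                             seed = derive_seed(seed, 9L)))
  aucs_null <- vapply(c("CRASH_CT", "CRASH_CT_VOL", "CRASH_CT_VOL_SUB"),
                      function(sp)
    fit_predict_cv(null_cohort, sp, "logistic", "A", seed = seed)$
      mean["auc"], numeric(1))
  names(aucs_null) <- c("CRASH_CT", "CRASH_CT_VOL", "CRASH_CT_VOL_SUB")
  list(auc = aucs[-1], auc_basic = aucs[1], auc_null = aucs_null)
}

#' End-to-end volumetry experiment
#'
#' Runs the full pipeline on a single-lesion phantom series and compares
#' the automated volume with the ground truth; also verifies that volumetry
#' on the ground-truth masks themselves reproduces the closed-form voxel
#' sum exactly.
#'
#' @param seed Integer seed.
#' @param models Optional list with `filter`, `stage1`, `stage2`,
#'   `multilabel` (reused from the other experiments); trained afresh at
#'   reduced epoch budgets when absent.
#' @param n_slices Series length.
#' @param side Slice side.
#' @return List with `volume_pred`, `volume_gt`, `rel_error`,
#'   `gt_exact_error` and the `report`.
#' @export
run_volumetry_experiment <- function(seed = 1L, models = NULL,
                                     n_slices = 6L, side = 64L) {
  if (is.null(models)) {
    filt <- run_filter_experiment(seed, n_train = 120L, n_test = 20L,
                                  epochs = 12L, side = side)$model
    casc <- run_cascade_experiment(seed, n_train = 120L, n_test = 5L,
                                   epochs = 20L, side = side, n_boot = 10L)
    fus <- run_fusion_experiment(seed, n_train = 80L, n_test = 10L,
                                 epochs = 10L, n_seeds = 1L, side = side)
    models <- list(filter = filt, stage1 = casc$stage1,
                   stage2 = casc$stage2, multilabel = fus$model)
  }
  gen <- generate_phantom_series(phantom_spec(
    image_side = side, n_slices = n_slices,
    subtype_mix = c(iph = 1), fraction_empty_slices = 0,
    max_lesions = 1L, seed = derive_seed(seed, 12L)))
  cfg <- pipeline_config(models$filter, models$stage1, models$stage2,
                         models$multilabel, seed = seed)
  res <- run_pipeline(gen$series, cfg)
  gt_masks <- lapply(gen$masks, binary_view)
  v_gt <- hematoma_volume_ml(gt_masks, gen$series)
  v_pred <- res$report$volume_ml
  sp <- gen$series$pixel_spacing_mm
  v_closed <- sum(vapply(gt_masks, function(m) sum(unclass(m) > 0),
                         numeric(1))) * sp[1] * sp[2] *
    gen$series$slice_thickness_mm / 1000
  list(volume_pred = v_pred, volume_gt = v_gt,
       rel_error = abs(v_pred - v_gt) / v_gt,
       gt_exact_error = abs(v_gt - v_closed), report = res$report)
}

#' Box-Tidwell calibration experiment
#'
#' Monte-Carlo estimate of the test's type-I error (outcome truly linear in
#' the predictor) and power (outcome linear in `log x`) at `alpha = 0.05`.
#'
#' @param seed Integer seed.
#' @param n_reps Replicates per scenario.
#' @param n Sample size per replicate.
#' @return List with `type1_rate` and `power`.
#' @export
run_boxtidwell_calibration <- function(seed = 1L, n_reps = 200L,
                                       n = 2000L) {
  set.seed(derive_seed(seed, 13L))
  p_lin <- p_log <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    x <- runif(n, 0.5, 10)
    y_lin <- rbinom(n, 1, plogis(-1 + 0.4 * x))
    y_log <- rbinom(n, 1, plogis(-1.5 + 1.5 * log(x)))
    p_lin[r] <- box_tidwell(x, y_lin)$p_value
    p_log[r] <- box_tidwell(x, y_log)$p_value
  }
  list(type1_rate = mean(p_lin < 0.05), power = mean(p_log < 0.05))
}

#' Logistic coefficient-recovery coverage experiment
#'
#' Generates cohorts with known coefficients (including two set exactly to
#' zero) and measures how often the 95% Wald CIs cover the truth.
#'
#' @param seed Integer base seed.
#' @param n_seeds Number of cohorts.
#' @param n_patients Cohort size.
#' @return List with `coverage` (all coefficients pooled) and
#'   `zero_coverage` (CIs covering 0 for the zeroed features).
#' @export
run_coverage_experiment <- function(seed = 1L, n_seeds = 20L,
                                    n_patients = 5000L) {
  beta <- default_cohort_coefficients("A")
  beta["petechiae"] <- 0; beta["edh"] <- 0
  hits <- total <- zero_hits <- zero_total <- 0L
  for (s in seq_len(n_seeds)) {
    cohort <- generate_cohort(cohort_spec(n_patients = n_patients,
                                          coefficients = beta,
                                          seed = derive_seed(seed, 100L + s)))
    est <- recover_coefficients(cohort, "CRASH_CT_VOL_SUB", "A")
    truth <- beta[c("intercept", setdiff(cohort_coef_names(), "intercept"))]
    covered <- est$ci_lo <= truth & truth <= est$ci_hi
    hits <- hits + sum(covered); total <- total + length(covered)
    zi <- est$term %in% c("petechiae", "edh")
    zero_hits <- zero_hits + sum(est$ci_lo[zi] <= 0 & est$ci_hi[zi] >= 0)
    zero_total <- zero_total + sum(zi)
  }
  list(coverage = hits / total, zero_coverage = zero_hits / zero_total)
}
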