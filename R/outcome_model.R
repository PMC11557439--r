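# 14-day mortality modelling: nested CRASH feature sets (clinical, +CT,
# +hematoma volume, +subtypes) under logistic regression and random forest,
# with Box-Cox age transformation, Box-Tidwell linearity diagnostics,
# stratified 5-fold cross-validation and impurity-based feature ranking.

FEATURE_SETS <- c("CRASH_BASIC", "CRASH_CT", "CRASH_CT_VOL",
                  "CRASH_CT_VOL_SUB")

feature_columns <- function(spec) {
  basic <- c("age_bc", "gcs", "pupils_one_reactive",
             "pupils_both_nonreactive", "major_extracranial_injury")
  ct <- c("petechiae", "effaced_basal_cistern", "sah_present",
          "midline_shift", "nonevacuated_hematoma")
  switch(spec,
         CRASH_BASIC = basic,
         CRASH_CT = c(basic, ct),
         CRASH_CT_VOL = c(basic, ct, "volume_ml"),
         CRASH_CT_VOL_SUB = c(basic, ct, "volume_ml", SUBTYPES),
         stop_validation(paste("unknown feature set:", spec)))
}

#' Box-Cox power transform chosen by profile maximum likelihood
#'
#' The exponent is selected on the grid `[-3, 3]` in steps of 0.01 by
#' maximizing the normal-theory profile log-likelihood
#' `-n/2 log(sigma^2_lambda) + (lambda - 1) * sum(log x)`; the transform is
#' `(x^lambda - 1)/lambda`, or `log x` at `lambda = 0`.
#'
#' @param x Strictly positive numeric vector.
#' @param lambda Optional fixed exponent, skipping estimation.
#' @return List with `transformed` and `lambda`.
#' @export
box_cox <- function(x, lambda = NULL) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop_validation("box_cox requires strictly positive finite values")
  bc <- function(l) if (abs(l) < 1e-12) log(x) else (x^l - 1) / l
  if (is.null(lambda)) {
    grid <- seq(-3, 3, by = 0.01)
    slx <- sum(log(x)); n <- length(x)
    ll <- vapply(grid, function(l) {
      z <- bc(l)
      -n / 2 * log(mean((z - mean(z))^2)) + (l - 1) * slx
    }, numeric(1))
    lambda <- grid[which.max(ll)]
  }
  list(transformed = bc(lambda), lambda = lambda)
}

#' Box-Tidwell linearity test for a positive continuous predictor
#'
#' Augments the logistic model `y ~ covariates + x` with the interaction
#' term `x * log(x)` and returns the Wald p-value of that term; a small
#' p-value indicates the predictor is not linear in the logit.
#'
#' @param x Strictly positive predictor.
#' @param y Binary outcome (0/1).
#' @param covariates Optional numeric matrix/data frame of adjustment
#'   columns.
#' @return List with `p_value`, `statistic` (z), and the fitted `model`.
#' @export
box_tidwell <- function(x, y, covariates = NULL) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop_validation("box_tidwell requires strictly positive x")
  if (var(x) < 1e-12)
    stop_validation("x is constant; x*log(x) is collinear with x")
  df <- data.frame(y = y, x = x, xlogx = x * log(x))
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  fit <- tryCatch(
    glm(y ~ ., data = df, family = binomial()),
    warning = function(w) hc_stop(paste("logistic fit did not converge",
                                        "cleanly:", conditionMessage(w)),
                                  "convergence_error"))
  sm <- summary(fit)$coefficients
  if (!"xlogx" %in% rownames(sm))
    hc_stop("x*log(x) term dropped (collinearity)", "convergence_error")
  list(p_value = sm["xlogx", 4], statistic = sm["xlogx", 3], model = fit)
}

#' Build a design matrix for one nested CRASH feature set
#'
#' `CRASH_BASIC` = standardized Box-Cox age, GCS, two pupil-reactivity
#' dummies (reference: both reactive), major extracranial injury.
#' `CRASH_CT` adds petechiae, effaced basal cistern, traumatic SAH, midline
#' shift and nonevacuated hematoma; `CRASH_CT_VOL` adds hematoma volume
#' (mL); `CRASH_CT_VOL_SUB` adds the five subtype indicators. Column order
#' is fixed.
#'
#' @param records Data frame with the cohort columns (see
#'   [generate_cohort()]).
#' @param spec One of `"CRASH_BASIC"`, `"CRASH_CT"`, `"CRASH_CT_VOL"`,
#'   `"CRASH_CT_VOL_SUB"`.
#' @param scheme `"A"` selects `death14` as outcome, `"B"`
#'   `death_or_coma14`.
#' @return List with `X` (matrix), `y` (0/1 vector) and `boxcox_lambda`.
#' @export
build_features <- function(records, spec = "CRASH_CT_VOL_SUB",
                           scheme = c("A", "B")) {
  scheme <- match.arg(scheme)
  spec <- match.arg(spec, FEATURE_SETS)
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop_validation("records must be a nonempty data frame")
  need <- c("age_years", "gcs", "pupils", "major_extracranial_injury",
            "petechiae", "effaced_basal_cistern", "sah_present",
            "midline_shift", "evacuated_hematoma", "volume_ml", SUBTYPES)
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop_validation(paste("records missing fields:",
                          paste(missing_cols, collapse = ", ")))
  full <- cohort_design(records)
  cols <- feature_columns(spec)
  out_col <- if (scheme == "A") "death14" else "death_or_coma14"
  y <- if (out_col %in% names(records)) records[[out_col]] else NULL
  list(X = full[, cols, drop = FALSE], y = y,
       boxcox_lambda = attr(full, "boxcox_lambda"))
}

# stratified fold assignment; deterministic in (y, seed), independent of
# record order up to the stable patient key ordering
stratified_folds <- function(y, k, seed) {
  set.seed(derive_seed(seed, 401L))
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

binary_metrics <- function(probs, y, threshold = 0.5) {
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  c(accuracy = mean(pred == y),
    precision = prec, recall = rec,
    f1 = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec),
    auc = if (length(unique(y)) < 2) NA_real_ else
      as.numeric(pROC::auc(pROC::roc(y, probs, levels = c(0, 1),
                                     direction = "<", quiet = TRUE))))
}

#' Stratified k-fold cross-validated mortality models
#'
#' Fits and evaluates one feature set under logistic regression (maximum
#' likelihood, Box-Cox-transformed age) or random forest (500 trees).
#' Scheme A scores death within 14 days; scheme B death or coma. Folds are
#' stratified by outcome so both classes appear in every fold; metrics use
#' threshold 0.5 plus ROC AUC from the out-of-fold probabilities.
#'
#' @param records Cohort data frame.
#' @param spec Feature set name, see [build_features()].
#' @param algorithm `"logistic"` or `"random_forest"`.
#' @param scheme `"A"` or `"B"`.
#' @param k Number of folds (default 5).
#' @param seed Fold-assignment / forest seed.
#' @param n_trees,mtry Random-forest hyperparameters (default 500 trees,
#'   `sqrt(p)` features per split).
#' @return Object of class `cv_result`: `per_fold` data frame, `mean`
#'   metrics, `fold_models`, `algorithm`, and for forests an `importance`
#'   matrix (folds x features, mean decrease in impurity).
#' @export
fit_predict_cv <- function(records, spec = "CRASH_CT_VOL_SUB",
                           algorithm = c("logistic", "random_forest"),
                           scheme = c("A", "B"), k = 5L, seed = 1L,
                           n_trees = 500L, mtry = NULL) {
  algorithm <- match.arg(algorithm); scheme <- match.arg(scheme)
  bf <- build_features(records, spec, scheme)
  X <- bf$X; y <- bf$y
  if (is.null(y)) stop_validation("records lack the outcome column")
  if (nrow(X) < k * 4L) stop_validation("too few records for k-fold CV")
  if (length(unique(y)) < 2L)
    stop_validation("both outcome classes must be present")
  fold <- stratified_folds(y, k, seed)
  per_fold <- NULL; fold_models <- list(); imp <- NULL
  probs_all <- rep(NA_real_, length(y))
  for (f in seq_len(k)) {
    tr <- fold != f; te <- fold == f
    if (length(unique(y[tr])) < 2L || length(unique(y[te])) < 2L) {
      warning(sprintf("fold %d is single-class; skipped", f))
      next
    }
    if (algorithm == "logistic") {
      dtr <- data.frame(y = y[tr], X[tr, , drop = FALSE])
      fit <- suppressWarnings(glm(y ~ ., data = dtr, family = binomial()))
      p <- predict(fit, newdata = data.frame(X[te, , drop = FALSE]),
                   type = "response")
    } else {
      set.seed(derive_seed(seed, 500L + f))
      fit <- randomForest::randomForest(
        x = X[tr, , drop = FALSE], y = factor(y[tr], levels = c(0, 1)),
        ntree = n_trees, mtry = mtry %||% max(1, floor(sqrt(ncol(X)))))
      p <- predict(fit, X[te, , drop = FALSE], type = "prob")[, "1"]
      imp <- rbind(imp, randomForest::importance(fit)[, 1])
    }
    probs_all[te] <- p
    per_fold <- rbind(per_fold,
                      data.frame(fold = f, t(binary_metrics(p, y[te]))))
    fold_models[[length(fold_models) + 1L]] <- fit
  }
  if (is.null(per_fold)) stop_validation("all folds were skipped")
  structure(list(
    spec = spec, algorithm = algorithm, scheme = scheme, k = k,
    per_fold = per_fold,
    mean = colMeans(per_fold[, -1, drop = FALSE], na.rm = TRUE),
    fold_models = fold_models, importance = imp, folds = fold,
    oof_probs = probs_all, boxcox_lambda = bf$boxcox_lambda),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result %s / %s / scheme %s (%d folds)\n", x$spec,
              x$algorithm, x$scheme, x$k))
  print(round(x$mean, 4))
  invisible(x)
}

#' Full-data logistic fit with Wald confidence intervals
#'
#' Intended as the oracle companion of [generate_cohort()]: on
#' generator-produced cohorts the estimates should cover the stored true
#' coefficients at the nominal 95% rate.
#'
#' @param records Cohort data frame.
#' @param spec Feature set name.
#' @param scheme Outcome scheme.
#' @return Data frame with `term`, `estimate`, `se`, `ci_lo`, `ci_hi`.
#' @export
recover_coefficients <- function(records, spec = "CRASH_CT_VOL_SUB",
                                 scheme = "A") {
  bf <- build_features(records, spec, scheme)
  d <- data.frame(y = bf$y, bf$X)
  fit <- glm(y ~ ., data = d, family = binomial())
  if (!fit$converged) hc_stop("logistic fit did not converge",
                              "convergence_error")
  sm <- summary(fit)$coefficients
  data.frame(term = c("intercept", colnames(bf$X)),
             estimate = sm[, 1], se = sm[, 2],
             ci_lo = sm[, 1] - qnorm(0.975) * sm[, 2],
             ci_hi = sm[, 1] + qnorm(0.975) * sm[, 2],
             row.names = NULL)
}

#' Random-forest feature priority ranking
#'
#' Mean decrease in impurity averaged over the CV folds and normalized to
#' sum 1, in descending order.
#'
#' @param cv A `cv_result` from a random-forest run.
#' @return Data frame with `feature` and `share`, sorted descending.
#' @export
feature_importance <- function(cv) {
  if (!inherits(cv, "cv_result") || cv$algorithm != "random_forest" ||
      is.null(cv$importance))
    stop_validation("feature_importance requires random-forest CV results")
  m <- colMeans(cv$importance)
  share <- m / sum(m)
  out <- data.frame(feature = names(share), share = as.numeric(share),
                    row.names = NULL)
  out[order(-out$share), , drop = FALSE]
}
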