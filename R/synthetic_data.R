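# Synthetic phantoms and cohorts with known ground truth, so every pipeline
# stage (filter, cascade, fusion classifier, volumetry, outcome models) can
# be trained and evaluated without any external imaging data.

#' Phantom series specification
#'
#' Describes a stack of stylized axial head slices: a bright elliptical
#' "skull" ring, mid-gray parenchyma, a darker central "ventricle", and 0-3
#' hemorrhage lesions per slice whose geometry encodes the subtype: EDH a
#' biconvex lens abutting the inner skull, SDH a thin crescent hugging it,
#' IPH a compact parenchymal blob, IVH a blob confined to the ventricle, SAH
#' thin curvilinear streaks. Lesions are brighter than parenchyma by
#' `lesion_intensity_contrast` before Gaussian noise, so masks are exact by
#' construction.
#'
#' @param image_side Slice side in pixels (>= 32; 64 is the test scale, 512
#'   the clinical-resolution scale).
#' @param n_slices Number of slices.
#' @param subtype_mix Named nonnegative weights (edh, iph, ivh, sah, sdh)
#'   from which each lesion's subtype is drawn; normalized internally.
#' @param lesion_intensity_contrast Lesion brightness above parenchyma, in
#'   `(0, 1]`.
#' @param noise_sd Additive Gaussian noise SD (applied after drawing, images
#'   clamped back to `[0, 1]`).
#' @param fraction_empty_slices Probability a slice carries no lesion.
#' @param max_lesions Maximum lesions per non-empty slice (1-3).
#' @param lesion_area_px Target mean lesion area in pixels; defaults to
#'   `0.015 * image_side^2`.
#' @param pixel_spacing_mm,slice_thickness_mm Voxel geometry; spacing
#'   defaults keep the head's physical size constant across `image_side`.
#' @param seed Integer seed; the same spec yields bit-identical output.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_side = 64L, n_slices = 10L,
                         subtype_mix = c(edh = 1, iph = 1, ivh = 1,
                                         sah = 1, sdh = 1),
                         lesion_intensity_contrast = 0.35,
                         noise_sd = 0.03,
                         fraction_empty_slices = 0.5,
                         max_lesions = 3L,
                         lesion_area_px = NULL,
                         pixel_spacing_mm = NULL,
                         slice_thickness_mm = 5,
                         seed = 1L) {
  image_side <- as.integer(image_side)
  if (image_side < 32L) stop_validation("image_side must be >= 32")
  if (n_slices < 1L) stop_validation("n_slices must be >= 1")
  mix <- rep(0, 5); names(mix) <- SUBTYPES
  mix[names(subtype_mix)] <- subtype_mix
  if (any(mix < 0))
    stop_validation("subtype_mix weights must be nonnegative")
  if (sum(mix) <= 0) stop_validation("subtype_mix must have positive mass")
  if (lesion_intensity_contrast <= 0 || lesion_intensity_contrast > 1)
    stop_validation("lesion_intensity_contrast must lie in (0, 1]")
  if (noise_sd < 0) stop_validation("noise_sd must be nonnegative")
  if (fraction_empty_slices < 0 || fraction_empty_slices > 1)
    stop_validation("fraction_empty_slices must lie in [0, 1]")
  max_lesions <- as.integer(max_lesions)
  if (max_lesions < 1L || max_lesions > 3L)
    stop_validation("max_lesions must be 1, 2 or 3")
  structure(list(
    image_side = image_side, n_slices = as.integer(n_slices),
    subtype_mix = mix / sum(mix),
    lesion_intensity_contrast = lesion_intensity_contrast,
    noise_sd = noise_sd, fraction_empty_slices = fraction_empty_slices,
    max_lesions = max_lesions,
    lesion_area_px = lesion_area_px %||% round(0.015 * image_side^2),
    pixel_spacing_mm = pixel_spacing_mm %||%
      rep(0.45 * 512 / image_side, 2),
    slice_thickness_mm = slice_thickness_mm,
    seed = as.integer(seed)), class = "phantom_spec")
}

# anatomy constants (fractions of image_side)
PH <- list(head_a = 0.40, head_b = 0.34, brain_u = 0.88,
           vent_a = 0.16, vent_b = 0.08,
           bg = 0.02, parenchyma = 0.35, ventricle = 0.15, skull = 0.90)

phantom_geometry <- function(side) {
  cr <- (side + 1) / 2
  rr <- row(matrix(0, side, side)) - cr
  cc <- col(matrix(0, side, side)) - cr
  a <- PH$head_a * side; b <- PH$head_b * side
  u <- sqrt((rr / a)^2 + (cc / b)^2)           # normalized head radius
  v <- sqrt((rr / (PH$vent_a * side))^2 + (cc / (PH$vent_b * side))^2)
  phi <- atan2(rr / a, cc / b)                 # normalized angle
  list(rr = rr, cc = cc, a = a, b = b, u = u, v = v, phi = phi, cr = cr)
}

# lesion pixel sets; each returns a logical matrix
lesion_edh <- function(g, area) {
  r <- sqrt(area / 1.228)                      # lens of two r-discs, d = r
  th <- runif(1, 0, 2 * pi)
  p <- c(g$cr + PH$brain_u * g$a * sin(th), g$cr + PH$brain_u * g$b * cos(th))
  nrm <- c(sin(th) / g$a, cos(th) / g$b); nrm <- nrm / sqrt(sum(nrm^2))
  q <- p - (r / 2 + 1) * nrm                   # lens center, just inside
  c1 <- q - (r / 2) * nrm; c2 <- q + (r / 2) * nrm
  rr <- g$rr + g$cr; cc <- g$cc + g$cr
  ((rr - c1[1])^2 + (cc - c1[2])^2 < r^2) &
    ((rr - c2[1])^2 + (cc - c2[2])^2 < r^2) & (g$u <= PH$brain_u)
}

ang_diff <- function(x, y) {
  d <- abs(x - y) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

# thin arc in normalized-radius band [u0 - w, u0]; angular width solved from
# the band's pixel count so the arc hits the target area
lesion_arc <- function(g, area, u0, w) {
  band <- (g$u <= u0) & (g$u > u0 - w)
  n_band <- sum(band)
  if (n_band == 0L) return(band)
  th <- runif(1, 0, 2 * pi)
  half <- pi * min(1, area / n_band)
  band & (ang_diff(g$phi, th) < half)
}

lesion_sdh <- function(g, area, side) {
  lesion_arc(g, area, u0 = PH$brain_u, w = max(2.5, 0.05 * side) /
               (0.5 * (g$a + g$b)))
}

lesion_sah <- function(g, area, side) {
  w <- max(1.8, 0.028 * side) / (0.5 * (g$a + g$b))
  a1 <- lesion_arc(g, area / 2, u0 = runif(1, 0.45, 0.6), w = w)
  a2 <- lesion_arc(g, area / 2, u0 = runif(1, 0.62, 0.78), w = w)
  a1 | a2
}

lesion_iph <- function(g, area) {
  k <- runif(1, 1, 1.4)
  ra <- sqrt(area / pi) * k; rb <- sqrt(area / pi) / k
  u0 <- runif(1, 0.3, 0.6); th <- runif(1, 0, 2 * pi)
  ctr <- c(u0 * g$a * sin(th), u0 * g$b * cos(th))
  rot <- runif(1, 0, pi)
  dr <- g$rr - ctr[1]; dc <- g$cc - ctr[2]
  x1 <- cos(rot) * dr + sin(rot) * dc
  x2 <- -sin(rot) * dr + cos(rot) * dc
  ((x1 / ra)^2 + (x2 / rb)^2 < 1) & (g$u <= PH$brain_u) & (g$v > 1)
}

lesion_ivh <- function(g, area) {
  r <- sqrt(area / pi)
  # center jittered along the long (row) axis of the ventricle
  off <- runif(1, -0.35, 0.35)
  ctr <- c(off * PH$vent_a * (g$a / PH$head_a), 0)
  ((g$rr - ctr[1])^2 + (g$cc - ctr[2])^2 < r^2) & (g$v <= 1)
}

draw_lesion <- function(subtype, g, area, side) {
  switch(subtype,
         edh = lesion_edh(g, area),
         iph = lesion_iph(g, area),
         ivh = lesion_ivh(g, area),
         sah = lesion_sah(g, area, side),
         sdh = lesion_sdh(g, area, side))
}

#' Generate a phantom CT series with exact ground truth
#'
#' @param spec A [phantom_spec].
#' @return A list with `series` (a [ct_series]), `masks` (subtype-coded
#'   [label_mask] per slice; `binary_view()` gives the binary mask), and
#'   `labels` (a [subtype_labels] per slice).
#' @export
generate_phantom_series <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop_validation("spec must be a phantom_spec")
  set.seed(derive_seed(spec$seed, 11L))
  side <- spec$image_side
  g <- phantom_geometry(side)
  base <- matrix(PH$bg, side, side)
  base[g$u <= 1] <- PH$skull
  base[g$u <= PH$brain_u] <- PH$parenchyma
  base[g$v <= 1] <- PH$ventricle

  slices <- masks <- labels <- vector("list", spec$n_slices)
  for (k in seq_len(spec$n_slices)) {
    img <- base
    msk <- matrix(0L, side, side)
    lab <- subtype_labels()
    if (runif(1) >= spec$fraction_empty_slices) {
      w_les <- c(0.65, 0.25, 0.10)[seq_len(spec$max_lesions)]
      n_les <- sample.int(spec$max_lesions, 1, prob = w_les)
      subs <- sample(SUBTYPES, n_les, replace = TRUE, prob = spec$subtype_mix)
      for (s in subs) {
        px <- draw_lesion(s, g, spec$lesion_area_px, side)
        if (!any(px)) next
        img[px] <- pmin(1, PH$parenchyma + spec$lesion_intensity_contrast)
        msk[px] <- match(s, SUBTYPES)
        lab[match(s, SUBTYPES)] <- TRUE
      }
    }
    if (spec$noise_sd > 0) {
      img <- img + matrix(rnorm(side * side, 0, spec$noise_sd), side, side)
      img[img < 0] <- 0
      img[img > 1] <- 1
    }
    slices[[k]] <- img
    masks[[k]] <- label_mask(msk, encoding = "subtype")
    labels[[k]] <- lab
  }
  list(series = ct_series(sprintf("phantom-%d", spec$seed), slices,
                          spec$pixel_spacing_mm, spec$slice_thickness_mm),
       masks = masks, labels = labels)
}

# ---------------------------------------------------------------------------
# Synthetic msTBI cohorts

#' Names of the linear-predictor coefficients used by the cohort generator
#'
#' Order matches the design matrix of [build_features()] for the
#' `CRASH_CT_VOL_SUB` feature set, plus an intercept. Age enters on the
#' standardized Box-Cox scale (see [build_features()]).
#' @return Character vector of coefficient names.
#' @export
cohort_coef_names <- function() {
  c("intercept", "age_bc", "gcs", "pupils_one_reactive",
    "pupils_both_nonreactive", "major_extracranial_injury", "petechiae",
    "effaced_basal_cistern", "sah_present", "midline_shift",
    "nonevacuated_hematoma", "volume_ml", SUBTYPES)
}

#' Default true coefficients for the synthetic mortality model
#'
#' Signs follow the CRASH literature (older age, lower GCS, nonreactive
#' pupils, CT findings and larger hematomas all increase 14-day mortality);
#' the intercept is set so the default cohort has roughly 30% mortality
#' under scheme A, resembling a moderate-to-severe TBI case mix.
#'
#' @param scheme `"A"` (death) or `"B"` (death or coma; higher base rate,
#'   slightly stronger GCS effect).
#' @return Named numeric vector over [cohort_coef_names()].
#' @export
default_cohort_coefficients <- function(scheme = c("A", "B")) {
  scheme <- match.arg(scheme)
  b <- c(intercept = -1.93, age_bc = 0.55, gcs = -0.28,
         pupils_one_reactive = 0.55, pupils_both_nonreactive = 1.25,
         major_extracranial_injury = 0.45, petechiae = 0.40,
         effaced_basal_cistern = 0.75, sah_present = 0.40,
         midline_shift = 0.70, nonevacuated_hematoma = 0.45,
         volume_ml = 0.040, edh = -0.20, iph = 0.40, ivh = 0.50,
         sah = 0.30, sdh = 0.20)
  if (scheme == "B") {
    b["intercept"] <- -0.57       # death-or-coma base rate ~45%
    b["gcs"] <- -0.34
  }
  b
}

#' Synthetic cohort specification
#'
#' Patients satisfy the moderate-to-severe TBI inclusion window: GCS drawn
#' from 3-12 and age from a truncated normal confined to 18-80 years (median
#' near 57.5 by default). Two binary outcomes are generated from stated
#' logistic models: `death14` (scheme A coefficients) and `death_or_coma14`
#' (scheme B coefficients).
#'
#' @param n_patients Cohort size (>= 20).
#' @param coefficients,coefficients_b Named vectors over
#'   [cohort_coef_names()] for schemes A and B.
#' @param age_mean,age_sd Truncated-normal age parameters (years).
#' @param gcs_probs Length-10 weights over GCS 3..12.
#' @param volume_meanlog,volume_sdlog Lognormal hematoma-volume parameters
#'   (mL).
#' @param prevalence Named list of Bernoulli rates for the binary CT /
#'   clinical features and the five subtype indicators.
#' @param seed Integer seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 500L,
                        coefficients = default_cohort_coefficients("A"),
                        coefficients_b = default_cohort_coefficients("B"),
                        age_mean = 57, age_sd = 13,
                        gcs_probs = c(1, 1, 1.2, 1.2, 1.2, 1.2, 1.2, 1.2,
                                      1.4, 1.4),
                        volume_meanlog = log(15), volume_sdlog = 0.8,
                        prevalence = list(
                          pupils = c(both_reactive = 0.60,
                                     one_reactive = 0.20,
                                     both_nonreactive = 0.20),
                          major_extracranial_injury = 0.30,
                          petechiae = 0.35, effaced_basal_cistern = 0.30,
                          sah_present = 0.45, midline_shift = 0.35,
                          evacuated_hematoma = 0.25,
                          edh = 0.15, iph = 0.55, ivh = 0.20, sah = 0.45,
                          sdh = 0.40),
                        seed = 1L) {
  if (n_patients < 20L) stop_validation("n_patients must be >= 20")
  if (length(gcs_probs) != 10L || any(gcs_probs < 0))
    stop_validation("gcs_probs must be 10 nonnegative weights over GCS 3..12")
  full <- cohort_coef_names()
  for (nm in list(coefficients, coefficients_b))
    if (!all(names(nm) %in% full))
      stop_validation("unknown coefficient names in cohort_spec")
  pad <- function(b) { v <- setNames(numeric(length(full)), full)
                       v[names(b)] <- b; v }
  structure(list(n_patients = as.integer(n_patients),
                 coefficients = pad(coefficients),
                 coefficients_b = pad(coefficients_b),
                 age_mean = age_mean, age_sd = age_sd,
                 gcs_probs = gcs_probs / sum(gcs_probs),
                 volume_meanlog = volume_meanlog,
                 volume_sdlog = volume_sdlog,
                 prevalence = prevalence, seed = as.integer(seed)),
            class = "cohort_spec")
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  qnorm(runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd)), mean, sd)
}

#' Generate a synthetic msTBI cohort table
#'
#' One row per patient with all CRASH-CT features, hematoma volume, subtype
#' indicators, and outcomes drawn from the spec's logistic models. The true
#' linear predictors are stored per row (`true_lp_death14`,
#' `true_lp_death_or_coma14`) for oracle checks such as coefficient
#' recovery.
#'
#' @param spec A [cohort_spec].
#' @return A data frame; booleans encoded 0/1.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop_validation("spec must be a cohort_spec")
  set.seed(derive_seed(spec$seed, 23L))
  n <- spec$n_patients
  pv <- spec$prevalence
  df <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    age_years = rtruncnorm1(n, spec$age_mean, spec$age_sd, 18, 80),
    gcs = sample(3:12, n, replace = TRUE, prob = spec$gcs_probs),
    pupils = sample(names(pv$pupils), n, replace = TRUE, prob = pv$pupils),
    major_extracranial_injury = rbinom(n, 1, pv$major_extracranial_injury),
    petechiae = rbinom(n, 1, pv$petechiae),
    effaced_basal_cistern = rbinom(n, 1, pv$effaced_basal_cistern),
    sah_present = rbinom(n, 1, pv$sah_present),
    midline_shift = rbinom(n, 1, pv$midline_shift),
    evacuated_hematoma = rbinom(n, 1, pv$evacuated_hematoma),
    volume_ml = exp(rnorm(n, spec$volume_meanlog, spec$volume_sdlog)),
    edh = rbinom(n, 1, pv$edh), iph = rbinom(n, 1, pv$iph),
    ivh = rbinom(n, 1, pv$ivh), sah = rbinom(n, 1, pv$sah),
    sdh = rbinom(n, 1, pv$sdh),
    stringsAsFactors = FALSE)
  X <- cohort_design(df)
  lp_a <- drop(cbind(1, X) %*% spec$coefficients)
  lp_b <- drop(cbind(1, X) %*% spec$coefficients_b)
  df$death14 <- rbinom(n, 1, plogis(lp_a))
  df$death_or_coma14 <- rbinom(n, 1, plogis(lp_b))
  df$true_lp_death14 <- lp_a
  df$true_lp_death_or_coma14 <- lp_b
  df
}

# full CRASH_CT_VOL_SUB design (no intercept), shared by the generator and
# build_features so the stored true linear predictor matches the fitted model
cohort_design <- function(records) {
  bc <- box_cox(records$age_years)
  age_bc <- as.numeric(scale(bc$transformed))
  X <- cbind(
    age_bc = age_bc,
    gcs = records$gcs,
    pupils_one_reactive = as.numeric(records$pupils == "one_reactive"),
    pupils_both_nonreactive = as.numeric(records$pupils ==
                                           "both_nonreactive"),
    major_extracranial_injury = records$major_extracranial_injury,
    petechiae = records$petechiae,
    effaced_basal_cistern = records$effaced_basal_cistern,
    sah_present = records$sah_present,
    midline_shift = records$midline_shift,
    nonevacuated_hematoma = 1 - records$evacuated_hematoma,
    volume_ml = records$volume_ml,
    edh = records$edh, iph = records$iph, ivh = records$ivh,
    sah = records$sah, sdh = records$sdh)
  attr(X, "boxcox_lambda") <- bc$lambda
  X
}
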