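# End-to-end orchestration: binary filter -> cascade segmentation ->
# fusion classification -> volumetry -> outcome features.

# tiny FNV-1a hash over a serialized object, for provenance stamping
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Pipeline configuration
#'
#' Bundles the four trained models (or checkpoint paths) with the decision
#' thresholds. All models must agree on resolution; this is validated
#' before any inference runs.
#'
#' @param filter Binary hemorrhage filter (`cls_model` or path).
#' @param stage1,stage2 Segmentation stages (`seg_model` or path).
#' @param multilabel Subtype classifier (`fusion_model` or path).
#' @param threshold Segmentation / vote threshold.
#' @param filter_threshold Slice-filter decision threshold.
#' @param cls_threshold Per-subtype decision threshold.
#' @param margin ROI margin in pixels.
#' @param vote_strategy See [vote()].
#' @param seed Integer seed stamped into reports.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(filter, stage1, stage2, multilabel,
                            threshold = 0.5, filter_threshold = 0.5,
                            cls_threshold = 0.5, margin = 20L,
                            vote_strategy = "mean", seed = 1L) {
  load1 <- function(m) if (is.character(m)) load_model(m) else m
  filter <- load1(filter); stage1 <- load1(stage1)
  stage2 <- load1(stage2); multilabel <- load1(multilabel)
  sides <- c(filter$side, stage1$side, multilabel$side)
  if (length(unique(sides)) != 1L)
    hc_stop(sprintf("checkpoint resolutions disagree: %s",
                    paste(sides, collapse = "/")), "configuration_error")
  structure(list(filter = filter, stage1 = stage1, stage2 = stage2,
                 multilabel = multilabel, threshold = threshold,
                 filter_threshold = filter_threshold,
                 cls_threshold = cls_threshold, margin = as.integer(margin),
                 vote_strategy = vote_strategy, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis cascade over a CT series
#'
#' Slices failing the binary filter receive empty masks and all-false
#' subtype labels without invoking the segmenter or classifier; the rest
#' flow through [cascade_predict()], [build_fusion_input()] and
#' [predict_subtypes()]. Scan-level subtype labels are the logical OR over
#' slice labels; total volume is [hematoma_volume_ml()] of the emitted
#' masks.
#'
#' @param series A [ct_series] at the models' resolution.
#' @param cfg A [pipeline_config].
#' @return List with `masks` (binary [label_mask] per slice) and `report`
#'   (class `patient_report`): per-slice probabilities and labels,
#'   scan-level labels, `volume_ml`, ROI provenance, stage call counters
#'   and a config hash.
#' @export
run_pipeline <- function(series, cfg) {
  if (!inherits(cfg, "pipeline_config"))
    hc_stop("cfg must be a pipeline_config", "configuration_error")
  side <- nrow(series$slices[[1]])
  if (side != cfg$stage1$side)
    hc_stop(sprintf("series is %dpx but models expect %dpx", side,
                    cfg$stage1$side), "configuration_error")
  n <- length(series$slices)
  masks <- vector("list", n)
  rois <- vector("list", n)
  probs <- matrix(NA_real_, n, 5,
                  dimnames = list(NULL, paste0("p_", SUBTYPES)))
  labels <- matrix(FALSE, n, 5, dimnames = list(NULL, SUBTYPES))
  filter_probs <- numeric(n)
  n_seg <- n_stage2 <- n_cls <- 0L
  empty <- label_mask(matrix(0L, side, side), "binary")
  for (k in seq_len(n)) {
    sl <- series$slices[[k]]
    fp <- predict_binary(cfg$filter, sl)
    filter_probs[k] <- fp
    if (fp < cfg$filter_threshold) {
      masks[[k]] <- empty
      probs[k, ] <- 0
      next
    }
    n_seg <- n_seg + 1L
    cp <- cascade_predict(cfg$stage1, cfg$stage2, sl,
                          threshold = cfg$threshold, margin = cfg$margin,
                          strategy = cfg$vote_strategy)
    if (!is.null(cp$roi)) n_stage2 <- n_stage2 + 1L
    masks[[k]] <- cp$mask
    rois[[k]] <- cp$roi
    fi <- build_fusion_input(sl, cp$mask, cp$roi)
    ps <- predict_subtypes(cfg$multilabel, fi, cfg$cls_threshold)
    n_cls <- n_cls + 1L
    probs[k, ] <- ps$probs
    labels[k, ] <- as.logical(unclass(ps$labels))
  }
  scan_lab <- apply(labels, 2, any)
  report <- structure(list(
    patient_id = series$patient_id,
    per_slice = data.frame(slice = seq_len(n), filter_prob = filter_probs,
                           probs, labels * 1L, check.names = FALSE),
    scan_labels = subtype_labels(scan_lab[1], scan_lab[2], scan_lab[3],
                                 scan_lab[4], scan_lab[5]),
    volume_ml = hematoma_volume_ml(masks, series),
    rois = lapply(rois, function(r) if (is.null(r)) NULL else
      as.character(roi_to_json(r))),
    counters = c(n_slices = n, n_filter_positive = n_seg,
                 n_stage2_calls = n_stage2, n_classifier_calls = n_cls),
    package_version = as.character(utils::packageVersion("hemocascade")),
    config_hash = config_hash(list(cfg$threshold, cfg$filter_threshold,
                                   cfg$cls_threshold, cfg$margin,
                                   cfg$vote_strategy, cfg$seed))),
    class = "patient_report")
  list(masks = masks, report = report)
}

#' @export
print.patient_report <- function(x, ...) {
  cat(sprintf("patient_report '%s': %d slices, volume %.2f mL, labels ",
              x$patient_id, nrow(x$per_slice), x$volume_ml))
  print(x$scan_labels)
  invisible(x)
}

#' Extract cohort-table outcome features from a patient report
#'
#' Emits the automated hematoma volume and scan-level subtype indicators in
#' the cohort CSV column convention, ready to merge with clinical CRASH
#' predictors for the `CRASH_CT_VOL_SUB` models.
#'
#' @param report A `patient_report`.
#' @return One-row data frame with `patient_id`, `volume_ml`, `edh` ...
#'   `sdh` (0/1).
#' @export
extract_outcome_features <- function(report) {
  lab <- as.integer(unclass(report$scan_labels))
  out <- data.frame(patient_id = report$patient_id,
                    volume_ml = report$volume_ml)
  out[SUBTYPES] <- as.list(lab)
  out
}
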