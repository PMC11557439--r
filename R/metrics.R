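# Overlap metrics, multi-label classification reports, and volumetry.

#' Dice and IoU overlap scores
#'
#' `dice_score(a, b)` = 2|A∩B| / (|A| + |B|); `iou_score(a, b)` =
#' |A∩B| / |A∪B|. A pair of empty masks scores 1.0: a model that correctly
#' predicts "no hemorrhage" is right. The two are algebraically linked by
#' dice = 2 iou / (1 + iou).
#'
#' @param a,b Binary masks ([label_mask] or 0/1 matrices) of equal shape.
#' @return A scalar in `[0, 1]`.
#' @export
dice_score <- function(a, b) {
  ab <- check_mask_pair(a, b)
  inter <- sum(ab$a & ab$b)
  tot <- sum(ab$a) + sum(ab$b)
  if (tot == 0L) return(1.0)
  2 * inter / tot
}

#' @rdname dice_score
#' @export
iou_score <- function(a, b) {
  ab <- check_mask_pair(a, b)
  uni <- sum(ab$a | ab$b)
  if (uni == 0L) return(1.0)
  sum(ab$a & ab$b) / uni
}

check_mask_pair <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  if (!identical(dim(a), dim(b)))
    stop_validation("mask shapes do not match")
  list(a = a > 0, b = b > 0)
}

#' Hematoma volume from a mask stack
#'
#' Sums foreground voxels and converts to millilitres using the series
#' geometry: `n_voxels * row_spacing * col_spacing * thickness / 1000`.
#'
#' @param masks List of [label_mask], one per slice.
#' @param series The [ct_series] providing spacing and thickness.
#' @return Volume in mL.
#' @export
hematoma_volume_ml <- function(masks, series) {
  if (length(masks) != length(series$slices))
    stop_validation("need one mask per slice")
  sp <- series$pixel_spacing_mm
  if (is.null(sp) || length(sp) != 2L || any(!is.finite(sp)))
    stop_validation("series lacks pixel spacing")
  nvox <- sum(vapply(masks, function(m) sum(unclass(m) > 0L), numeric(1)))
  nvox * sp[1] * sp[2] * series$slice_thickness_mm / 1000
}

# Mann-Whitney AUC used as the cross-check oracle in tests; the reports use
# pROC.
rank_auc <- function(probs, truth) {
  pos <- probs[truth == 1]; neg <- probs[truth == 0]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Multi-label classification report with micro-averaged metrics
#'
#' Micro precision/recall/F1 are computed on the pooled `5n` per-label
#' decisions; micro-AUC is the AUROC over the pooled (probability, truth)
#' pairs. Two accuracies are reported under distinct names: subset accuracy
#' (all five labels of a sample correct) and per-label mean accuracy (the
#' mean per-decision accuracy).
#'
#' @param probs `n x 5` matrix of per-label probabilities (columns EDH, IPH,
#'   IVH, SAH, SDH).
#' @param truths `n x 5` binary matrix of reference labels.
#' @param threshold Decision threshold (default 0.5).
#' @return A list of class `multilabel_report` with fields `subset_accuracy`,
#'   `per_label_mean_accuracy`, `micro_precision`, `micro_recall`, `micro_f1`,
#'   `micro_auc` (NA when the pooled truths are single-class).
#' @export
multilabel_report <- function(probs, truths, threshold = 0.5) {
  probs <- as.matrix(probs); truths <- as.matrix(truths)
  if (!identical(dim(probs), dim(truths)) || nrow(probs) < 1L)
    stop_validation("probs and truths must be equal-shaped with n >= 1")
  truths <- (truths > 0) * 1L
  pred <- (probs >= threshold) * 1L
  tp <- sum(pred == 1L & truths == 1L)
  fp <- sum(pred == 1L & truths == 0L)
  fn <- sum(pred == 0L & truths == 1L)
  prec <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  rec  <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1   <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  pooled_truth <- as.vector(truths)
  auc <- if (length(unique(pooled_truth)) < 2L) NA_real_ else
    as.numeric(pROC::auc(pROC::roc(pooled_truth, as.vector(probs),
                                   levels = c(0, 1), direction = "<",
                                   quiet = TRUE)))
  structure(list(
    subset_accuracy = mean(apply(pred == truths, 1, all)),
    per_label_mean_accuracy = mean(pred == truths),
    micro_precision = prec, micro_recall = rec, micro_f1 = f1,
    micro_auc = auc), class = "multilabel_report")
}

#' @export
print.multilabel_report <- function(x, ...) {
  cat(sprintf(paste0("multilabel_report: subset acc %.4f | per-label acc ",
                     "%.4f | micro P %.4f R %.4f F1 %.4f AUC %s\n"),
              x$subset_accuracy, x$per_label_mean_accuracy,
              x$micro_precision, x$micro_recall, x$micro_f1,
              ifelse(is.na(x$micro_auc), "undefined",
                     sprintf("%.4f", x$micro_auc))))
  invisible(x)
}

#' Per-subtype segmentation scores
#'
#' Attributes each slice's binary-mask Dice/IoU to every subtype present in
#' its reference labels, so a slice labelled EDH+SDH contributes to both
#' buckets.
#'
#' @param pred_masks,gt_masks Aligned lists of binary masks.
#' @param labels Aligned list of [subtype_labels].
#' @return Named list (edh..sdh) of data frames with columns `slice`, `dice`,
#'   `iou`; empty data frame for subtypes never observed.
#' @export
per_subtype_seg_scores <- function(pred_masks, gt_masks, labels) {
  n <- length(pred_masks)
  if (length(gt_masks) != n || length(labels) != n)
    stop_validation("pred_masks, gt_masks and labels must be aligned")
  out <- setNames(vector("list", length(SUBTYPES)), SUBTYPES)
  for (s in SUBTYPES)
    out[[s]] <- data.frame(slice = integer(), dice = numeric(),
                           iou = numeric())
  for (i in seq_len(n)) {
    present <- SUBTYPES[unclass(labels[[i]])]
    if (length(present) == 0L) next
    d <- dice_score(pred_masks[[i]], gt_masks[[i]])
    j <- iou_score(pred_masks[[i]], gt_masks[[i]])
    for (s in present)
      out[[s]] <- rbind(out[[s]], data.frame(slice = i, dice = d, iou = j))
  }
  out
}
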