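# Two-stage coarse-to-fine hematoma segmentation: Stage I localizes the
# hemorrhage on the full slice, its binarized output defines an ROI, Stage II
# re-segments the margin-expanded crop, and the two probability maps are
# vote-fused in original-slice coordinates.

#' Joint image/mask augmentation policy
#'
#' Horizontal flip, vertical flip, rotation (within ±45°), zoom (80%-120%),
#' translation (±20% of the side) and shear (0%-10%), each applied with
#' probability `p_apply` (default 50%); the identical geometric transform is
#' applied to image and mask, the mask warped with nearest-neighbour
#' resampling so label values are never blended.
#'
#' @param p_apply Per-transform application probability.
#' @param rotation_deg Maximum absolute rotation in degrees.
#' @param zoom Length-2 zoom factor range.
#' @param translate_frac Maximum absolute translation as a fraction of side.
#' @param shear_frac Length-2 shear factor range.
#' @param flips Enable horizontal/vertical flips.
#' @return Object of class `augment_policy`.
#' @export
augment_policy <- function(p_apply = 0.5, rotation_deg = 45,
                           zoom = c(0.8, 1.2), translate_frac = 0.2,
                           shear_frac = c(0, 0.1), flips = TRUE) {
  if (p_apply < 0 || p_apply > 1) stop_validation("p_apply must be in [0,1]")
  structure(list(p_apply = p_apply, rotation_deg = rotation_deg,
                 zoom = zoom, translate_frac = translate_frac,
                 shear_frac = shear_frac, flips = flips),
            class = "augment_policy")
}

#' Apply a random joint augmentation to an image/mask pair
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param mask Aligned integer mask (may be `NULL` for classifier inputs).
#' @param policy An [augment_policy].
#' @param seed Optional seed making the draw reproducible; when `NULL` the
#'   current RNG stream is used (the training loops rely on this).
#' @return List with `image` and `mask`.
#' @export
augment <- function(image, mask = NULL, policy = augment_policy(),
                    seed = NULL) {
  if (!is.null(mask) && !identical(dim(unclass(image)), dim(unclass(mask))))
    stop_validation("image and mask shapes must match")
  if (!is.null(seed)) set.seed(seed)
  img <- unclass(image); msk <- if (is.null(mask)) NULL else unclass(mask)
  p <- policy$p_apply
  if (policy$flips && runif(1) < p) {        # horizontal flip
    img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
    if (!is.null(msk)) msk <- msk[, rev(seq_len(ncol(msk))), drop = FALSE]
  }
  if (policy$flips && runif(1) < p) {        # vertical flip
    img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
    if (!is.null(msk)) msk <- msk[rev(seq_len(nrow(msk))), , drop = FALSE]
  }
  ang <- if (runif(1) < p) runif(1, -policy$rotation_deg,
                                 policy$rotation_deg) * pi / 180 else 0
  zf  <- if (runif(1) < p) runif(1, policy$zoom[1], policy$zoom[2]) else 1
  tr  <- if (runif(1) < p) runif(2, -policy$translate_frac,
                                 policy$translate_frac) * nrow(img) else c(0, 0)
  sh  <- if (runif(1) < p) runif(1, policy$shear_frac[1],
                                 policy$shear_frac[2]) else 0
  if (ang != 0 || zf != 1 || any(tr != 0) || sh != 0) {
    ctr <- (dim(img) + 1) / 2
    A <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2) %*%
      matrix(c(zf, 0, 0, zf), 2) %*% matrix(c(1, 0, sh, 1), 2)
    offs <- ctr - A %*% ctr + tr
    m <- rbind(t(A), as.numeric(offs))
    img <- as_plain_matrix(EBImage::affine(img, m, filter = "bilinear",
                                           bg.col = 0))
    if (!is.null(msk)) {
      msk <- round(as_plain_matrix(EBImage::affine(
        `storage.mode<-`(msk, "double"), m, filter = "none", bg.col = 0)))
      storage.mode(msk) <- "integer"
    }
  }
  list(image = img, mask = msk)
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)` with smoothing
#' `eps = 1`, which keeps the loss finite and the gradient stable on
#' empty-mask samples.
#'
#' @param probs Probability matrix in `[0, 1]`.
#' @param target Binary mask of the same shape.
#' @param eps Smoothing constant.
#' @return Scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(probs, target, eps = 1) {
  p <- unclass(probs); t <- unclass(target)
  if (!identical(dim(p), dim(t))) stop_validation("shape mismatch")
  if (any(p < 0) || any(p > 1)) stop_validation("probs must lie in [0,1]")
  t <- (t > 0) * 1
  1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
}

# gradient of dice_loss wrt probs
dice_loss_grad <- function(p, t, eps = 1) {
  t <- (t > 0) * 1
  num <- 2 * sum(p * t) + eps
  den <- sum(p) + sum(t) + eps
  -(2 * t * den - num) / den^2
}

#' Segmentation training configuration
#'
#' Defaults follow the published training recipe: Adam with initial learning
#' rate 1e-4, cosine-annealing schedule, Dice loss, 500 epochs. The `tiny`
#' encoder (a 3-level UNet) is the CPU-scale backbone used throughout the
#' test suite; `resnet50` / `efficientnet_b6` with `unet` / `deeplabv3plus`
#' heads are accepted as configuration but require pretrained weights that
#' are not bundled.
#'
#' @param architecture `"unet"` or `"deeplabv3plus"`.
#' @param encoder `"tiny"`, `"resnet50"` or `"efficientnet_b6"`.
#' @param stage `"I"` (full slices) or `"II"` (ROI crops).
#' @param lr Initial learning rate (> 0).
#' @param epochs Number of passes over the data (>= 1).
#' @param batch_size Minibatch size.
#' @param base_channels Channel width of the tiny UNet's first level.
#' @param grad_clip Global L2 gradient-norm ceiling per batch (stabilizes
#'   the small networks against rare loss spikes).
#' @param augment Apply the augmentation `policy` during training.
#' @param policy An [augment_policy].
#' @param seed Integer seed controlling init, shuffling and augmentation.
#' @return Object of class `seg_train_config`.
#' @export
seg_train_config <- function(architecture = c("unet", "deeplabv3plus"),
                             encoder = c("tiny", "resnet50",
                                         "efficientnet_b6"),
                             stage = c("I", "II"), lr = 1e-4, epochs = 500L,
                             batch_size = 8L, base_channels = 8L,
                             grad_clip = 1, augment = TRUE,
                             policy = augment_policy(), seed = 1L) {
  architecture <- match.arg(architecture); encoder <- match.arg(encoder)
  stage <- match.arg(stage)
  if (lr <= 0) stop_validation("lr must be positive")
  if (epochs < 1) stop_validation("epochs must be >= 1")
  structure(list(architecture = architecture, encoder = encoder,
                 stage = stage, lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 base_channels = as.integer(base_channels),
                 grad_clip = grad_clip, augment = augment, policy = policy,
                 seed = as.integer(seed)),
            class = "seg_train_config")
}

check_tiny <- function(cfg) {
  if (cfg$encoder != "tiny" ||
      (!is.null(cfg$architecture) && cfg$architecture == "deeplabv3plus"))
    stop_validation(paste("encoder", cfg$encoder, "with architecture",
                          cfg$architecture,
                          "requires pretrained weights that are not",
                          "bundled; use encoder = 'tiny'"))
}

#' Train one segmentation stage
#'
#' Stage I is trained on full slices with full masks; Stage II on
#' ground-truth-ROI crops (see [stage2_training_data()]). Optimized with
#' Adam under a cosine-annealed learning rate and the soft Dice loss; the
#' run is bit-reproducible under `cfg$seed` on a single thread.
#'
#' @param data List of `list(image =, mask =)` pairs; images in `[0, 1]`,
#'   masks binary, all the same square side divisible by 4.
#' @param cfg A [seg_train_config].
#' @return A `seg_model` (serializable with [save_model()]), carrying the
#'   per-epoch mean training loss in `$history`.
#' @export
train_stage <- function(data, cfg) {
  if (!length(data)) stop_validation("empty training set")
  check_tiny(cfg)
  side <- nrow(data[[1]]$image)
  if (side %% 4L != 0L) stop_validation("slice side must be divisible by 4")
  set.seed(derive_seed(cfg$seed, 101L))
  params <- unet_init(1L, cfg$base_channels)
  opt <- adam_init(params)
  history <- numeric(cfg$epochs)
  n <- length(data)
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cosine_lr(cfg$lr, epoch, cfg$epochs)
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      grads <- NULL
      bl <- 0
      for (i in idx) {
        im <- data[[i]]$image; mk <- (unclass(data[[i]]$mask) > 0) * 1
        if (cfg$augment) {
          a <- augment(im, mk, cfg$policy)
          im <- a$image; mk <- a$mask
        }
        fw <- unet_forward(params, im)
        pr <- sigmoid(fw$z)
        bl <- bl + dice_loss(pr, mk)
        gz <- dice_loss_grad(pr, mk) * pr * (1 - pr)
        g <- unet_backward(params, fw$cache, gz)
        grads <- if (is.null(grads)) g else tree_map2(`+`, grads, g)
      }
      grads <- clip_global_norm(tree_map(function(x) x / length(idx),
                                         grads), cfg$grad_clip)
      st <- adam_step(params, grads, opt, lr)
      params <- st$params; opt <- st$state
      losses <- c(losses, bl / length(idx))
    }
    history[epoch] <- mean(losses)
  }
  structure(list(kind = "seg", params = params, cfg = cfg, side = side,
                 history = history), class = "seg_model")
}

#' Build Stage II training pairs from ground-truth ROIs
#'
#' Crops each slice and mask to the margin-expanded ground-truth bounding
#' square and resizes both to `out_side`; slices with empty masks are
#' dropped (Stage II only ever sees hemorrhage ROIs).
#'
#' @param slices,masks Aligned lists.
#' @param margin ROI margin in pixels.
#' @param out_side Output crop side; defaults to the slice side.
#' @return List of `list(image =, mask =)` pairs.
#' @export
stage2_training_data <- function(slices, masks, margin = 20L,
                                 out_side = NULL) {
  out <- list()
  for (i in seq_along(slices)) {
    m <- (unclass(masks[[i]]) > 0) * 1L
    if (!any(m > 0)) next
    roi <- compute_roi(m, margin = margin,
                       resized_side = out_side %||% nrow(slices[[i]]))
    out[[length(out) + 1L]] <- list(
      image = crop_and_resize(slices[[i]], roi, is_mask = FALSE),
      mask = crop_and_resize(m, roi, is_mask = TRUE))
  }
  if (!length(out)) stop_validation("no nonempty masks for Stage II data")
  out
}

#' Per-pixel foreground probabilities from a trained segmentation model
#'
#' @param model A `seg_model`.
#' @param slice Square matrix at the model's training resolution.
#' @return Probability matrix in `[0, 1]`; deterministic.
#' @export
predict_seg <- function(model, slice) {
  s <- unclass(slice)
  if (!inherits(model, "seg_model")) stop_validation("not a seg_model")
  if (nrow(s) != model$side || ncol(s) != model$side)
    stop_validation(sprintf("slice is %dx%d but model expects %dx%d",
                            nrow(s), ncol(s), model$side, model$side))
  sigmoid(unet_forward(model$params, s)$z)
}

#' Fuse two probability maps into a final mask by voting
#'
#' The default `mean` strategy averages the two maps pixel-wise and
#' thresholds the result; `union` / `intersection` threshold each map first
#' and combine logically, provided for sensitivity checks.
#'
#' @param probs_a,probs_b Equal-shaped probability maps in `[0, 1]`.
#' @param threshold Decision threshold.
#' @param strategy `"mean"`, `"union"` or `"intersection"`.
#' @return Binary [label_mask].
#' @export
vote <- function(probs_a, probs_b, threshold = 0.5,
                 strategy = c("mean", "union", "intersection")) {
  strategy <- match.arg(strategy)
  a <- unclass(probs_a); b <- unclass(probs_b)
  if (!identical(dim(a), dim(b))) stop_validation("shape mismatch")
  if (any(c(a, b) < 0) || any(c(a, b) > 1))
    stop_validation("probabilities must lie in [0,1]")
  keep <- switch(strategy,
                 mean = (a + b) / 2 >= threshold,
                 union = (a >= threshold) | (b >= threshold),
                 intersection = (a >= threshold) & (b >= threshold))
  label_mask(matrix(as.integer(keep), nrow(a), ncol(a)), "binary")
}

#' Coarse-to-fine cascade prediction for one slice
#'
#' Stage I probabilities are thresholded; if nothing survives, an empty mask
#' is returned and Stage II is never invoked. Otherwise the Stage I binary
#' map defines the margin-expanded ROI, the crop is re-segmented by Stage
#' II, its probabilities are back-projected to slice coordinates, and the
#' two maps are vote-fused.
#'
#' @param stage1,stage2 Trained `seg_model`s at compatible resolutions.
#' @param slice Input slice at Stage I resolution.
#' @param threshold Binarization threshold for both the Stage I gate and the
#'   final vote.
#' @param margin ROI margin in pixels.
#' @param strategy Vote strategy, see [vote()].
#' @return List with `mask` (binary [label_mask]) and `roi` ([roi_box] or
#'   `NULL` when Stage I found nothing).
#' @export
cascade_predict <- function(stage1, stage2, slice, threshold = 0.5,
                            margin = 20L, strategy = "mean") {
  p1 <- predict_seg(stage1, slice)
  bin1 <- p1 >= threshold
  if (!any(bin1)) {
    empty <- label_mask(matrix(0L, nrow(p1), ncol(p1)), "binary")
    return(list(mask = empty, roi = NULL, stage1_probs = p1))
  }
  roi <- compute_roi(matrix(as.integer(bin1), nrow(p1), ncol(p1)),
                     margin = margin, resized_side = stage2$side)
  crop <- crop_and_resize(unclass(slice), roi, is_mask = FALSE)
  p2 <- predict_seg(stage2, crop)
  p2_full <- backproject(p2, roi, is_mask = FALSE)
  p2_full <- pmin(pmax(p2_full, 0), 1)
  list(mask = vote(p1, p2_full, threshold, strategy), roi = roi,
       stage1_probs = p1, stage2_probs = p2_full)
}

#' Save / load a model checkpoint
#'
#' Checkpoints round-trip bit-exactly: a reloaded model produces identical
#' prediction rasters.
#'
#' @param model A `seg_model`, `cls_model` or `fusion_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `path` / the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_io(paste("no such checkpoint:", path))
  readRDS(path)
}
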