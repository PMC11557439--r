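# Slice-level hemorrhage filtering and mask-guided subtype classification.
# The multi-label model runs two CNN branches — the full slice and the ROI
# crop, each with the predicted mask stacked as a second channel — pools
# each with global average pooling, concatenates the pooled vectors and maps
# them through one linear layer to five sigmoid outputs.

#' Focal loss
#'
#' Mean over labels of `-alpha * (1 - p_t)^gamma * log(p_t)` with
#' `p_t = p` when the target is 1 and `1 - p` otherwise. With `gamma = 0`,
#' `alpha = 1` this reduces exactly to binary cross-entropy.
#'
#' @param probs Probabilities in `[0, 1]`.
#' @param targets Binary targets of the same length.
#' @param gamma Focusing exponent (>= 0), default 2.
#' @param alpha Class weight in `(0, 1]`, default 0.25.
#' @return Nonnegative scalar.
#' @export
focal_loss <- function(probs, targets, gamma = 2, alpha = 0.25) {
  if (length(probs) != length(targets))
    stop_validation("probs and targets must have equal length")
  if (any(probs < 0) || any(probs > 1))
    stop_validation("probs must lie in [0,1]")
  if (gamma < 0 || alpha <= 0 || alpha > 1)
    stop_validation("need gamma >= 0 and alpha in (0,1]")
  t <- (targets > 0) * 1
  pt <- ifelse(t == 1, probs, 1 - probs)
  pt <- pmin(pmax(pt, 1e-7), 1 - 1e-7)
  mean(-alpha * (1 - pt)^gamma * log(pt))
}

# d(mean focal)/d(logits); reduces to (p - t)/K at gamma = 0, alpha = 1
focal_grad_logits <- function(probs, targets, gamma, alpha) {
  t <- (targets > 0) * 1
  p <- pmin(pmax(probs, 1e-7), 1 - 1e-7)
  g1 <- alpha * gamma * p * (1 - p)^gamma * log(p) - alpha * (1 - p)^(gamma + 1)
  g0 <- alpha * p^(gamma + 1) - alpha * gamma * (1 - p) * p^gamma * log(1 - p)
  ifelse(t == 1, g1, g0) / length(p)
}

#' Classifier training configuration
#'
#' @param backbone `"tiny"` (the CPU-scale CNN), `"resnet50"` or
#'   `"efficientnet_b6"` (accepted but require pretrained weights that are
#'   not bundled).
#' @param task `"binary"` (cross-entropy) or `"multilabel"` (focal loss).
#' @param lr Initial learning rate; cosine-annealed, Adam.
#' @param epochs Training epochs (default 100).
#' @param focal_gamma,focal_alpha Focal-loss parameters for the multilabel
#'   task.
#' @param batch_size Minibatch size.
#' @param base_channels First-level channel width of the tiny backbone.
#' @param head_lr_mult Learning-rate multiplier for the linear head relative
#'   to the backbone; the head adapts quickly on top of slowly evolving
#'   convolutional features.
#' @param grad_clip Global L2 gradient-norm ceiling per batch.
#' @param fusion `"both"` (global + local branches) or `"global_only"`
#'   (ablation without the ROI branch).
#' @param seed Integer seed.
#' @return Object of class `cls_train_config`.
#' @export
cls_train_config <- function(backbone = c("tiny", "resnet50",
                                          "efficientnet_b6"),
                             task = c("binary", "multilabel"),
                             lr = 1e-4, epochs = 100L,
                             focal_gamma = 2, focal_alpha = 0.25,
                             batch_size = 8L, base_channels = 8L,
                             head_lr_mult = 10, grad_clip = 1,
                             fusion = c("both", "global_only"),
                             seed = 1L) {
  backbone <- match.arg(backbone); task <- match.arg(task)
  fusion <- match.arg(fusion)
  if (lr <= 0) stop_validation("lr must be positive")
  if (epochs < 1) stop_validation("epochs must be >= 1")
  if (focal_gamma < 0 || focal_alpha <= 0 || focal_alpha > 1)
    stop_validation("need focal_gamma >= 0 and focal_alpha in (0,1]")
  structure(list(backbone = backbone, task = task, lr = lr,
                 epochs = as.integer(epochs), focal_gamma = focal_gamma,
                 focal_alpha = focal_alpha,
                 batch_size = as.integer(batch_size),
                 base_channels = as.integer(base_channels),
                 head_lr_mult = head_lr_mult, grad_clip = grad_clip,
                 fusion = fusion,
                 seed = as.integer(seed)),
            class = "cls_train_config")
}

check_tiny_cls <- function(cfg) {
  if (cfg$backbone != "tiny")
    stop_validation(paste("backbone", cfg$backbone, "requires pretrained",
                          "weights that are not bundled; use 'tiny'"))
}

#' Train the slice-level binary hemorrhage filter
#'
#' Slices scoring probability >= 0.5 pass downstream to segmentation;
#' negatives are filtered out so the expensive stages never see them.
#'
#' @param data List of `list(image =, label =)` with binary labels; both
#'   classes must be present.
#' @param cfg A [cls_train_config] with `task = "binary"`.
#' @return A `cls_model` with per-epoch training loss in `$history`.
#' @export
train_binary_filter <- function(data, cfg = cls_train_config(task = "binary")) {
  if (!length(data)) stop_validation("empty training set")
  labs <- vapply(data, function(d) as.numeric(d$label), numeric(1))
  if (length(unique(labs > 0)) < 2L)
    stop_validation("both classes must be present")
  check_tiny_cls(cfg)
  side <- nrow(data[[1]]$image)
  if (side %% 8L != 0L) stop_validation("slice side must be divisible by 8")
  set.seed(derive_seed(cfg$seed, 211L))
  f <- cfg$base_channels
  params <- list(bb = cnn_init(1L, f),
                 head = list(w = matrix(rnorm(4 * f, 0, sqrt(1 / (4 * f))),
                                        4 * f, 1), b = 0))
  feats <- t(vapply(data, function(d)
    cnn_forward(params$bb, d$image)$pooled, numeric(4 * f)))
  norm <- feature_norm_stats(feats)
  fit <- cls_train_loop(params, data, cfg, norm,
                        get_input = function(d) d$image,
                        get_target = function(d) (d$label > 0) * 1)
  structure(list(kind = "cls_binary", params = fit$params, cfg = cfg,
                 norm = norm, side = side, history = fit$history),
            class = "cls_model")
}

# frozen per-feature standardization of the pooled vector: raw GAP features
# are tiny and ill-scaled for the linear head; the stats are computed once
# over the training set with the freshly initialized backbone and kept
# fixed thereafter (they travel with the checkpoint)
feature_norm_stats <- function(feats) {
  list(mu = colMeans(feats),
       sd = pmax(apply(feats, 2, sd), 1e-6))
}

cls_forward <- function(params, x, norm) {
  fw <- cnn_forward(params$bb, x)
  yn <- (fw$pooled - norm$mu) / norm$sd
  z <- drop(crossprod(params$head$w, yn)) + params$head$b
  list(z = z, fw = fw, yn = yn)
}

cls_train_loop <- function(params, data, cfg, norm, get_input, get_target) {
  opt <- adam_init(params)
  n <- length(data)
  history <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    lr0 <- cosine_lr(cfg$lr, epoch, cfg$epochs)
    lr <- list(head = lr0 * cfg$head_lr_mult, .default = lr0)
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      grads <- NULL; bl <- 0
      for (i in idx) {
        x <- get_input(data[[i]]); t <- get_target(data[[i]])
        fo <- cls_forward(params, x, norm)
        p <- sigmoid(fo$z)
        if (cfg$task == "binary") {
          pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
          bl <- bl + mean(-(t * log(pc) + (1 - t) * log(1 - pc)))
          gz <- (p - t) / length(p)
        } else {
          bl <- bl + focal_loss(p, t, cfg$focal_gamma, cfg$focal_alpha)
          gz <- focal_grad_logits(p, t, cfg$focal_gamma, cfg$focal_alpha)
        }
        gz <- matrix(gz, ncol = 1)
        ghead <- list(w = fo$yn %*% t(gz), b = drop(gz))
        gpooled <- drop(params$head$w %*% gz) / norm$sd
        g <- list(bb = cnn_backward(params$bb, fo$fw$cache, gpooled),
                  head = ghead)
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
  list(params = params, history = history)
}

#' Hemorrhage probability for one slice
#' @param model A `cls_model` from [train_binary_filter()].
#' @param slice Matrix at the model's training resolution.
#' @return Probability scalar.
#' @export
predict_binary <- function(model, slice) {
  s <- unclass(slice)
  if (nrow(s) != model$side) stop_validation("resolution mismatch")
  sigmoid(cls_forward(model$params, s, model$norm)$z)
}

#' Build the global/local fusion input for the subtype classifier
#'
#' The predicted mask is superimposed on the slice as a second channel
#' (channel concatenation, lossless for both signals). The local view crops
#' both channels to the cascade's ROI and resizes them to the classifier
#' resolution; when the segmenter found nothing (`roi = NULL`) the local
#' view degenerates to a copy of the global view.
#'
#' @param slice Intensity matrix.
#' @param pred_mask Aligned binary [label_mask].
#' @param roi [roi_box] from the cascade, or `NULL`.
#' @param out_side Classifier resolution; defaults to the slice side.
#' @return Object of class `fusion_input` with `global_view` and
#'   `local_view`, each an `out_side x out_side x 2` array.
#' @export
build_fusion_input <- function(slice, pred_mask, roi = NULL,
                               out_side = NULL) {
  s <- unclass(slice); m <- unclass(pred_mask)
  if (!identical(dim(s), dim(m)))
    stop_validation("slice and mask shapes must match")
  out_side <- out_side %||% nrow(s)
  gs <- resize_to_standard(s, out_side, is_mask = FALSE)
  gm <- resize_to_standard(m, out_side, is_mask = TRUE)
  global_view <- array(c(gs, as.numeric(gm > 0)), c(out_side, out_side, 2))
  local_view <- if (is.null(roi)) global_view else {
    ls <- crop_and_resize(s, roi, out_side, is_mask = FALSE)
    lm <- crop_and_resize(m, roi, out_side, is_mask = TRUE)
    array(c(ls, as.numeric(lm > 0)), c(out_side, out_side, 2))
  }
  structure(list(global_view = global_view, local_view = local_view),
            class = "fusion_input")
}

#' Train the multi-label subtype classifier
#'
#' Two tiny CNN branches (global and local view) each end in global average
#' pooling; the pooled vectors are concatenated and mapped by one linear
#' layer to five sigmoid outputs (EDH, IPH, IVH, SAH, SDH), trained with
#' focal loss. `cfg$fusion = "global_only"` drops the local branch, the
#' ablation used to quantify the fusion benefit.
#'
#' @param data List of `list(input = fusion_input, labels = subtype_labels)`.
#' @param cfg A [cls_train_config] with `task = "multilabel"`.
#' @return A `fusion_model` with `$history`.
#' @export
train_multilabel <- function(data,
                             cfg = cls_train_config(task = "multilabel")) {
  if (!length(data)) stop_validation("empty training set")
  check_tiny_cls(cfg)
  side <- dim(data[[1]]$input$global_view)[1]
  if (side %% 8L != 0L) stop_validation("input side must be divisible by 8")
  set.seed(derive_seed(cfg$seed, 307L))
  f <- cfg$base_channels
  nb <- if (cfg$fusion == "both") 2L else 1L
  params <- list(g = cnn_init(2L, f),
                 head = list(w = matrix(rnorm(nb * 4 * f * 5, 0,
                                              sqrt(1 / (nb * 4 * f))),
                                        nb * 4 * f, 5), b = numeric(5)))
  if (cfg$fusion == "both") params$l <- cnn_init(2L, f)
  norm <- list(g = feature_norm_stats(t(vapply(data, function(d)
    cnn_forward(params$g, d$input$global_view)$pooled, numeric(4 * f)))))
  if (cfg$fusion == "both")
    norm$l <- feature_norm_stats(t(vapply(data, function(d)
      cnn_forward(params$l, d$input$local_view)$pooled, numeric(4 * f))))
  opt <- adam_init(params)
  n <- length(data)
  history <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    lr0 <- cosine_lr(cfg$lr, epoch, cfg$epochs)
    lr <- list(head = lr0 * cfg$head_lr_mult, .default = lr0)
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      grads <- NULL; bl <- 0
      for (i in idx) {
        inp <- data[[i]]$input
        t <- as.numeric(unclass(data[[i]]$labels))
        fg <- cnn_forward(params$g, inp$global_view)
        feat <- (fg$pooled - norm$g$mu) / norm$g$sd
        fl <- NULL
        if (cfg$fusion == "both") {
          fl <- cnn_forward(params$l, inp$local_view)
          feat <- c(feat, (fl$pooled - norm$l$mu) / norm$l$sd)
        }
        z <- drop(crossprod(params$head$w, feat)) + params$head$b
        p <- sigmoid(z)
        bl <- bl + focal_loss(p, t, cfg$focal_gamma, cfg$focal_alpha)
        gz <- focal_grad_logits(p, t, cfg$focal_gamma, cfg$focal_alpha)
        ghead <- list(w = feat %*% t(gz), b = gz)
        gfeat <- drop(params$head$w %*% gz)
        f4 <- length(fg$pooled)
        g <- list(g = cnn_backward(params$g, fg$cache,
                                   gfeat[seq_len(f4)] / norm$g$sd),
                  head = ghead)
        if (cfg$fusion == "both")
          g$l <- cnn_backward(params$l, fl$cache,
                              gfeat[-seq_len(f4)] / norm$l$sd)
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
  structure(list(kind = "cls_multilabel", params = params, cfg = cfg,
                 norm = norm, side = side, history = history),
            class = "fusion_model")
}

#' Predict subtype labels and probabilities
#'
#' @param model A `fusion_model`.
#' @param input A [build_fusion_input()] object at the model resolution.
#' @param threshold Per-label decision threshold.
#' @return List with `labels` ([subtype_labels]) and `probs` (named length-5
#'   vector).
#' @export
predict_subtypes <- function(model, input, threshold = 0.5) {
  if (!inherits(model, "fusion_model")) stop_validation("not a fusion_model")
  if (dim(input$global_view)[1] != model$side)
    stop_validation("resolution mismatch")
  p <- model$params; nrm <- model$norm
  feat <- (cnn_forward(p$g, input$global_view)$pooled - nrm$g$mu) /
    nrm$g$sd
  if (model$cfg$fusion == "both")
    feat <- c(feat, (cnn_forward(p$l, input$local_view)$pooled -
                       nrm$l$mu) / nrm$l$sd)
  z <- drop(crossprod(p$head$w, feat)) + p$head$b
  probs <- setNames(sigmoid(z), SUBTYPES)
  on <- probs >= threshold
  list(labels = subtype_labels(on[1], on[2], on[3], on[4], on[5]),
       probs = probs)
}
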