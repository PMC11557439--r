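# Small trained models shared across pipeline tests; built once per run.
.model_cache <- new.env(parent = emptyenv())

quick_models <- function() {
  if (!is.null(.model_cache$models)) return(.model_cache$models)
  train <- phantom_slice_dataset(60, seed = 101, image_side = 64,
                                 fraction_empty_slices = 0.4)
  cls_data <- lapply(train, function(s)
    list(image = s$image, label = as.integer(any(unclass(s$mask) > 0))))
  filt <- train_binary_filter(
    cls_data, cls_train_config(task = "binary", lr = 1e-3, epochs = 8,
                               seed = 1))
  seg_data <- lapply(train, function(s)
    list(image = s$image, mask = s$mask))
  stage1 <- train_stage(seg_data,
                        seg_train_config(stage = "I", lr = 1e-3,
                                         epochs = 8, seed = 1))
  s2 <- stage2_training_data(lapply(train, `[[`, "image"),
                             lapply(train, `[[`, "mask"))
  stage2 <- train_stage(s2, seg_train_config(stage = "II", lr = 1e-3,
                                             epochs = 8, seed = 1))
  pos <- Filter(function(s) any(unclass(s$mask) > 0), train)
  ml_data <- lapply(pos, function(s) {
    roi <- compute_roi(unclass(s$mask), margin = 20)
    list(input = build_fusion_input(s$image, s$mask, roi), labels = s$label)
  })
  multilabel <- train_multilabel(
    ml_data, cls_train_config(task = "multilabel", lr = 1e-3, epochs = 5,
                              seed = 1))
  .model_cache$models <- list(filter = filt, stage1 = stage1,
                              stage2 = stage2, multilabel = multilabel)
  .model_cache$models
}
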