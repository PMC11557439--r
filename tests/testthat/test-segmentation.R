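test_that("dice loss matches its closed form and the dice score", {
  t <- matrix(0L, 64, 64); t[1:32, ] <- 1L     # half foreground
  p_perfect <- matrix(as.numeric(t), 64, 64)
  expect_lte(dice_loss(p_perfect, t), 1e-3)
  expect_gte(dice_loss(1 - p_perfect, t), 0.999)
  A <- sum(t); N <- length(t)
  p_half <- matrix(0.5, 64, 64)
  expect_equal(dice_loss(p_half, t),
               1 - (2 * 0.5 * A + 1) / (0.5 * N + A + 1), tolerance = 1e-12)
  # binary inputs: loss = 1 - dice up to the epsilon smoothing, and equals
  # the epsilon-smoothed closed form exactly
  set.seed(51)
  for (i in 1:10) {
    a <- random_rect_mask(32, min_sz = 6); b <- random_rect_mask(32,
                                                                 min_sz = 6)
    I <- sum(a & b); S <- sum(a) + sum(b)
    expect_equal(dice_loss(matrix(as.numeric(a), 32, 32), b),
                 1 - (2 * I + 1) / (S + 1), tolerance = 1e-12)
    expect_equal(dice_loss(matrix(as.numeric(a), 32, 32), b),
                 1 - dice_score(a, b), tolerance = 2 / (S + 1))
  }
  expect_error(dice_loss(matrix(0.5, 2, 2), matrix(0L, 3, 3)),
               class = "hemocascade_validation_error")
  expect_error(dice_loss(matrix(2, 2, 2), matrix(0L, 2, 2)),
               class = "hemocascade_validation_error")
})

test_that("flips are involutions and masks keep their label sets", {
  img <- matrix(runif(64^2), 64, 64)
  msk <- random_rect_mask(64) * 3L
  flip_only <- augment_policy(p_apply = 1, rotation_deg = 0, zoom = c(1, 1),
                              translate_frac = 0, shear_frac = c(0, 0))
  once <- augment(img, msk, flip_only, seed = 1)
  twice <- augment(once$image, once$mask, flip_only, seed = 1)
  expect_equal(twice$image, img)
  expect_identical(twice$mask, msk)
  warped <- augment(img, msk, augment_policy(p_apply = 1), seed = 4)
  expect_true(all(unique(as.vector(warped$mask)) %in% c(0L, 3L)))
  expect_identical(augment(img, msk, augment_policy(), seed = 9),
                   augment(img, msk, augment_policy(), seed = 9))
  expect_error(augment(img, matrix(0L, 32, 32)),
               class = "hemocascade_validation_error")
})

test_that("rotations never exceed the declared +/-45 degree range", {
  # rotation-only policy; track where a marker pixel lands over many draws
  pol <- augment_policy(p_apply = 1, zoom = c(1, 1), translate_frac = 0,
                        shear_frac = c(0, 0), flips = FALSE)
  side <- 65; ctr <- (side + 1) / 2; r <- 20
  msk <- matrix(0L, side, side)
  msk[ctr + (-1:1), ctr + r + (-1:1)] <- 1L        # 3x3 marker block
  img <- matrix(0, side, side)
  for (s in 1:100) {
    w <- augment(img, msk, pol, seed = s)$mask
    hit <- which(w > 0, arr.ind = TRUE)
    expect_gte(nrow(hit), 1)
    dr <- mean(hit[, 1]) - ctr; dc <- mean(hit[, 2]) - ctr
    expect_lt(abs(sqrt(dr^2 + dc^2) - r), 2.5)      # radius preserved
    expect_lte(abs(atan2(dr, dc)), 46 * pi / 180)   # sweep bounded
  }
})

test_that("vote combines probability maps per strategy", {
  a <- matrix(0.9, 2, 2); b <- matrix(0.2, 2, 2)
  expect_equal(sum(vote(a, b, 0.5)), 4L)          # mean 0.55 -> foreground
  expect_equal(sum(vote(a, b, 0.6)), 0L)
  p <- matrix(runif(16), 4, 4)
  expect_equal(unclass(vote(p, p, 0.5)),
               matrix(as.integer(p >= 0.5), 4, 4), ignore_attr = TRUE)
  da <- matrix(0, 4, 4); da[1, 1] <- 0.9
  db <- matrix(0, 4, 4); db[4, 4] <- 0.8
  u <- vote(da, db, 0.5, strategy = "union")
  expect_equal(which(unclass(u) == 1L), c(1L, 16L))
  expect_equal(sum(vote(da, db, 0.5, strategy = "intersection")), 0L)
  expect_error(vote(a, matrix(0.1, 3, 3), 0.5),
               class = "hemocascade_validation_error")
})

test_that("segmentation training smokes, declines and round-trips", {
  data <- lapply(tiny_phantoms(12, fraction_empty_slices = 0.25),
                 function(s) list(image = s$image, mask = s$mask))
  cfg <- seg_train_config(lr = 1e-3, epochs = 3, seed = 1, augment = FALSE)
  m <- train_stage(data, cfg)
  expect_true(all(is.finite(m$history)))
  expect_lt(m$history[3], m$history[1])
  p <- predict_seg(m, data[[1]]$image)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(p, predict_seg(m, data[[1]]$image))
  tf <- withr::local_tempfile(fileext = ".rds")
  save_model(m, tf)
  expect_identical(predict_seg(load_model(tf), data[[1]]$image), p)
  expect_error(train_stage(list(), cfg),
               class = "hemocascade_validation_error")
  expect_error(predict_seg(m, matrix(0, 32, 32)),
               class = "hemocascade_validation_error")
  expect_error(seg_train_config(lr = 0),
               class = "hemocascade_validation_error")
  expect_error(train_stage(data, seg_train_config(encoder = "resnet50")),
               class = "hemocascade_validation_error")
})

test_that("training is reproducible bit-for-bit under a fixed seed", {
  data <- lapply(tiny_phantoms(8, fraction_empty_slices = 0.25),
                 function(s) list(image = s$image, mask = s$mask))
  cfg <- seg_train_config(lr = 1e-3, epochs = 2, seed = 3)
  m1 <- train_stage(data, cfg)
  m2 <- train_stage(data, cfg)
  expect_identical(m1$params, m2$params)
})

test_that("stage II data are ROI crops of hemorrhage slices only", {
  items <- tiny_phantoms(10, fraction_empty_slices = 0.5)
  slices <- lapply(items, `[[`, "image")
  masks <- lapply(items, `[[`, "mask")
  n_pos <- sum(vapply(masks, function(m) any(unclass(m) > 0), logical(1)))
  s2 <- stage2_training_data(slices, masks, margin = 10)
  expect_length(s2, n_pos)
  expect_true(all(vapply(s2, function(d) any(d$mask > 0), logical(1))))
  empt <- lapply(masks, function(m) label_mask(matrix(0L, 64, 64)))
  expect_error(stage2_training_data(slices, empt),
               class = "hemocascade_validation_error")
})

test_that("the cascade gate skips Stage II when Stage I finds nothing", {
  data <- lapply(tiny_phantoms(6, fraction_empty_slices = 0.25),
                 function(s) list(image = s$image, mask = s$mask))
  m <- train_stage(data, seg_train_config(lr = 1e-3, epochs = 1, seed = 1))
  silent <- m
  silent$params$out$w[] <- 0
  silent$params$out$b <- -10       # sigmoid ~ 0 everywhere
  res <- cascade_predict(silent, m, data[[1]]$image)
  expect_null(res$roi)
  expect_equal(sum(res$mask), 0L)
  loud <- m
  loud$params$out$w[] <- 0
  loud$params$out$b <- 10
  res2 <- cascade_predict(loud, silent, data[[1]]$image)
  expect_s3_class(res2$roi, "roi_box")
  expect_identical(res2, cascade_predict(loud, silent, data[[1]]$image))
})
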