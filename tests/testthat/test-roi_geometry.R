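test_that("compute_roi reproduces hand-worked bounding-square geometry", {
  m <- matrix(0L, 512, 512)
  m[101:150, 201:240] <- 1L   # rows [100,150), cols [200,240) 0-based
  r <- compute_roi(m, margin = 20)
  expect_equal(c(r$row_min, r$row_max, r$col_min, r$col_max),
               c(80L, 170L, 175L, 265L))
  m1 <- matrix(0L, 512, 512); m1[101, 101] <- 1L
  r1 <- compute_roi(m1, margin = 20)
  expect_equal(c(r1$row_min, r1$row_max, r1$col_min, r1$col_max),
               c(80L, 121L, 80L, 121L))
  expect_error(compute_roi(matrix(0L, 64, 64)),
               class = "hemocascade_empty_mask_error")
})

test_that("odd square expansion puts the extra pixel on the high side", {
  m <- matrix(0L, 64, 64)
  m[11:15, 11:14] <- 1L     # 5 rows x 4 cols: expand cols by 1
  r <- compute_roi(m, margin = 0)
  expect_equal(c(r$row_min, r$row_max), c(10L, 15L))
  expect_equal(c(r$col_min, r$col_max), c(10L, 15L))  # high side got +1
})

test_that("border clamping keeps the rectangle and records pre-clamp box", {
  m <- matrix(0L, 64, 64)
  m[1:4, 30:33] <- 1L        # touches row 0
  r <- compute_roi(m, margin = 20)
  expect_equal(r$row_min, 0L)
  expect_true(r$pre_clamp[1] < 0)        # would have gone past the border
  expect_equal(r$pre_clamp[2] - r$pre_clamp[1],
               r$pre_clamp[4] - r$pre_clamp[3])  # pre-clamp box is square
})

test_that("every foreground pixel keeps margin clearance unless clamped", {
  set.seed(11)
  for (i in 1:20) {
    m <- random_rect_mask(96)
    r <- compute_roi(m, margin = 12)
    fg <- which(m > 0, arr.ind = TRUE) - 1L
    expect_true(all(fg[, 1] >= r$row_min & fg[, 1] < r$row_max))
    expect_true(all(fg[, 2] >= r$col_min & fg[, 2] < r$col_max))
    if (r$row_min > 0) expect_gte(min(fg[, 1]) - r$row_min, 12)
    if (r$row_max < 96) expect_gte(r$row_max - 1 - max(fg[, 1]), 12)
  }
})

test_that("crop_and_resize honors identity, constants and label sets", {
  img <- matrix(runif(64^2), 64, 64)
  full <- roi_box(0, 64, 0, 64, source_side = 64)
  expect_equal(crop_and_resize(img, full), img)
  m <- matrix(0L, 64, 64); m[20:40, 22:38] <- 3L
  roi <- compute_roi(m, margin = 4)
  cr <- crop_and_resize(m, roi, out_side = 64, is_mask = TRUE)
  expect_true(all(unique(as.vector(cr)) %in% c(0L, 3L)))
  cimg <- matrix(0.42, 64, 64)
  expect_equal(crop_and_resize(cimg, roi, out_side = 32),
               matrix(0.42, 32, 32), tolerance = 1e-12)
  bad <- roi_box(0, 64, 0, 64, source_side = 64)
  expect_error(crop_and_resize(matrix(0, 32, 32), bad),
               class = "hemocascade_validation_error")
})

test_that("backproject inverts cropping up to resampling", {
  expect_equal(backproject(matrix(0, 64, 64),
                           roi_box(8, 40, 8, 40, 64, resized_side = 64)),
               matrix(0L, 64, 64), ignore_attr = TRUE)
  roi <- roi_box(8, 40, 10, 42, 64, resized_side = 64)
  ones <- backproject(matrix(1, 64, 64), roi, is_mask = TRUE)
  expect_equal(sum(ones), 32L * 32L)
  expect_true(all(ones[9:40, 11:42] == 1L))
  expect_error(backproject(matrix(0, 16, 16), roi),
               class = "hemocascade_validation_error")
})

test_that("crop -> backproject round-trip Dice grows with blob size", {
  set.seed(21)
  mean_dice <- function(blob) {
    d <- replicate(15, {
      m <- matrix(0L, 64, 64)
      r0 <- sample(64 - blob, 1); c0 <- sample(64 - blob, 1)
      m[r0:(r0 + blob - 1), c0:(c0 + blob - 1)] <- 1L
      roi <- compute_roi(m, margin = 10)
      back <- backproject(crop_and_resize(m, roi, is_mask = TRUE), roi,
                          is_mask = TRUE)
      dice_score(back, m)
    })
    mean(d)
  }
  d8 <- mean_dice(8); d16 <- mean_dice(16); d32 <- mean_dice(32)
  expect_gte(d8, 0.95)
  expect_gte(d16, d8 - 0.01)
  expect_gte(d32, d16 - 0.01)
})

test_that("roi boxes serialize to JSON and back", {
  m <- matrix(0L, 64, 64); m[1:6, 5:9] <- 1L
  r <- compute_roi(m, margin = 20)
  r2 <- roi_from_json(roi_to_json(r))
  expect_equal(unclass(r2), unclass(r))
})
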