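test_that("ct_series enforces its invariants", {
  sl <- list(matrix(0.5, 8, 8), matrix(0.2, 8, 8))
  s <- ct_series("p1", sl, c(0.5, 0.5), 5)
  expect_s3_class(s, "ct_series")
  expect_length(s$slices, 2)
  expect_error(ct_series("p1", list(matrix(0, 8, 8), matrix(0, 4, 4)),
                         c(0.5, 0.5), 5),
               class = "hemocascade_format_error")
  expect_error(ct_series("p1", sl, c(-1, 0.5), 5),
               class = "hemocascade_validation_error")
  expect_error(ct_series("p1", sl, c(0.5, 0.5), 0),
               class = "hemocascade_validation_error")
  expect_error(ct_series("p1", list(), c(0.5, 0.5), 5),
               class = "hemocascade_validation_error")
})

test_that("label_mask validates encodings and binary view thresholds", {
  m <- label_mask(matrix(c(0L, 3L, 5L, 0L), 2, 2), "subtype")
  expect_identical(unclass(binary_view(m))[, 1], c(0L, 1L))
  expect_error(label_mask(matrix(2L, 2, 2), "binary"),
               class = "hemocascade_validation_error")
  expect_error(label_mask(matrix(6L, 2, 2), "subtype"),
               class = "hemocascade_validation_error")
})

test_that("mask series round-trips bit-exactly through NIfTI", {
  gen <- attr(tiny_phantoms(3), "generated")
  tf <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask_series(gen$masks, gen$series, tf)
  back <- read_mask_series(tf, "subtype")
  for (k in 1:3)
    expect_identical(unclass(back[[k]]), unclass(gen$masks[[k]]))
  s2 <- read_series(tf)
  expect_lt(max(abs(s2$pixel_spacing_mm - gen$series$pixel_spacing_mm)),
            1e-6)
  expect_equal(s2$slice_thickness_mm, gen$series$slice_thickness_mm,
               tolerance = 1e-6)
  expect_error(write_mask_series(list(), gen$series, tf),
               class = "hemocascade_validation_error")
  expect_error(write_mask_series(gen$masks[1:2], gen$series, tf),
               class = "hemocascade_validation_error")
})

test_that("PNG slice directories read back with sidecar metadata", {
  d <- withr::local_tempdir()
  img <- matrix(runif(64^2), 64, 64)
  png::writePNG(img, file.path(d, "slice_000.png"))
  writeLines(jsonlite::toJSON(
    list(pixel_spacing_mm = c(0.45, 0.45), slice_thickness_mm = 5,
         patient_id = "p7"), auto_unbox = TRUE),
    file.path(d, "meta.json"))
  s <- read_series(d)
  expect_equal(s$patient_id, "p7")
  expect_length(s$slices, 1)
  # 8-bit quantization on write
  expect_lt(max(abs(s$slices[[1]] - img)), 1 / 255)
  png::writePNG(matrix(0, 32, 32), file.path(d, "slice_001.png"))
  expect_error(read_series(d), class = "hemocascade_format_error")
  expect_error(read_series(file.path(d, "nope.nii")),
               class = "hemocascade_io_error")
})

test_that("resize_to_standard uses the right resampling per content type", {
  m <- matrix(0L, 256, 256); m[100:120, 30:200] <- 1L
  up <- resize_to_standard(m, 512, is_mask = TRUE)
  expect_identical(dim(up), c(512L, 512L))
  expect_true(all(up %in% c(0L, 1L)))
  img <- matrix(0.37, 64, 64)
  expect_equal(resize_to_standard(img, 512), matrix(0.37, 512, 512),
               tolerance = 1e-12)
  ident <- matrix(runif(512^2), 512, 512)
  expect_equal(resize_to_standard(ident, 512), ident)
  expect_error(resize_to_standard(img, 0),
               class = "hemocascade_validation_error")
})

test_that("intensities outside [0,1.5] are brain-windowed on read", {
  # HU volume: values 0 (water), 40 (brain), 80 and beyond window edges
  arr <- array(c(-100, 0, 40, 80, 200, 40, 40, 40), dim = c(2, 2, 2))
  img <- RNifti::asNifti(arr, internal = FALSE)
  RNifti::pixdim(img) <- c(0.5, 0.5, 5)
  tf <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, tf)
  s <- read_series(tf)
  v <- s$slices[[1]]
  expect_equal(v[1, 1], 0)        # below window floor
  expect_equal(v[2, 1], 0)        # 0 HU -> floor
  expect_equal(v[1, 2], 0.5)      # window center
  expect_equal(v[2, 2], 1)        # window ceiling
})
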