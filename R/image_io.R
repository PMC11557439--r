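#' Core imaging containers
#'
#' `ct_series()` bundles an ordered stack of axial CT slices with its voxel
#' geometry; `label_mask()` wraps a per-pixel annotation aligned to one slice;
#' `subtype_labels()` is the fixed-order 5-way hemorrhage subtype vector
#' (alphabetical: EDH, IPH, IVH, SAH, SDH).
#'
#' @param patient_id Character scalar identifier.
#' @param slices List of equally sized numeric matrices, one per axial slice,
#'   ordered inferior to superior; order is index-stable.
#' @param pixel_spacing_mm Length-2 positive numeric, (row, col) spacing in mm.
#' @param slice_thickness_mm Positive numeric slice thickness in mm.
#' @return `ct_series()` returns an object of class `ct_series`.
#' @export
ct_series <- function(patient_id, slices, pixel_spacing_mm,
                      slice_thickness_mm) {
  if (!is.character(patient_id) || length(patient_id) != 1L)
    stop_validation("patient_id must be a single string")
  if (!is.list(slices) || length(slices) == 0L ||
      !all(vapply(slices, is.matrix, logical(1))))
    stop_validation("slices must be a nonempty list of matrices")
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_format("all slices must share identical dimensions")
  if (length(pixel_spacing_mm) != 2L || any(!is.finite(pixel_spacing_mm)) ||
      any(pixel_spacing_mm <= 0))
    stop_validation("pixel_spacing_mm must be two strictly positive reals")
  if (length(slice_thickness_mm) != 1L || !is.finite(slice_thickness_mm) ||
      slice_thickness_mm <= 0)
    stop_validation("slice_thickness_mm must be strictly positive")
  structure(
    list(patient_id = patient_id,
         slices = lapply(slices, function(s) `storage.mode<-`(s, "double")),
         pixel_spacing_mm = as.numeric(pixel_spacing_mm),
         slice_thickness_mm = as.numeric(slice_thickness_mm)),
    class = "ct_series")
}

#' @export
print.ct_series <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf(
    "ct_series '%s': %d slices of %dx%d, spacing %.3gx%.3g mm, thickness %.3g mm\n",
    x$patient_id, length(x$slices), d[1], d[2],
    x$pixel_spacing_mm[1], x$pixel_spacing_mm[2], x$slice_thickness_mm))
  invisible(x)
}

#' @rdname ct_series
#' @param pixels Integer matrix of labels, same shape as its paired slice.
#' @param encoding `"binary"` (0 background / 1 hemorrhage) or `"subtype"`
#'   (0 background, 1-5 = EDH, IPH, IVH, SAH, SDH).
#' @export
label_mask <- function(pixels, encoding = c("binary", "subtype")) {
  encoding <- match.arg(encoding)
  if (!is.matrix(pixels)) stop_validation("pixels must be a matrix")
  storage.mode(pixels) <- "integer"
  top <- if (encoding == "binary") 1L else 5L
  if (any(is.na(pixels)) || any(pixels < 0L) || any(pixels > top))
    stop_validation(sprintf("mask values must lie in 0..%d for %s encoding",
                            top, encoding))
  structure(pixels, encoding = encoding, class = c("label_mask", "matrix"))
}

#' @rdname ct_series
#' @param mask A `label_mask`.
#' @return `binary_view()` returns the mask thresholded at > 0 as a binary
#'   `label_mask`.
#' @export
binary_view <- function(mask) {
  label_mask(matrix(as.integer(unclass(mask) > 0L), nrow(mask), ncol(mask)),
             encoding = "binary")
}

# fixed label order used everywhere
SUBTYPES <- c("edh", "iph", "ivh", "sah", "sdh")

#' @rdname ct_series
#' @param edh,iph,ivh,sah,sdh Logical scalars; any combination is allowed,
#'   including all `FALSE` (no hemorrhage).
#' @export
subtype_labels <- function(edh = FALSE, iph = FALSE, ivh = FALSE,
                           sah = FALSE, sdh = FALSE) {
  v <- c(edh = isTRUE(edh), iph = isTRUE(iph), ivh = isTRUE(ivh),
         sah = isTRUE(sah), sdh = isTRUE(sdh))
  structure(v, class = "subtype_labels")
}

#' @export
print.subtype_labels <- function(x, ...) {
  pos <- toupper(SUBTYPES[unclass(x)])
  cat("subtype_labels:", if (length(pos)) paste(pos, collapse = "+")
      else "none", "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Reading and writing

brain_window <- function(x, center = 40, width = 80) {
  lo <- center - width / 2
  pmin(pmax((x - lo) / width, 0), 1)
}

read_png_slice <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  unclass(as.matrix(a))
}

#' Read a CT series from NIfTI or a PNG slice directory
#'
#' Accepts either a NIfTI volume (`.nii` / `.nii.gz`), whose voxel spacing is
#' taken from the header, or a directory of equally sized grayscale PNG slices
#' (sorted by filename) accompanied by a JSON sidecar `meta.json` of the form
#' `{"pixel_spacing_mm": [r, c], "slice_thickness_mm": t, "patient_id": s}`.
#'
#' Intensities that look like Hounsfield units (values outside `[0, 1.5]`) are
#' passed through a brain window (center 40 HU, width 80 HU) and min-max
#' scaled to `[0, 1]`; data already in `[0, 1]` (PNG, synthetic phantoms) are
#' used as-is.
#'
#' @param path Path to a NIfTI file or a slice directory.
#' @return A [ct_series].
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop_io(paste("no such file or directory:", path))
  if (dir.exists(path)) {
    pngs <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(pngs) == 0L) stop_io("directory contains no PNG slices")
    sidecar <- file.path(path, "meta.json")
    if (!file.exists(sidecar)) stop_io("missing meta.json sidecar")
    meta <- jsonlite::fromJSON(sidecar)
    slices <- lapply(pngs, read_png_slice)
    dims <- vapply(slices, dim, integer(2))
    if (any(dims != dims[, 1]))
      stop_format("PNG slices have inconsistent dimensions")
    return(ct_series(as.character(meta$patient_id %||% "unknown"), slices,
                     as.numeric(meta$pixel_spacing_mm),
                     as.numeric(meta$slice_thickness_mm)))
  }
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_io(conditionMessage(e)))
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 3L) stop_format("expected a 3D NIfTI volume")
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3L || any(pd[1:3] <= 0))
    stop_validation("nonpositive voxel spacing in NIfTI header")
  vals <- range(arr, finite = TRUE)
  if (vals[1] < -1e-6 || vals[2] > 1.5) arr <- brain_window(arr)
  slices <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
  ct_series(patient_id = basename(path), slices = slices,
            pixel_spacing_mm = pd[1:2], slice_thickness_mm = pd[3])
}

#' Write a mask stack as a NIfTI volume
#'
#' Labels are stored as 16-bit integers so that a read-back reproduces them
#' bit-exactly; spacing and thickness are copied from `meta`.
#'
#' @param masks List of [label_mask] objects, one per slice of `meta`.
#' @param meta The [ct_series] supplying geometry.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_mask_series <- function(masks, meta, path) {
  if (!is.list(masks) || length(masks) == 0L)
    stop_validation("masks must be a nonempty list")
  if (length(masks) != length(meta$slices))
    stop_validation("need exactly one mask per slice")
  arr <- array(0L, dim = c(dim(masks[[1]])[1], dim(masks[[1]])[2],
                           length(masks)))
  for (k in seq_along(masks)) arr[, , k] <- unclass(masks[[k]])
  img <- RNifti::asNifti(arr, internal = FALSE)
  RNifti::pixdim(img) <- c(meta$pixel_spacing_mm, meta$slice_thickness_mm)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Read a mask volume written by [write_mask_series()]
#'
#' @param path NIfTI path.
#' @param encoding Label encoding of the stored volume.
#' @return List of [label_mask] objects.
#' @export
read_mask_series <- function(path, encoding = c("binary", "subtype")) {
  encoding <- match.arg(encoding)
  if (!file.exists(path)) stop_io(paste("no such file:", path))
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  lapply(seq_len(dim(arr)[3]), function(k)
    label_mask(matrix(as.integer(round(arr[, , k])), dim(arr)[1], dim(arr)[2]),
               encoding = encoding))
}
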