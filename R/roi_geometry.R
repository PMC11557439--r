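# ROI production: minimal bounding square over all lesion pixels, fixed
# margin, crop-and-resize, and the inverse back-projection used at inference.
# All coordinates are row-major, 0-based, half-open [min, max).

#' Axis-aligned ROI crop window
#'
#' @param row_min,row_max,col_min,col_max Half-open 0-based pixel bounds.
#' @param source_side Side length of the originating slice.
#' @param resized_side Side length crops are resized to (defaults to
#'   `source_side`, mirroring resizing the crop back to the original size).
#' @param pre_clamp Optional length-4 integer vector recording the bounds
#'   before clamping to the image; equal to the clamped bounds away from
#'   borders, where the box is an exact square.
#' @return An object of class `roi_box`.
#' @export
roi_box <- function(row_min, row_max, col_min, col_max, source_side,
                    resized_side = source_side, pre_clamp = NULL) {
  v <- as.integer(c(row_min, row_max, col_min, col_max))
  if (any(is.na(v))) stop_validation("roi bounds must be integers")
  if (!(0L <= v[1] && v[1] < v[2] && v[2] <= source_side) ||
      !(0L <= v[3] && v[3] < v[4] && v[4] <= source_side))
    stop_validation("roi bounds must satisfy 0 <= min < max <= source_side")
  structure(
    list(row_min = v[1], row_max = v[2], col_min = v[3], col_max = v[4],
         source_side = as.integer(source_side),
         resized_side = as.integer(resized_side),
         pre_clamp = if (is.null(pre_clamp)) v else as.integer(pre_clamp)),
    class = "roi_box")
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf("roi_box rows [%d,%d) cols [%d,%d) in %dx%d (resized to %d)\n",
              x$row_min, x$row_max, x$col_min, x$col_max,
              x$source_side, x$source_side, x$resized_side))
  invisible(x)
}

#' Serialize / deserialize an ROI box for provenance logs
#' @param roi An `roi_box`.
#' @return `roi_to_json()` returns a JSON string; `roi_from_json()` inverts it.
#' @export
roi_to_json <- function(roi) {
  jsonlite::toJSON(unclass(roi), auto_unbox = TRUE)
}

#' @rdname roi_to_json
#' @param json JSON string from `roi_to_json()`.
#' @export
roi_from_json <- function(json) {
  l <- jsonlite::fromJSON(json)
  roi_box(l$row_min, l$row_max, l$col_min, l$col_max, l$source_side,
          l$resized_side, pre_clamp = l$pre_clamp)
}

#' Compute the margin-expanded bounding square of all lesion pixels
#'
#' The tight bounding box of every foreground pixel is expanded to a square
#' of side `max(height, width)` centered on the tight box (any odd leftover
#' pixel goes to the high-index side), grown by `margin` pixels on every side
#' — surrounding tissue context helps the fine segmenter — and finally
#' clamped to the image bounds. Near a border the clamped box may be
#' rectangular; both pre- and post-clamp extents are kept.
#'
#' @param mask A [label_mask] (or integer matrix) with at least one
#'   foreground (> 0) pixel.
#' @param margin Nonnegative integer margin in pixels (default 20).
#' @param resized_side Side crops will be resized to; defaults to the slice
#'   side.
#' @return An [roi_box].
#' @export
compute_roi <- function(mask, margin = 20L, resized_side = NULL) {
  m <- unclass(mask)
  if (!is.matrix(m)) stop_validation("mask must be a matrix")
  if (nrow(m) != ncol(m)) stop_validation("mask must be square")
  side <- nrow(m)
  fg <- which(m > 0L, arr.ind = TRUE)
  if (nrow(fg) == 0L) stop_empty_mask("mask contains no foreground pixels")
  margin <- as.integer(margin)
  if (margin < 0L) stop_validation("margin must be nonnegative")

  # tight box, half-open, 0-based
  r0 <- min(fg[, 1]) - 1L; r1 <- max(fg[, 1])      # [r0, r1)
  c0 <- min(fg[, 2]) - 1L; c1 <- max(fg[, 2])
  h <- r1 - r0; w <- c1 - c0
  s <- max(h, w)
  # expand the short axis symmetrically, odd leftover to the high-index side
  pad_r <- s - h; pad_c <- s - w
  r0 <- r0 - pad_r %/% 2L; r1 <- r1 + (pad_r - pad_r %/% 2L)
  c0 <- c0 - pad_c %/% 2L; c1 <- c1 + (pad_c - pad_c %/% 2L)
  # margin, then clamp
  pre <- c(r0 - margin, r1 + margin, c0 - margin, c1 + margin)
  post <- c(max(pre[1], 0L), min(pre[2], side), max(pre[3], 0L),
            min(pre[4], side))
  roi_box(post[1], post[2], post[3], post[4], source_side = side,
          resized_side = resized_side %||% side, pre_clamp = pre)
}

#' Crop an ROI out of a slice and resize it
#'
#' @param slice 2D raster (intensity image or mask).
#' @param roi An [roi_box] lying within the slice.
#' @param out_side Output side length; defaults to `roi$resized_side`.
#' @param is_mask Nearest-neighbour resampling when `TRUE`.
#' @return An `out_side` x `out_side` matrix.
#' @export
crop_and_resize <- function(slice, roi, out_side = roi$resized_side,
                            is_mask = FALSE) {
  m <- unclass(slice)
  if (roi$row_max > nrow(m) || roi$col_max > ncol(m))
    stop_validation("roi exceeds slice bounds")
  crop <- m[(roi$row_min + 1L):roi$row_max, (roi$col_min + 1L):roi$col_max,
            drop = FALSE]
  resize_to_standard(crop, out_side, is_mask = is_mask)
}

#' Back-project an ROI-space prediction into original slice coordinates
#'
#' Inverse of [crop_and_resize()]: the `resized_side` square prediction is
#' resampled to the actual (possibly clamped, rectangular) ROI extent and
#' pasted into a zero raster of the source slice size.
#'
#' @param pred `resized_side` x `resized_side` matrix (mask labels or
#'   probabilities).
#' @param roi The [roi_box] the prediction was made in.
#' @param is_mask Nearest-neighbour when `TRUE`, bilinear for probabilities.
#' @return A `source_side` x `source_side` matrix, zero outside the ROI.
#' @export
backproject <- function(pred, roi, is_mask = FALSE) {
  p <- unclass(pred)
  if (!is.matrix(p) || nrow(p) != roi$resized_side ||
      ncol(p) != roi$resized_side)
    stop_validation("prediction shape must equal roi$resized_side squared")
  h <- roi$row_max - roi$row_min
  w <- roi$col_max - roi$col_min
  filt <- if (is_mask) "none" else "bilinear"
  patch <- as_plain_matrix(EBImage::resize(`storage.mode<-`(p, "double"),
                                           w = h, h = w, filter = filt))
  if (is_mask) patch <- round(patch)
  out <- matrix(0, roi$source_side, roi$source_side)
  out[(roi$row_min + 1L):roi$row_max, (roi$col_min + 1L):roi$col_max] <- patch
  if (is_mask) storage.mode(out) <- "integer"
  out
}
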