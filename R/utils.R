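# Classed error helpers so callers can distinguish failure modes.

hc_stop <- function(msg, class) {
  stop(structure(
    class = c(paste0("hemocascade_", class), "hemocascade_error",
              "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_validation <- function(msg) hc_stop(msg, "validation_error")
stop_format     <- function(msg) hc_stop(msg, "format_error")
stop_io         <- function(msg) hc_stop(msg, "io_error")
stop_empty_mask <- function(msg) hc_stop(msg, "empty_mask_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

# EBImage returns Image objects; all package code works on plain matrices.
as_plain_matrix <- function(x) {
  m <- EBImage::imageData(x)
  dim(m) <- dim(m)[1:2]
  unclass(as.matrix(m))
}

#' Resize a 2D raster to a square standard size
#'
#' Intensity rasters are resampled bilinearly; masks use nearest-neighbour
#' resampling so that no label value absent from the input can appear in the
#' output.
#'
#' @param image Numeric or integer matrix.
#' @param out_side Positive integer side length of the square output.
#' @param is_mask Logical; `TRUE` selects nearest-neighbour resampling.
#' @return An `out_side` x `out_side` matrix (integer-valued when `is_mask`).
#' @export
resize_to_standard <- function(image, out_side, is_mask = FALSE) {
  if (!is.matrix(image) || length(image) == 0L)
    stop_validation("image must be a nonempty matrix")
  if (!is.numeric(out_side) || length(out_side) != 1L || out_side < 1)
    stop_validation("out_side must be a positive integer")
  out_side <- as.integer(out_side)
  if (nrow(image) == out_side && ncol(image) == out_side) return(image)
  filt <- if (is_mask) "none" else "bilinear"
  out <- as_plain_matrix(EBImage::resize(`storage.mode<-`(image, "double"),
                                         w = out_side, h = out_side,
                                         filter = filt))
  if (is_mask) {
    out <- round(out)
    storage.mode(out) <- "integer"
  }
  out
}

# deterministic seed streams derived from one integer seed (double
# arithmetic: products exceed integer range but stay exact below 2^53)
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %%
               2147483647)
}
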