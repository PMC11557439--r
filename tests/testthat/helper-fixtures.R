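# Shared fixtures: everything is generated in code at test time.

# small random binary mask with a filled rectangle
random_rect_mask <- function(side, min_sz = 2L, max_sz = NULL) {
  max_sz <- max_sz %||% (side %/% 2)
  h <- sample(min_sz:max_sz, 1); w <- sample(min_sz:max_sz, 1)
  r0 <- sample(seq_len(side - h), 1); c0 <- sample(seq_len(side - w), 1)
  m <- matrix(0L, side, side)
  m[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- 1L
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a tiny phantom set reused across fast tests
tiny_phantoms <- function(n = 12, seed = 7, ...) {
  phantom_slice_dataset(n, seed = seed, image_side = 64, ...)
}

# brute-force overlap scores via pixel index sets (independent oracle)
brute_dice <- function(a, b) {
  A <- which(a > 0); B <- which(b > 0)
  if (length(A) + length(B) == 0) return(1)
  2 * length(intersect(A, B)) / (length(A) + length(B))
}
brute_iou <- function(a, b) {
  A <- which(a > 0); B <- which(b > 0)
  if (length(union(A, B)) == 0) return(1)
  length(intersect(A, B)) / length(union(A, B))
}
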