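# Composition of the RcppArmadillo primitives into the two tiny trainable
# backbones: a 3-level UNet for segmentation and a 3-block CNN for
# classification. Backprop is hand-derived; a finite-difference check lives
# in the test suite. All activations are H x W x C arrays (channels last).

as_cube <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}

relu <- function(x) { x[x < 0] <- 0; x }

concat3 <- function(a, b) {
  array(c(a, b), dim = c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
}

conv_init <- function(cin, cout, rng_sd = NULL) {
  sd <- rng_sd %||% sqrt(2 / (9 * cin))   # He initialization
  list(w = matrix(rnorm(9 * cin * cout, 0, sd), 9 * cin, cout),
       b = numeric(cout))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# --- tiny UNet -------------------------------------------------------------

unet_init <- function(cin, f) {
  list(c1 = conv_init(cin, f), c2 = conv_init(f, f),
       c3 = conv_init(f, 2 * f), c4 = conv_init(2 * f, 4 * f),
       c5 = conv_init(6 * f, 2 * f), c6 = conv_init(3 * f, f),
       out = list(w = rnorm(f, 0, sqrt(1 / f)), b = 0))
}

unet_forward <- function(p, x) {
  x <- as_cube(x)
  a1 <- relu(.conv3_forward(x, p$c1$w, p$c1$b))
  a2 <- relu(.conv3_forward(a1, p$c2$w, p$c2$b))
  p1 <- .maxpool2_forward(a2)
  a3 <- relu(.conv3_forward(p1$y, p$c3$w, p$c3$b))
  p2 <- .maxpool2_forward(a3)
  a4 <- relu(.conv3_forward(p2$y, p$c4$w, p$c4$b))
  u1 <- .upsample2_forward(a4)
  k1 <- concat3(u1, a3)
  a5 <- relu(.conv3_forward(k1, p$c5$w, p$c5$b))
  u2 <- .upsample2_forward(a5)
  k2 <- concat3(u2, a2)
  a6 <- relu(.conv3_forward(k2, p$c6$w, p$c6$b))
  # 1x1 output convolution done natively in R
  z <- matrix(p$out$b, dim(a6)[1], dim(a6)[2])
  for (c in seq_along(p$out$w)) z <- z + p$out$w[c] * a6[, , c]
  list(z = z,
       cache = list(x = x, a1 = a1, a2 = a2, p1 = p1, a3 = a3, p2 = p2,
                    a4 = a4, k1 = k1, a5 = a5, k2 = k2, a6 = a6))
}

unet_backward <- function(p, cache, gz) {
  g <- list()
  a6 <- cache$a6
  f <- length(p$out$w)
  g$out <- list(w = vapply(seq_len(f), function(c) sum(gz * a6[, , c]),
                           numeric(1)),
                b = sum(gz))
  ga6 <- array(0, dim(a6))
  for (c in seq_len(f)) ga6[, , c] <- gz * p$out$w[c]
  ga6 <- ga6 * (a6 > 0)
  b6 <- .conv3_backward(cache$k2, p$c6$w, ga6)
  g$c6 <- list(w = b6$gw, b = b6$gb)
  n_u2 <- dim(cache$k2)[3] - dim(cache$a2)[3]
  gu2 <- b6$gx[, , seq_len(n_u2), drop = FALSE]
  ga2_skip <- b6$gx[, , -seq_len(n_u2), drop = FALSE]
  ga5 <- .upsample2_backward(gu2) * (cache$a5 > 0)
  b5 <- .conv3_backward(cache$k1, p$c5$w, ga5)
  g$c5 <- list(w = b5$gw, b = b5$gb)
  n_u1 <- dim(cache$k1)[3] - dim(cache$a3)[3]
  gu1 <- b5$gx[, , seq_len(n_u1), drop = FALSE]
  ga3_skip <- b5$gx[, , -seq_len(n_u1), drop = FALSE]
  ga4 <- .upsample2_backward(gu1) * (cache$a4 > 0)
  b4 <- .conv3_backward(cache$p2$y, p$c4$w, ga4)
  g$c4 <- list(w = b4$gw, b = b4$gb)
  ga3 <- (ga3_skip + .maxpool2_backward(b4$gx, cache$p2$idx,
                                        dim(cache$a3)[1],
                                        dim(cache$a3)[2])) * (cache$a3 > 0)
  b3 <- .conv3_backward(cache$p1$y, p$c3$w, ga3)
  g$c3 <- list(w = b3$gw, b = b3$gb)
  ga2 <- (ga2_skip + .maxpool2_backward(b3$gx, cache$p1$idx,
                                        dim(cache$a2)[1],
                                        dim(cache$a2)[2])) * (cache$a2 > 0)
  b2 <- .conv3_backward(cache$a1, p$c2$w, ga2)
  g$c2 <- list(w = b2$gw, b = b2$gb)
  ga1 <- b2$gx * (cache$a1 > 0)
  b1 <- .conv3_backward(cache$x, p$c1$w, ga1)
  g$c1 <- list(w = b1$gw, b = b1$gb)
  g
}

# --- tiny CNN classifier backbone ------------------------------------------

cnn_init <- function(cin, f) {
  list(c1 = conv_init(cin, f), c2 = conv_init(f, 2 * f),
       c3 = conv_init(2 * f, 4 * f))
}

cnn_forward <- function(p, x) {
  x <- as_cube(x)
  a1 <- relu(.conv3_forward(x, p$c1$w, p$c1$b)); q1 <- .maxpool2_forward(a1)
  a2 <- relu(.conv3_forward(q1$y, p$c2$w, p$c2$b)); q2 <- .maxpool2_forward(a2)
  a3 <- relu(.conv3_forward(q2$y, p$c3$w, p$c3$b)); q3 <- .maxpool2_forward(a3)
  pooled <- apply(q3$y, 3, mean)       # global average pooling
  list(pooled = pooled,
       cache = list(x = x, a1 = a1, q1 = q1, a2 = a2, q2 = q2, a3 = a3,
                    q3 = q3))
}

cnn_backward <- function(p, cache, gpooled) {
  hw <- dim(cache$q3$y)[1] * dim(cache$q3$y)[2]
  gq3 <- array(rep(gpooled / hw, each = hw), dim(cache$q3$y))
  ga3 <- .maxpool2_backward(gq3, cache$q3$idx, dim(cache$a3)[1],
                            dim(cache$a3)[2]) * (cache$a3 > 0)
  b3 <- .conv3_backward(cache$q2$y, p$c3$w, ga3)
  ga2 <- .maxpool2_backward(b3$gx, cache$q2$idx, dim(cache$a2)[1],
                            dim(cache$a2)[2]) * (cache$a2 > 0)
  b2 <- .conv3_backward(cache$q1$y, p$c2$w, ga2)
  ga1 <- .maxpool2_backward(b2$gx, cache$q1$idx, dim(cache$a1)[1],
                            dim(cache$a1)[2]) * (cache$a1 > 0)
  b1 <- .conv3_backward(cache$x, p$c1$w, ga1)
  list(c1 = list(w = b1$gw, b = b1$gb), c2 = list(w = b2$gw, b = b2$gb),
       c3 = list(w = b3$gw, b = b3$gb))
}

# --- parameter trees, Adam, cosine schedule --------------------------------

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    for (nm in names(a)) out[[nm]] <- tree_map2(f, a[[nm]], b[[nm]])
    out
  } else f(a, b)
}

tree_map <- function(f, a) {
  if (is.list(a)) { out <- a
    for (nm in names(a)) out[[nm]] <- tree_map(f, a[[nm]]); out
  } else f(a)
}

# rescale a gradient tree so its global L2 norm is at most `clip`;
# protects Adam's running moments from rare loss spikes that would
# otherwise collapse the small networks irrecoverably
clip_global_norm <- function(grads, clip) {
  sq <- 0
  walk <- function(g) {
    if (is.list(g)) lapply(g, walk) else sq <<- sq + sum(g^2)
    invisible(NULL)
  }
  walk(grads)
  nrm <- sqrt(sq)
  if (!is.finite(nrm) || nrm <= clip) {
    if (!is.finite(nrm)) return(tree_map(function(x) x * 0, grads))
    return(grads)
  }
  tree_map(function(x) x * clip / nrm, grads)
}

adam_init <- function(params) {
  list(m = tree_map(function(x) x * 0, params),
       v = tree_map(function(x) x * 0, params), t = 0L)
}

# lr may be a scalar, or a named list keyed by top-level parameter groups
# (e.g. list(head = 1e-2, .default = 1e-3)) for discriminative rates
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    lr_nm <- if (is.list(lr)) (lr[[nm]] %||% lr$.default) else lr
    upd <- tree_map2(function(m, v)
      lr_nm * (m / bc1) / (sqrt(v / bc2) + eps),
      state$m[[nm]], state$v[[nm]])
    params[[nm]] <- tree_map2(`-`, params[[nm]], upd)
  }
  list(params = params, state = state)
}

cosine_lr <- function(lr0, epoch, total, lr_min = 0) {
  lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * (epoch - 1) / max(1, total)))
}
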