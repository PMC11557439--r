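# Correctness of the hand-derived backprop against finite differences and
# a naive R convolution oracle.

hc <- asNamespace("hemocascade")

naive_conv3 <- function(x, w, b) {
  # x: H x W x Cin; w: (9*Cin) x Cout, kernel offsets row-major per channel
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]; Cout <- ncol(w)
  out <- array(0, c(H, W, Cout))
  for (co in seq_len(Cout)) {
    acc <- matrix(b[co], H, W)
    for (ci in seq_len(Cin)) {
      for (dr in -1:1) for (dc in -1:1) {
        k <- (ci - 1) * 9 + (dr + 1) * 3 + (dc + 1) + 1
        for (i in 1:H) for (j in 1:W) {
          si <- i + dr; sj <- j + dc
          if (si >= 1 && si <= H && sj >= 1 && sj <= W)
            acc[i, j] <- acc[i, j] + w[k, co] * x[si, sj, ci]
        }
      }
    }
    out[, , co] <- acc
  }
  out
}

test_that("the Rcpp convolution matches a naive R implementation", {
  set.seed(41)
  x <- array(rnorm(5 * 5 * 2), c(5, 5, 2))
  w <- matrix(rnorm(18 * 3), 18, 3)
  b <- rnorm(3)
  expect_equal(hc$.conv3_forward(x, w, b), naive_conv3(x, w, b),
               tolerance = 1e-12)
})

test_that("UNet backprop matches finite differences", {
  set.seed(42)
  p <- hc$unet_init(1L, 2L)
  x <- matrix(runif(64), 8, 8)
  t <- matrix(rbinom(64, 1, 0.3), 8, 8)
  lossf <- function(pp) {
    pr <- hc$sigmoid(hc$unet_forward(pp, x)$z)
    dice_loss(pr, t)
  }
  fw <- hc$unet_forward(p, x)
  pr <- hc$sigmoid(fw$z)
  gz <- hc$dice_loss_grad(pr, t) * pr * (1 - pr)
  g <- hc$unet_backward(p, fw$cache, gz)
  eps <- 1e-6
  base <- lossf(p)
  for (layer in c("c1", "c3", "c5", "c6")) {
    i <- sample(length(p[[layer]]$w), 1)
    p2 <- p; p2[[layer]]$w[i] <- p2[[layer]]$w[i] + eps
    expect_equal((lossf(p2) - base) / eps, g[[layer]]$w[i],
                 tolerance = 1e-3)
  }
  p2 <- p; p2$out$b <- p2$out$b + eps
  expect_equal((lossf(p2) - base) / eps, g$out$b, tolerance = 1e-3)
})

test_that("classifier backprop matches finite differences", {
  set.seed(43)
  pc <- list(bb = hc$cnn_init(1L, 2L),
             head = list(w = matrix(rnorm(8, 0, 0.3), 8, 1), b = 0))
  norm <- list(mu = rnorm(8, 0, 0.01), sd = runif(8, 0.5, 2))
  x <- matrix(runif(64), 8, 8)
  lossc <- function(pp) {
    pr <- hc$sigmoid(hc$cls_forward(pp, x, norm)$z)
    -log(pr)   # BCE with target 1
  }
  fo <- hc$cls_forward(pc, x, norm)
  pr <- hc$sigmoid(fo$z)
  gz <- matrix(pr - 1, 1, 1)
  ghead <- list(w = fo$yn %*% t(gz), b = drop(gz))
  gpooled <- drop(pc$head$w %*% gz) / norm$sd
  gb <- hc$cnn_backward(pc$bb, fo$fw$cache, gpooled)
  eps <- 1e-6
  base <- lossc(pc)
  for (layer in c("c1", "c2", "c3")) {
    i <- sample(length(pc$bb[[layer]]$w), 1)
    p2 <- pc; p2$bb[[layer]]$w[i] <- p2$bb[[layer]]$w[i] + eps
    expect_equal((lossc(p2) - base) / eps, gb[[layer]]$w[i],
                 tolerance = 1e-3)
  }
  i <- 5
  p2 <- pc; p2$head$w[i] <- p2$head$w[i] + eps
  expect_equal((lossc(p2) - base) / eps, ghead$w[i], tolerance = 1e-3)
})

test_that("focal-loss logit gradient matches finite differences", {
  set.seed(44)
  z <- rnorm(5); t5 <- c(1, 0, 1, 1, 0)
  fl <- function(z) focal_loss(hc$sigmoid(z), t5, 2, 0.25)
  ga <- hc$focal_grad_logits(hc$sigmoid(z), t5, 2, 0.25)
  eps <- 1e-7
  gn <- vapply(1:5, function(i) {
    z2 <- z; z2[i] <- z2[i] + eps; (fl(z2) - fl(z)) / eps
  }, numeric(1))
  expect_equal(ga, gn, tolerance = 1e-5)
})

test_that("pooling and upsampling are exact inverses where defined", {
  set.seed(45)
  x <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  up <- hc$.upsample2_forward(x)
  expect_equal(dim(up), c(32L, 32L, 3L))
  # nearest upsample then 2x2 max pool recovers the input exactly
  expect_equal(hc$.maxpool2_forward(up)$y, x)
  expect_equal(hc$.upsample2_backward(up), 4 * x)
})
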