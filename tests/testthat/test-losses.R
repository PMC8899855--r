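test_that("pixel-wise MSE matches hand computations", {
  expect_equal(mse_loss(c(0, 1), c(1, 1)), 0.5)
  x <- array(runif(4 * 4 * 2), c(4, 4, 2))
  expect_equal(mse_loss(x, x), 0)
  ## duplicating the batch leaves the mean unchanged
  x2 <- array(c(x, x), c(4, 4, 4))
  xh <- array(runif(4 * 4 * 2), c(4, 4, 2))
  xh2 <- array(c(xh, xh), c(4, 4, 4))
  expect_equal(mse_loss(x2, xh2), mse_loss(x, xh))
  expect_error(mse_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "dimension")
})

test_that("sparsity loss is the normalized batch-mean L1 norm", {
  s <- matrix(c(rep(1, 410), rep(0, 614)), 1024, 1)
  expect_equal(sparsity_loss(s), 0.400390625)
  expect_equal(sparsity_loss(matrix(0, 64, 3)), 0)
  expect_equal(sparsity_loss(matrix(1, 64, 3)), 1)
  ## raw mode: batch-mean L1 sum
  expect_equal(sparsity_loss(s, normalize = FALSE), 410)
  ## gradient for relaxed non-negative protocols
  g <- sparsity_loss(matrix(0.5, 4, 2), grad = TRUE)$grad
  expect_equal(g, matrix(1 / 8, 4, 2))
})

test_that("total loss is the kappa-weighted affine combination", {
  expect_equal(total_loss(0.2, 0.5, 0.4), 0.32)
  expect_equal(total_loss(0.7, 0.1, 0), 0.7)
  expect_equal(total_loss(0.7, 0.1, 1), 0.1)
  expect_error(total_loss(1, 1, 1.2), "kappa")
  ## affine in kappa: three collinear points
  ks <- c(0.1, 0.5, 0.9)
  ls <- vapply(ks, function(k) total_loss(0.3, 0.8, k), 1.0)
  expect_equal(diff(ls)[1], diff(ls)[2])
})

test_that("feature loss matches an explicit forward-pass oracle", {
  ex <- build_feature_extractor(channels = c(3L, 4L), in_channels = 1L,
                                seed = 11)
  set.seed(12)
  x <- array(runif(4 * 4), c(4, 4, 1, 1))
  xh <- array(runif(4 * 4), c(4, 4, 1, 1))
  ## independent oracle: direct dense 3x3 convolution + ReLU per stage
  conv_naive <- function(img, w, b) {
    Ci <- dim(img)[3]; Co <- dim(w)[4]
    out <- array(0, c(4, 4, Co))
    for (co in seq_len(Co)) {
      acc <- matrix(b[co], 4, 4)
      for (ci in seq_len(Ci)) for (kh in 1:3) for (kw in 1:3)
        for (r in 1:4) for (cc in 1:4) {
          ri <- r + kh - 2; ci2 <- cc + kw - 2
          if (ri >= 1 && ri <= 4 && ci2 >= 1 && ci2 <= 4)
            acc[r, cc] <- acc[r, cc] + img[ri, ci2, ci] * w[kh, kw, ci, co]
        }
      out[, , co] <- pmax(acc, 0)
    }
    out
  }
  feat <- function(img) {
    h <- array(img, c(4, 4, 1))
    for (li in seq_along(ex$net$layers))
      h <- conv_naive(h, ex$net$layers[[li]]$par$w, ex$net$layers[[li]]$par$b)
    h
  }
  f1 <- feat(x[, , 1, 1]); f2 <- feat(xh[, , 1, 1])
  K <- dim(f1)[3]
  oracle <- sum((f1 - f2)^2) / K            # N = 1
  expect_equal(feature_loss(x, xh, ex, d = 2), oracle, tolerance = 1e-10)
  expect_equal(feature_loss(x, x, ex, d = 2), 0)
  expect_error(feature_loss(x, xh, ex, d = 5), "depth")
  ## analytic gradient vs finite differences
  r <- feature_loss(x, xh, ex, d = 2, grad = TRUE)
  eps <- 1e-6
  for (i in c(2, 9)) {
    x2 <- xh; x2[i] <- x2[i] + eps
    fd <- (feature_loss(x, x2, ex, d = 2) - r$loss) / eps
    expect_equal(fd, r$grad[i], tolerance = 1e-4)
  }
})

test_that("weighted BCE matches hand values and the unweighted form", {
  expect_equal(weighted_bce_loss(0.5, 1), 0.925 * log(2))
  z <- matrix(c(1, 0, 1, 0), 2)
  p <- matrix(c(0.8, 0.2, 0.6, 0.3), 2)
  ## w = 0.5 is half the standard BCE (independent inline implementation)
  std_bce <- -mean(z * log(p) + (1 - z) * log(1 - p))
  expect_equal(weighted_bce_loss(p, z, w = 0.5), 0.5 * std_bce)
  ## perfect prediction limit under clamping
  expect_lt(weighted_bce_loss(z, z), 1e-5)
  expect_error(weighted_bce_loss(matrix(0.5, 2, 2), matrix(1, 3, 3)),
               "dimension")
  ## gradient vs finite differences at interior points
  r <- weighted_bce_loss(p, z, grad = TRUE)
  eps <- 1e-7
  for (i in 1:4) {
    p2 <- p; p2[i] <- p2[i] + eps
    fd <- (weighted_bce_loss(p2, z) - r$loss) / eps
    expect_equal(fd, r$grad[i], tolerance = 1e-4)
  }
})

test_that("spatial regularization samples targets at phosphene centres", {
  cm <- sample_custom_map(2, 64, seed = 1)
  tgt <- array(0, c(64, 64, 1))
  tgt[cm$center_row[1], cm$center_col[1], 1] <- 1
  a <- matrix(c(0.9, 0.1), 2, 1)
  expect_equal(spatial_reg_loss(a, tgt, cm), -mean(log(c(0.9, 0.9))),
               tolerance = 1e-9)
  ## activations equal to (clamped) targets give near-zero loss
  a2 <- matrix(c(1, 0), 2, 1)
  expect_lt(spatial_reg_loss(a2, tgt, cm), 0.05)
  ## any active phosphene is penalized under an all-zero target
  z0 <- array(0, c(64, 64, 1))
  expect_gt(spatial_reg_loss(matrix(c(1, 0), 2, 1), z0, cm),
            spatial_reg_loss(matrix(c(0, 0), 2, 1), z0, cm))
  expect_error(spatial_reg_loss(matrix(0.5, 3, 1), tgt, cm), "dimension")
})

test_that("all losses are non-negative and vanish at their optimum", {
  set.seed(20)
  ex <- build_feature_extractor(channels = c(2L, 3L), in_channels = 1L,
                                seed = 2)
  for (rep in 1:5) {
    x <- array(runif(6 * 6), c(6, 6, 1, 1))
    xh <- array(runif(6 * 6), c(6, 6, 1, 1))
    z <- array(rbinom(36, 1, 0.3), c(6, 6, 1, 1))
    expect_gte(mse_loss(x, xh), 0)
    expect_gte(sparsity_loss(abs(xh)), 0)
    expect_gte(feature_loss(x, xh, ex, d = 2), 0)
    expect_gte(weighted_bce_loss(pmin(pmax(xh, 0.01), 0.99), z), 0)
  }
  x <- array(runif(36), c(6, 6, 1, 1))
  expect_equal(mse_loss(x, x), 0)
  expect_equal(feature_loss(x, x, ex, d = 1), 0)
  expect_equal(sparsity_loss(array(0, c(6, 6))), 0)
})
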