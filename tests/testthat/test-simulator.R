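test_that("regular grid map construction honors jitter, gains and determinism", {
  m <- build_regular_grid_map(c(32, 32), 256, 8, seed = 42)
  expect_equal(nrow(m$centers), 1024)
  nominal <- as.matrix(expand.grid(4 + 8 * 0:31, 4 + 8 * 0:31))
  expect_true(all(abs(m$centers - nominal) <= 0.25 * 8 + 1e-12))
  expect_true(all(m$gains >= 0.5 & m$gains <= 1.5))

  m2 <- build_regular_grid_map(c(32, 32), 256, 8, seed = 42)
  expect_identical(m, m2)

  ## degenerate randomness: exact rectangular grid, unit gains
  m0 <- build_regular_grid_map(c(8, 8), 64, 8, jitter_fraction = 0,
                               gain_range = c(1, 1), seed = 1)
  expect_equal(unname(m0$centers),
               unname(as.matrix(expand.grid(4 + 8 * 0:7, 4 + 8 * 0:7))))
  expect_equal(m0$gains, rep(1, 64))

  expect_error(build_regular_grid_map(c(40, 40), 256, 8), "dimension")
  expect_error(build_regular_grid_map(gain_range = c(0, 1)), "gain_range")
})

test_that("regular simulation matches the dense convolution oracle", {
  m0 <- build_regular_grid_map(c(8, 8), 64, 8, jitter_fraction = 0,
                               gain_range = c(1, 1), seed = 1)
  p <- matrix(0, 8, 8); p[3, 5] <- 1
  s <- simulate_regular(p, m0)
  pk <- which(s[, , 1] == max(s), arr.ind = TRUE)
  e <- which(as.vector(p) == 1)
  expect_equal(unname(pk[1, ]), unname(m0$centers_px[e, ]))
  expect_equal(max(s), max(m0$kernel))

  ## full-image comparison against an independent dense convolution
  mj <- build_regular_grid_map(c(8, 8), 64, 8, seed = 7)
  set.seed(3)
  pr <- matrix(rbinom(64, 1, 0.3), 8, 8)
  dep <- matrix(0, 64, 64)
  for (i in which(as.vector(pr) == 1)) {
    px <- mj$centers_px[i, ]
    dep[px[1], px[2]] <- dep[px[1], px[2]] + mj$gains[i]
  }
  expect_equal(simulate_regular(pr, mj)[, , 1], oracle_blur(dep, mj$kernel),
               tolerance = 1e-10)

  expect_equal(max(abs(simulate_regular(matrix(0, 8, 8), m0))), 0)
  expect_error(simulate_regular(matrix(0, 4, 4), m0), "dimension")
})

test_that("simulation is linear in the protocol", {
  m <- build_regular_grid_map(c(8, 8), 64, 8, seed = 9)
  set.seed(11)
  for (rep in 1:5) {
    a <- matrix(rbinom(64, 1, 0.3), 8, 8)
    b <- matrix(rbinom(64, 1, 0.3), 8, 8) * (1 - a)   # disjoint actives
    lhs <- simulate_regular(a, m) + simulate_regular(b, m)
    rhs <- simulate_regular(a + b, m)
    expect_equal(as.vector(lhs), as.vector(rhs), tolerance = 1e-10)
  }
  ## relaxed real weights, alpha/beta scaling
  w1 <- matrix(runif(64), 8, 8); w2 <- matrix(runif(64), 8, 8)
  al <- 0.7; be <- -1.3
  lin <- simulate_regular(al * w1 + be * w2, m)
  comb <- al * simulate_regular(w1, m) + be * simulate_regular(w2, m)
  expect_equal(as.vector(lin), as.vector(comb), tolerance = 1e-5 * max(abs(comb)))
})

test_that("regular simulator gradient matches finite differences and mass", {
  m <- build_regular_grid_map(c(8, 8), 64, 8, seed = 13)
  set.seed(2)
  w0 <- matrix(runif(64), 8, 8)
  g <- array(rnorm(64 * 64), c(64, 64, 1))
  gp <- simulate_regular_grad(g, m)
  eps <- 1e-5
  for (i in c(1, 17, 36, 64)) {
    w1 <- w0; w1[i] <- w1[i] + eps
    fd <- (sum(simulate_regular(w1, m)[, , 1] * g[, , 1]) -
             sum(simulate_regular(w0, m)[, , 1] * g[, , 1])) / eps
    expect_equal(fd, gp[i], tolerance = 1e-6)
  }
  ## gradient of the total pixel sum w.r.t. a weight equals rendered mass
  ones <- array(1, c(64, 64, 1))
  gm <- simulate_regular_grad(ones, m)
  interior <- which(m$centers_px[, 1] > 8 & m$centers_px[, 1] < 57 &
                      m$centers_px[, 2] > 8 & m$centers_px[, 2] < 57)
  expect_equal(as.vector(gm)[interior], m$gains[interior], tolerance = 1e-3)
})

test_that("mean rendered peak tracks mean gain times kernel peak", {
  m <- build_regular_grid_map(c(16, 16), 128, 8, seed = 21)
  interior <- which(m$centers_px[, 1] > 8 & m$centers_px[, 1] < 121 &
                      m$centers_px[, 2] > 8 & m$centers_px[, 2] < 121)
  peaks <- vapply(interior, function(i) {
    p <- matrix(0, 16, 16); p[i] <- 1
    max(simulate_regular(p, m))
  }, 1.0)
  expect_equal(mean(peaks), mean(m$gains[interior]) * max(m$kernel),
               tolerance = 0.02)
})

test_that("custom map sampling follows the eccentricity model", {
  cm <- sample_custom_map(650, 256, seed = 5)
  expect_equal(cm$n, 650L)
  expect_equal(dim(cm$P), c(256^2, 650))
  expect_true(all(cm$phi >= pi & cm$phi <= 3 * pi / 2))
  ## Cartesian centres confined to the lower-left quadrant square
  cx <- cm$ecc * cos(cm$phi); cy <- cm$ecc * sin(cm$phi)
  expect_true(all(cx <= 0 & cx >= -1 & cy <= 0 & cy >= -1))
  ## eccentricity law and size law
  expect_equal(cm$ecc, (cm$x + 2 * cm$x^2) / 3)
  expect_equal(cm$sigma, 2 * cm$ecc + 1)
  ord <- order(cm$ecc)
  expect_true(all(diff(cm$sigma[ord]) >= 0))       # strictly with r
  ## the x = 0 limit: r = 0, sigma = 1, centre at the fixation corner
  i0 <- which.min(cm$x)
  expect_lt(cm$ecc[i0], 0.01)
  expect_lt(abs(cm$sigma[i0] - 1), 0.02)
  expect_equal(sample_custom_map(650, 256, seed = 5), cm)
  expect_error(sample_custom_map(0), "n must be")
})

test_that("custom simulation is the weighted basis sum", {
  cm <- sample_custom_map(40, 64, seed = 8)
  ## basis-selection identity
  for (i in c(1, 17, 40)) {
    w <- numeric(40); w[i] <- 1
    expect_equal(simulate_custom(w, cm)[, , 1], matrix(cm$P[, i], 64, 64))
  }
  expect_equal(max(abs(simulate_custom(numeric(40), cm))), 0)
  ## naive loop-summed oracle
  set.seed(4)
  w <- rbinom(40, 1, 0.4)
  acc <- matrix(0, 64, 64)
  for (i in seq_len(40)) acc <- acc + w[i] * matrix(cm$P[, i], 64, 64)
  expect_equal(simulate_custom(w, cm)[, , 1], acc, tolerance = 1e-12)
  ## peak-1 blobs
  expect_equal(unname(apply(as.matrix(cm$P), 2, max)), rep(1, 40))
  expect_error(simulate_custom(numeric(39), cm), "dimension")
})

test_that("custom simulator gradient matches finite differences", {
  cm <- sample_custom_map(25, 48, seed = 10)
  set.seed(6)
  w0 <- runif(25)
  g <- array(rnorm(48 * 48), c(48, 48, 1))
  gw <- simulate_custom_grad(g, cm)
  eps <- 1e-6
  for (i in c(1, 12, 25)) {
    w1 <- w0; w1[i] <- w1[i] + eps
    fd <- (sum(simulate_custom(w1, cm)[, , 1] * g[, , 1]) -
             sum(simulate_custom(w0, cm)[, , 1] * g[, , 1])) / eps
    expect_equal(fd, gw[i], tolerance = 1e-5)
  }
})

test_that("phosphene maps round-trip through the tabular format", {
  tf <- tempfile(fileext = ".tsv")
  m <- build_regular_grid_map(c(8, 8), 64, 8, seed = 3)
  write_phosphene_map(m, tf)
  m2 <- read_phosphene_map(tf)
  p <- matrix(rbinom(64, 1, 0.4), 8, 8)
  expect_equal(as.vector(simulate_regular(p, m)),
               as.vector(simulate_regular(p, m2)))

  cm <- sample_custom_map(30, 64, seed = 4)
  write_phosphene_map(cm, tf)
  cm2 <- read_phosphene_map(tf)
  w <- rbinom(30, 1, 0.5)
  expect_equal(as.vector(simulate_custom(w, cm)),
               as.vector(simulate_custom(w, cm2)))

  pf <- tempfile(fileext = ".png")
  write_image_png(simulate_regular(p, m)[, , 1], pf, rescale = TRUE)
  expect_true(file.exists(pf))
})
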