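test_that("Heaviside step with straight-through gradient", {
  expect_equal(as.vector(heaviside_ste(c(-0.3, 0.7, 0))), c(0, 1, 1))
  x <- matrix(rnorm(12), 3, 4)
  y <- heaviside_ste(x)
  expect_true(all(y %in% c(0, 1)))
  expect_equal(dim(y), dim(x))
  ## identity surrogate: upstream gradient passes through exactly
  g <- matrix(rnorm(12), 3, 4)
  expect_identical(phosphenr:::heaviside_ste_grad(x, g), g)
  ## clipped variant zeroes |x| > 1
  gc <- phosphenr:::heaviside_ste_grad(x, g, clip = TRUE)
  expect_equal(gc, g * (abs(x) <= 1))
  ## through the engine: a step output layer propagates sum-gradient as ones
  net <- phosphenr:::nn_init(list(phosphenr:::layer_fc(4L, 3L, act = "step")),
                             seed = 1)
  xm <- matrix(rnorm(8), 4, 2)
  fw <- phosphenr:::nn_forward(net, xm)
  bk <- phosphenr:::nn_backward(net, fw$caches, matrix(1, 3, 2))
  expect_equal(bk$grads[[1]]$w, xm %*% t(matrix(1, 3, 2)))
})

test_that("encoder and decoder produce the documented shape chain", {
  ## full-scale geometry: 128 -> 32 protocol -> 256 percept -> 128 output
  enc <- build_encoder(encoder_config(), seed = 1)
  dec <- build_decoder(decoder_config(), seed = 2)
  x <- array(runif(128 * 128), c(128, 128, 1, 1))
  fe <- network_forward(enc, x, train = FALSE)
  expect_equal(dim(fe$out), c(32L, 32L, 1L, 1L))
  expect_true(all(fe$out %in% c(0, 1)))
  map <- build_regular_grid_map(seed = 1)
  spv <- simulate_regular(array(fe$out, c(32, 32, 1)), map)
  expect_equal(dim(spv), c(256L, 256L, 1L))
  fd <- network_forward(dec, array(spv, c(256, 256, 1, 1)), train = FALSE)
  expect_equal(dim(fd$out), c(128L, 128L, 1L, 1L))
  expect_true(min(fd$out) > 0 && max(fd$out) < 1)
})

test_that("vector-mode encoder emits one binary activation per phosphene", {
  cfg <- encoder_config(widths = c(4, 8, 16), n_res = 2, mode = "vector",
                        n_phosphenes = 650L, input_size = 64L)
  enc <- build_encoder(cfg, seed = 3)
  x <- array(runif(64 * 64 * 2), c(64, 64, 1, 2))
  fe <- network_forward(enc, x, train = FALSE)
  expect_equal(dim(fe$out), c(650L, 2L))
  expect_true(all(fe$out %in% c(0, 1)))
  expect_error(encoder_config(mode = "vector"), "n_phosphenes")
  expect_error(encoder_config(widths = c(1, 2)), "config error")
})

test_that("degenerate weights give constant / identity behavior", {
  cfg <- tiny_encoder_cfg()
  enc <- build_encoder(cfg, seed = 4)
  for (i in seq_along(enc$layers))
    for (nm in names(enc$layers[[i]]$par))
      enc$layers[[i]]$par[[nm]][] <-
        if (nm %in% c("gamma", "gamma1", "gamma2")) 1 else 0
  x1 <- array(runif(16 * 16), c(16, 16, 1, 1))
  x2 <- array(runif(16 * 16), c(16, 16, 1, 1))
  f1 <- network_forward(enc, x1, train = FALSE)
  f2 <- network_forward(enc, x2, train = FALSE)
  expect_equal(f1$out, f2$out)            # constant output of the quantizer

  ## residual block with zeroed conv branch: out = activation(input)
  res <- phosphenr:::nn_init(list(phosphenr:::layer_res(3L)), seed = 5)
  for (nm in c("w1", "b1", "beta1", "w2", "b2", "beta2"))
    res$layers[[1]]$par[[nm]][] <- 0
  xp <- array(abs(rnorm(8 * 8 * 3 * 2)) + 0.1, c(8, 8, 3, 2))  # positive
  fr <- phosphenr:::nn_forward(res, xp, train = FALSE)
  expect_equal(fr$out, xp, tolerance = 1e-6)
})

test_that("network gradients agree with finite differences", {
  dec <- build_decoder(tiny_decoder_cfg(), seed = 6)
  x <- array(runif(8 * 8 * 1 * 3), c(8, 8, 1, 3))
  fw <- network_forward(dec, x, train = TRUE)
  set.seed(7)
  gy <- array(rnorm(length(fw$out)), dim(fw$out))
  bk <- network_backward(dec, fw$caches, gy)
  obj <- function(net) sum(network_forward(net, x, train = TRUE)$out * gy)
  base <- obj(dec)
  eps <- 1e-6
  for (li in seq_along(dec$layers)) {
    if (is.null(dec$layers[[li]]$par)) next
    for (nm in names(dec$layers[[li]]$par)) {
      net2 <- dec
      net2$layers[[li]]$par[[nm]][1] <- net2$layers[[li]]$par[[nm]][1] + eps
      fd <- (obj(net2) - base) / eps
      expect_equal(fd, bk$grads[[li]][[nm]][1], tolerance = 1e-3,
                   label = sprintf("layer %d param %s", li, nm))
    }
  }
  ## input gradient
  x2 <- x; x2[5] <- x2[5] + eps
  fd <- (sum(network_forward(dec, x2, train = TRUE)$out * gy) - base) / eps
  expect_equal(fd, bk$gx[5], tolerance = 1e-3)
})

test_that("gradients flow end to end through simulator and quantizer", {
  cfg <- tiny_train_cfg(task = "intensity", epochs = 1L, restarts = 1L)
  map <- phosphenr:::default_map_for(cfg)
  model <- phosphenr:::build_model(cfg, map)
  d <- tiny_char_data(8L, 4L)
  r <- phosphenr:::model_step(model, d$train[, , 1:8],
                              d$train[, , 1:8], train = TRUE, backward = TRUE)
  enc_norm <- sum(vapply(r$enc_grads, function(g)
    if (is.null(g)) 0 else sum(vapply(g, function(p) sum(p^2), 1.0)), 1.0))
  expect_gt(enc_norm, 0)
  dec_norm <- sum(vapply(r$dec_grads, function(g)
    if (is.null(g)) 0 else sum(vapply(g, function(p) sum(p^2), 1.0)), 1.0))
  expect_gt(dec_norm, 0)
})

test_that("checkpoints round-trip with their config", {
  cfg <- tiny_train_cfg(task = "intensity", epochs = 1L, restarts = 1L)
  map <- phosphenr:::default_map_for(cfg)
  model <- phosphenr:::build_model(cfg, map)
  tf <- tempfile(fileext = ".rds")
  save_checkpoint(model, tf)
  m2 <- load_checkpoint(tf)
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  expect_equal(network_forward(m2$encoder, x, train = FALSE)$out,
               network_forward(model$encoder, x, train = FALSE)$out)
  expect_true(file.exists(sub("\\.rds$", ".yaml", tf)))
})
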