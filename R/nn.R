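## Minimal neural-network engine: explicit forward/backward passes for the
## layer types the encoder and decoder need (3x3 convolutions with batch
## normalization and leaky rectification, 2x2 max pooling, residual blocks,
## a fully connected head, sigmoid and Heaviside/straight-through output
## activations) plus the Adam optimizer.  Tensors are base-R arrays in
## (H, W, C, N) layout; the convolution/pooling kernels live in src/.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

## Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Heaviside step activation with a straight-through gradient
#'
#' Forward pass: elementwise threshold at zero, with the boundary convention
#' that an exactly-zero pre-activation maps to 1.  Backward pass (as used by
#' the network engine): the identity surrogate, i.e. the upstream gradient is
#' passed through unchanged, which keeps gradients flowing through the binary
#' stimulation protocol during end-to-end training.
#'
#' @param x Numeric array of pre-activations.
#' @param clip If `TRUE`, the backward surrogate zeroes the gradient where
#'   `|x| > 1` (the clipped straight-through variant); the default is the
#'   plain identity surrogate.
#' @return Binary array of the same shape as `x` (values 0/1), with the
#'   surrogate choice recorded in attribute `"ste_clip"`.
#' @export
heaviside_ste <- function(x, clip = FALSE) {
  y <- (x >= 0) * 1
  if (!is.null(dim(x))) dim(y) <- dim(x)
  attr(y, "ste_clip") <- clip
  y
}

## Gradient of the straight-through surrogate.
heaviside_ste_grad <- function(x, g, clip = FALSE) {
  if (clip) g * (abs(x) <= 1) else g
}

lrelu_fwd <- function(x, slope) {
  pos <- x > 0
  x * slope + x * (1 - slope) * pos
}
lrelu_bwd <- function(x, g, slope) {
  pos <- x > 0
  g * (slope + (1 - slope) * pos)
}

sigmoid_fwd <- function(x) 1 / (1 + exp(-x))

## ---- layer constructors ----------------------------------------------------

layer_conv <- function(cin, cout, k = 3, stride = 1, pad = 1,
                       bn = TRUE, act = "lrelu") {
  list(type = "conv", cin = cin, cout = cout, k = k, stride = stride,
       pad = pad, bn = bn, act = act)
}

layer_pool <- function() list(type = "pool")

layer_res <- function(c) list(type = "res", cin = c, cout = c)

layer_flatten <- function() list(type = "flatten")

layer_fc <- function(din, dout, act = "none") {
  list(type = "fc", din = din, dout = dout, act = act)
}

## ---- parameter initialization ---------------------------------------------

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

init_conv_par <- function(cin, cout, k) {
  list(w = he_init(c(k, k, cin, cout), k * k * cin), b = numeric(cout),
       gamma = rep(1, cout), beta = numeric(cout))
}

#' @keywords internal
nn_init <- function(layers, leaky_slope = 0.01, seed = NULL) {
  build <- function() {
    for (i in seq_along(layers)) {
      l <- layers[[i]]
      if (l$type == "conv") {
        l$par <- init_conv_par(l$cin, l$cout, l$k)
        if (!l$bn) l$par$gamma <- l$par$beta <- NULL
        l$buf <- if (l$bn) list(rm = numeric(l$cout), rv = rep(1, l$cout))
      } else if (l$type == "res") {
        p1 <- init_conv_par(l$cin, l$cout, 3)
        p2 <- init_conv_par(l$cout, l$cout, 3)
        l$par <- list(w1 = p1$w, b1 = p1$b, gamma1 = p1$gamma, beta1 = p1$beta,
                      w2 = p2$w, b2 = p2$b, gamma2 = p2$gamma, beta2 = p2$beta)
        l$buf <- list(rm1 = numeric(l$cout), rv1 = rep(1, l$cout),
                      rm2 = numeric(l$cout), rv2 = rep(1, l$cout))
      } else if (l$type == "fc") {
        l$par <- list(w = he_init(c(l$din, l$dout), l$din),
                      b = numeric(l$dout))
      }
      layers[[i]] <- l
    }
    layers
  }
  layers <- if (is.null(seed)) build() else with_seed(seed, build())
  structure(list(layers = layers, leaky_slope = leaky_slope),
            class = "phr_net")
}

## ---- batch normalization ---------------------------------------------------

## x: (H, W, C, N).  Returns normalized output plus the cache needed for the
## backward pass; updates running statistics when training.
bn_fwd <- function(x, gamma, beta, rm, rv, train) {
  d <- dim(x); hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  if (train) {
    mu <- .rowMeans(.colMeans(x, hw, C * N), C, N)
    v <- .rowMeans(.colMeans(x * x, hw, C * N), C, N) - mu^2
    v <- pmax(v, 0)
  } else {
    mu <- rm; v <- rv
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  mu_b <- rep(mu, each = hw)          # recycles over N
  is_b <- rep(invstd, each = hw)
  xhat <- (x - mu_b) * is_b
  y <- xhat * rep(gamma, each = hw) + rep(beta, each = hw)
  dim(y) <- d
  upd <- NULL
  if (train) {
    m <- hw * N
    vu <- if (m > 1) v * m / (m - 1) else v   # unbiased for running var
    upd <- list(rm = (1 - BN_MOMENTUM) * rm + BN_MOMENTUM * mu,
                rv = (1 - BN_MOMENTUM) * rv + BN_MOMENTUM * vu)
  }
  list(y = y, cache = list(xhat = xhat, invstd = invstd, gamma = gamma,
                           hw = hw, C = C, N = N, train = train), upd = upd)
}

bn_bwd <- function(g, cache) {
  hw <- cache$hw; C <- cache$C; N <- cache$N
  xhat <- cache$xhat
  ## per-channel sums over (H, W, N)
  ch_sum <- function(z) .rowSums(.colSums(z, hw, C * N), C, N)
  gbeta <- ch_sum(g)
  ggamma <- ch_sum(g * xhat)
  gxhat <- g * rep(cache$gamma, each = hw)
  if (cache$train) {
    m <- hw * N
    s1 <- ch_sum(gxhat)
    s2 <- ch_sum(gxhat * xhat)
    gx <- (gxhat - rep(s1 / m, each = hw) - xhat * rep(s2 / m, each = hw)) *
      rep(cache$invstd, each = hw)
  } else {
    gx <- gxhat * rep(cache$invstd, each = hw)
  }
  dim(gx) <- dim(g)
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

## ---- forward / backward over a layer stack ---------------------------------

act_fwd <- function(x, act, slope) {
  switch(act,
         none = x,
         lrelu = lrelu_fwd(x, slope),
         sigmoid = sigmoid_fwd(x),
         step = heaviside_ste(x),
         stop("unknown activation: ", act))
}

act_bwd <- function(x, y, g, act, slope) {
  switch(act,
         none = g,
         lrelu = lrelu_bwd(x, g, slope),
         sigmoid = g * y * (1 - y),
         step = heaviside_ste_grad(x, g),
         stop("unknown activation: ", act))
}

conv_block_fwd <- function(x, w, b, stride, pad, gamma, beta, rm, rv,
                           bn, act, slope, train) {
  z <- cpp_conv2d_fwd(x, w, b, stride, pad)
  cache <- list(x = x, z = z)
  upd <- NULL
  if (bn) {
    r <- bn_fwd(z, gamma, beta, rm, rv, train)
    cache$bn <- r$cache
    cache$zn <- r$y
    upd <- r$upd
    h <- r$y
  } else h <- z
  y <- act_fwd(h, act, slope)
  cache$y <- y
  list(y = y, cache = cache, upd = upd)
}

conv_block_bwd <- function(g, cache, w, stride, pad, bn, act, slope) {
  pre <- if (bn) cache$zn else cache$z
  g <- act_bwd(pre, cache$y, g, act, slope)
  ggamma <- gbeta <- NULL
  if (bn) {
    r <- bn_bwd(g, cache$bn)
    g <- r$gx; ggamma <- r$ggamma; gbeta <- r$gbeta
  }
  r <- cpp_conv2d_bwd(cache$x, w, g, stride, pad)
  list(gx = r$gx, gw = r$gw, gb = r$gb, ggamma = ggamma, gbeta = gbeta)
}

#' @keywords internal
nn_forward <- function(net, x, train = TRUE) {
  slope <- net$leaky_slope
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$type == "conv") {
      r <- conv_block_fwd(x, l$par$w, l$par$b, l$stride, l$pad,
                          l$par$gamma, l$par$beta,
                          l$buf$rm, l$buf$rv, l$bn, l$act, slope, train)
      if (!is.null(r$upd)) net$layers[[i]]$buf <- r$upd
      caches[[i]] <- r$cache
      x <- r$y
    } else if (l$type == "pool") {
      r <- cpp_maxpool2_fwd(x)
      caches[[i]] <- list(idx = r$idx, xdim = dim(x))
      x <- r$y
    } else if (l$type == "res") {
      r1 <- conv_block_fwd(x, l$par$w1, l$par$b1, 1L, 1L, l$par$gamma1,
                           l$par$beta1, l$buf$rm1, l$buf$rv1, TRUE, "lrelu",
                           slope, train)
      r2 <- conv_block_fwd(r1$y, l$par$w2, l$par$b2, 1L, 1L, l$par$gamma2,
                           l$par$beta2, l$buf$rm2, l$buf$rv2, TRUE, "none",
                           slope, train)
      if (!is.null(r1$upd))
        net$layers[[i]]$buf[c("rm1", "rv1")] <- r1$upd[c("rm", "rv")]
      if (!is.null(r2$upd))
        net$layers[[i]]$buf[c("rm2", "rv2")] <- r2$upd[c("rm", "rv")]
      pre <- r2$y + x                         # skip added before activation
      y <- lrelu_fwd(pre, slope)
      caches[[i]] <- list(c1 = r1$cache, c2 = r2$cache, pre = pre)
      x <- y
    } else if (l$type == "flatten") {
      caches[[i]] <- list(xdim = dim(x))
      x <- matrix(x, nrow = prod(dim(x)[1:3]))
    } else if (l$type == "fc") {
      z <- crossprod(l$par$w, x) + l$par$b    # (dout, N)
      y <- act_fwd(z, l$act, slope)
      caches[[i]] <- list(x = x, z = z, y = y)
      x <- y
    }
  }
  list(out = x, caches = caches, net = net)
}

#' @keywords internal
nn_backward <- function(net, caches, g) {
  slope <- net$leaky_slope
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    cc <- caches[[i]]
    if (l$type == "conv") {
      r <- conv_block_bwd(g, cc, l$par$w, l$stride, l$pad, l$bn, l$act, slope)
      grads[[i]] <- if (l$bn)
        list(w = r$gw, b = r$gb, gamma = r$ggamma, beta = r$gbeta)
      else list(w = r$gw, b = r$gb)
      g <- r$gx
    } else if (l$type == "pool") {
      g <- cpp_maxpool2_bwd(cc$idx, g, as.integer(cc$xdim))
    } else if (l$type == "res") {
      g <- lrelu_bwd(cc$pre, g, slope)
      r2 <- conv_block_bwd(g, cc$c2, l$par$w2, 1L, 1L, TRUE, "none", slope)
      r1 <- conv_block_bwd(r2$gx, cc$c1, l$par$w1, 1L, 1L, TRUE, "lrelu", slope)
      grads[[i]] <- list(w1 = r1$gw, b1 = r1$gb, gamma1 = r1$ggamma,
                         beta1 = r1$gbeta, w2 = r2$gw, b2 = r2$gb,
                         gamma2 = r2$ggamma, beta2 = r2$gbeta)
      g <- r1$gx + g                          # skip path
    } else if (l$type == "flatten") {
      dim(g) <- cc$xdim
    } else if (l$type == "fc") {
      g <- act_bwd(cc$z, cc$y, g, l$act, slope)
      grads[[i]] <- list(w = cc$x %*% t(g), b = rowSums(g))
      g <- l$par$w %*% g
    }
  }
  list(grads = grads, gx = g)
}

## ---- parameter bookkeeping and Adam ----------------------------------------

#' Number of trainable parameters in a network
#' @param net A network built by [build_encoder()] or [build_decoder()].
#' @return Integer count of trainable scalars.
#' @export
n_trainable <- function(net) {
  if (is.null(net)) return(0L)
  sum(vapply(net$layers, function(l)
    if (is.null(l$par)) 0L else sum(vapply(l$par, length, 1L)), 1L))
}

adam_init <- function(net) {
  st <- lapply(net$layers, function(l) {
    if (is.null(l$par)) return(NULL)
    list(m = lapply(l$par, function(p) p * 0),
         v = lapply(l$par, function(p) p * 0))
  })
  list(layers = st, t = 0L)
}

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(net$layers)) {
    if (is.null(net$layers[[i]]$par)) next
    for (nm in names(net$layers[[i]]$par)) {
      gr <- grads[[i]][[nm]]
      m <- beta1 * state$layers[[i]]$m[[nm]] + (1 - beta1) * gr
      v <- beta2 * state$layers[[i]]$v[[nm]] + (1 - beta2) * gr^2
      state$layers[[i]]$m[[nm]] <- m
      state$layers[[i]]$v[[nm]] <- v
      net$layers[[i]]$par[[nm]] <- net$layers[[i]]$par[[nm]] -
        lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  list(net = net, state = state)
}
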