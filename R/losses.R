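## Training objectives: pixel-wise reconstruction (MSE), stimulation
## sparsity (L1), their kappa-weighted combination, deep-feature perceptual
## loss, class-weighted binary cross-entropy for boundary prediction, and
## the spatial regularization used with arbitrary phosphene maps.  Each loss
## can also return its analytic gradient for the training loop.

LOG_EPS <- 1e-7

#' Pixel-wise mean squared error loss
#'
#' Mean over batch and pixels of the squared intensity difference.
#'
#' @param x,x_hat Image arrays of identical shape.
#' @param grad Also return the gradient with respect to `x_hat`.
#' @return The scalar loss, or (if `grad`) a list `(loss, grad)`.
#' @export
mse_loss <- function(x, x_hat, grad = FALSE) {
  if (!identical(dim2(x), dim2(x_hat)))
    stop("dimension error: shapes differ")
  d <- x_hat - x
  loss <- mean(d * d)
  if (!grad) return(loss)
  list(loss = loss, grad = 2 * d / length(d))
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Stimulation sparsity loss (L1)
#'
#' Mean over the batch of the L1 norm of the stimulation vector.  With
#' `normalize = TRUE` (default) the per-sample norm is divided by the
#' electrode count M, so a fully active binary protocol scores 1 and the
#' kappa trade-off is scale-free; `normalize = FALSE` gives the raw
#' batch-mean L1 sum.
#'
#' @param s Protocol batch: any array whose last dimension is the batch (a
#'   vector or matrix without batch structure is one sample).
#' @param normalize Divide by the electrode count.
#' @param grad Also return the gradient with respect to `s` (for relaxed
#'   non-negative protocols the L1 derivative is 1 per element).
#' @return Scalar loss, or a list `(loss, grad)`.
#' @export
sparsity_loss <- function(s, normalize = TRUE, grad = FALSE) {
  d <- dim(s)
  N <- if (is.null(d) || length(d) < 2) 1L else d[length(d)]
  M <- length(s) / N
  denom <- if (normalize) N * M else N
  loss <- sum(abs(s)) / denom
  if (!grad) return(loss)
  g <- array(sign(s) + (s == 0), dim2(s)) / denom   # subgradient 1 at 0
  list(loss = loss, grad = g)
}

#' Total loss: kappa-weighted reconstruction/sparsity trade-off
#'
#' `(1 - kappa) * L_I + kappa * L_S`.
#'
#' @param L_I Reconstruction (task) loss.
#' @param L_S Sparsity loss.
#' @param kappa Relative sparsity weight in `[0, 1]`.
#' @return Scalar total loss.
#' @export
total_loss <- function(L_I, L_S, kappa) {
  if (kappa < 0 || kappa > 1) stop("kappa out of range [0, 1]")
  (1 - kappa) * L_I + kappa * L_S
}

#' Build a VGG-style convolutional feature extractor
#'
#' A stack of 3x3 convolution + rectification stages (max pooling after
#' every second stage), with fixed, seeded random weights.  Used by
#' [feature_loss()]; pretrained weights can be substituted by supplying any
#' extractor with the same structure.  Random deep features are a
#' well-established stand-in for pretrained perceptual features.
#'
#' @param channels Output channels of each rectified conv stage.
#' @param in_channels Extractor input channels; grayscale images are
#'   replicated to this count (3 mimics an RGB-trained backbone).
#' @param seed Weight seed.
#' @return An object of class `phr_extractor`; its maximum usable depth `d`
#'   equals `length(channels)`.
#' @export
build_feature_extractor <- function(channels = c(16L, 16L, 32L, 32L),
                                    in_channels = 3L, seed = 1L) {
  layers <- list()
  cin <- in_channels
  conv_idx <- integer(0)
  for (i in seq_along(channels)) {
    layers <- c(layers, list(layer_conv(cin, channels[i], bn = FALSE,
                                        act = "lrelu")))
    conv_idx <- c(conv_idx, length(layers))
    if (i %% 2 == 0 && i < length(channels))
      layers <- c(layers, list(layer_pool()))
    cin <- channels[i]
  }
  net <- nn_init(layers, leaky_slope = 0, seed = seed)   # slope 0 = plain ReLU
  structure(list(net = net, conv_idx = conv_idx, in_channels = in_channels,
                 channels = channels, seed = seed), class = "phr_extractor")
}

## Forward an image batch through the extractor up to rectified stage d.
extractor_forward <- function(extractor, x, d) {
  if (d < 1 || d > length(extractor$conv_idx))
    stop("depth ", d, " not available in extractor (max ",
         length(extractor$conv_idx), ")")
  if (length(dim(x)) == 3) dim(x) <- c(dim(x)[1:2], 1L, dim(x)[3])
  if (dim(x)[3] == 1 && extractor$in_channels > 1)
    x <- x[, , rep(1L, extractor$in_channels), , drop = FALSE]
  last <- extractor$conv_idx[d]
  sub <- extractor$net
  sub$layers <- sub$layers[seq_len(last)]
  r <- nn_forward(sub, x, train = FALSE)
  list(feat = r$out, caches = r$caches, sub = sub, gray_in = TRUE)
}

#' Deep-feature (perceptual) reconstruction loss
#'
#' Mean over the batch and the K feature maps at depth `d` of the squared
#' difference between the feature maps of `x` and `x_hat` (each feature map
#' difference is summed over its spatial positions).  Depth `d` counts
#' rectified convolution stages from the input.
#'
#' @param x,x_hat Image batches (grayscale; replicated to the extractor's
#'   input channels).
#' @param extractor A [build_feature_extractor()] object (or compatible).
#' @param d Feature depth (default 3).
#' @param grad Also return the gradient with respect to `x_hat`.
#' @return Scalar loss, or a list `(loss, grad)`.
#' @export
feature_loss <- function(x, x_hat, extractor, d = 3L, grad = FALSE) {
  fx <- extractor_forward(extractor, x, d)
  fh <- extractor_forward(extractor, x_hat, d)
  fd <- dim(fx$feat)
  K <- fd[3]; N <- fd[4]
  diff <- fh$feat - fx$feat
  loss <- sum(diff * diff) / (N * K)
  if (!grad) return(loss)
  gfeat <- 2 * diff / (N * K)
  r <- nn_backward(fh$sub, fh$caches, gfeat)
  gx <- r$gx
  ## collapse replicated input channels back to grayscale
  g <- array(0, c(dim(gx)[1:2], 1L, dim(gx)[4]))
  for (c in seq_len(dim(gx)[3])) g[, , 1, ] <- g[, , 1, ] + gx[, , c, ]
  list(loss = loss, grad = g)
}

#' Class-weighted binary cross-entropy loss
#'
#' `-mean(w * z * log(x_hat) + (1 - w) * (1 - z) * log(1 - x_hat))`, with
#' predictions clamped away from 0/1.  The weight `w` counterbalances the
#' scarcity of boundary pixels; the default 0.925 matches a boundary-pixel
#' fraction of 7.5% (see [boundary_class_weight()]).
#'
#' @param x_hat Predicted probabilities in (0, 1).
#' @param z Binary targets.
#' @param w Positive-class weight in (0, 1).
#' @param grad Also return the gradient with respect to `x_hat`.
#' @return Scalar loss, or a list `(loss, grad)`.
#' @export
weighted_bce_loss <- function(x_hat, z, w = 0.925, grad = FALSE) {
  if (!identical(dim2(x_hat), dim2(z)))
    stop("dimension error: shapes differ")
  p <- pmin(pmax(x_hat, LOG_EPS), 1 - LOG_EPS)
  loss <- -mean(w * z * log(p) + (1 - w) * (1 - z) * log1p(-p))
  if (!grad) return(loss)
  g <- -(w * z / p - (1 - w) * (1 - z) / (1 - p)) / length(p)
  g[x_hat <= LOG_EPS | x_hat >= 1 - LOG_EPS] <- 0
  if (!is.null(dim(x_hat))) dim(g) <- dim(x_hat)
  list(loss = loss, grad = g)
}

#' Spatial regularization loss for arbitrary phosphene maps
#'
#' Unweighted binary cross-entropy between the encoder's per-phosphene
#' activations and the training-target intensity sampled at each phosphene's
#' centre pixel.  Drives the fully connected encoder head to activate
#' phosphenes over bright target regions, restoring the spatial coherence a
#' fully connected layer does not get for free.
#'
#' @param activations `(n, N)` matrix (or length-n vector) of encoder
#'   outputs in `[0, 1]`.
#' @param target Target image batch `(H, W, N)` with values in `[0, 1]`;
#'   centre coordinates are scaled from the map canvas to `(H, W)`.
#' @param map A `phr_custom_map` (or `phr_regular_map`).
#' @param grad Also return the gradient with respect to the activations.
#' @return Scalar loss, or a list `(loss, grad)`.
#' @export
spatial_reg_loss <- function(activations, target, map, grad = FALSE) {
  a <- if (is.null(dim(activations))) matrix(activations, ncol = 1)
       else activations
  if (inherits(map, "phr_regular_map")) {
    rows <- map$centers_px[, 1]; cols <- map$centers_px[, 2]
  } else {
    rows <- map$center_row; cols <- map$center_col
  }
  n <- length(rows)
  if (nrow(a) != n)
    stop("dimension error: ", nrow(a), " activations for ", n, " phosphenes")
  td <- dim(target)
  if (length(td) == 2) { dim(target) <- c(td, 1L); td <- dim(target) }
  S <- map$canvas_size
  ri <- pmin(pmax(round((rows - 1) / (S - 1) * (td[1] - 1)) + 1, 1), td[1])
  ci <- pmin(pmax(round((cols - 1) / (S - 1) * (td[2] - 1)) + 1, 1), td[2])
  tvals <- matrix(0, n, td[3])
  flat <- matrix(target, td[1] * td[2], td[3])
  tvals[] <- flat[(ci - 1L) * td[1] + ri, ]
  ## The encoder head is binary, so activations sit exactly on 0/1; a wider
  ## clamp than LOG_EPS keeps the straight-through gradient finite and
  ## bounded instead of vanishing or exploding at the saturation points.
  eps <- 1e-2
  p <- pmin(pmax(a, eps), 1 - eps)
  loss <- -mean(tvals * log(p) + (1 - tvals) * log1p(-p))
  if (!grad) return(loss)
  g <- -(tvals / p - (1 - tvals) / (1 - p)) / length(p)
  list(loss = loss, grad = g, targets = tvals)
}

#' Boundary class weight from data
#'
#' The inverse ratio rule for the weighted cross-entropy: `w = 1 - f` where
#' `f` is the boundary-pixel fraction of the supplied maps.
#'
#' @param boundary_maps Binary array of boundary maps.
#' @return Scalar weight in (0, 1).
#' @export
boundary_class_weight <- function(boundary_maps) 1 - mean(boundary_maps)
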