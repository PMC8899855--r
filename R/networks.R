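## Encoder and decoder architectures.
##
## The encoder maps a grayscale input image to a binary stimulation protocol:
## conv(1->w1), conv+pool(w1->w2), conv+pool(w2->w3), a stack of residual
## blocks at w3 channels, conv(w3->w2), conv(w2->1, no normalization) and a
## Heaviside step output with a straight-through gradient.  Two pooling
## stages give a protocol of side input/4 (128 -> 32).  In "vector" mode the
## binary head is a fully connected layer over the flattened penultimate
## feature map, producing one activation per phosphene of an arbitrary map.
##
## The decoder maps a simulated percept back to an image: conv(1->v1),
## conv(v1->v2), conv(v2->v3, stride 2), residual blocks at v3, conv(v3->v2),
## conv(v2->1) with sigmoid output; one stride-2 stage gives output side
## input/2 (256 -> 128).

#' Encoder configuration
#'
#' @param in_channels Input image channels (1 for grayscale).
#' @param widths Channel widths of the three downsampling stages
#'   (default `c(8, 16, 32)`).
#' @param n_res Number of residual blocks (default 4).
#' @param leaky_slope Negative slope of the leaky rectifier (default 0.01).
#' @param mode `"grid"` (convolutional head, protocol = input/4 per side) or
#'   `"vector"` (fully connected head over the flattened feature map).
#' @param n_phosphenes Required in vector mode: output length.
#' @param input_size Input image side in pixels (needed to size the fully
#'   connected head in vector mode; default 128).
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(in_channels = 1L, widths = c(8L, 16L, 32L),
                           n_res = 4L, leaky_slope = 0.01,
                           mode = c("grid", "vector"), n_phosphenes = NULL,
                           input_size = 128L) {
  mode <- match.arg(mode)
  if (length(widths) != 3 || any(widths < 1))
    stop("config error: widths must be three positive integers")
  if (mode == "vector" && is.null(n_phosphenes))
    stop("config error: vector mode requires n_phosphenes")
  if (input_size %% 4 != 0)
    stop("config error: input_size must be divisible by 4")
  structure(list(in_channels = as.integer(in_channels),
                 widths = as.integer(widths), n_res = as.integer(n_res),
                 leaky_slope = leaky_slope, mode = mode,
                 n_phosphenes = if (!is.null(n_phosphenes))
                   as.integer(n_phosphenes),
                 input_size = as.integer(input_size)),
            class = "encoder_config")
}

#' Decoder configuration
#'
#' @param widths Channel widths of the three input stages
#'   (default `c(16, 32, 64)`); the third stage has stride 2.
#' @param n_res Number of residual blocks (default 4).
#' @param leaky_slope Negative slope of the leaky rectifier.
#' @return A `decoder_config` list.
#' @export
decoder_config <- function(widths = c(16L, 32L, 64L), n_res = 4L,
                           leaky_slope = 0.01) {
  if (length(widths) != 3 || any(widths < 1))
    stop("config error: widths must be three positive integers")
  structure(list(widths = as.integer(widths), n_res = as.integer(n_res),
                 leaky_slope = leaky_slope),
            class = "decoder_config")
}

#' Build a stimulation encoder
#'
#' @param config An [encoder_config()].
#' @param seed Weight-initialization seed (fan-in scaled normal draws).
#' @return A network of class `c("phr_encoder", "phr_net")`.
#' @export
build_encoder <- function(config, seed = NULL) {
  w <- config$widths
  layers <- list(layer_conv(config$in_channels, w[1]),
                 layer_conv(w[1], w[2]), layer_pool(),
                 layer_conv(w[2], w[3]), layer_pool())
  for (i in seq_len(config$n_res)) layers <- c(layers, list(layer_res(w[3])))
  layers <- c(layers, list(layer_conv(w[3], w[2])))
  if (config$mode == "grid") {
    layers <- c(layers, list(layer_conv(w[2], 1L, bn = FALSE, act = "step")))
  } else {
    feat_side <- config$input_size / 4L
    layers <- c(layers, list(layer_flatten(),
                             layer_fc(as.integer(w[2] * feat_side^2),
                                      config$n_phosphenes, act = "step")))
  }
  net <- nn_init(layers, leaky_slope = config$leaky_slope, seed = seed)
  net$config <- config
  class(net) <- c("phr_encoder", class(net))
  net
}

#' Build a reconstruction decoder
#'
#' @param config A [decoder_config()].
#' @param seed Weight-initialization seed.
#' @return A network of class `c("phr_decoder", "phr_net")`.
#' @export
build_decoder <- function(config, seed = NULL) {
  v <- config$widths
  layers <- list(layer_conv(1L, v[1]),
                 layer_conv(v[1], v[2]),
                 layer_conv(v[2], v[3], stride = 2L))
  for (i in seq_len(config$n_res)) layers <- c(layers, list(layer_res(v[3])))
  layers <- c(layers, list(layer_conv(v[3], v[2]),
                           layer_conv(v[2], 1L, bn = FALSE, act = "sigmoid")))
  net <- nn_init(layers, leaky_slope = config$leaky_slope, seed = seed)
  net$config <- config
  class(net) <- c("phr_decoder", class(net))
  net
}

#' Run a network forward
#'
#' @param net A `phr_encoder` or `phr_decoder`.
#' @param x Input array `(H, W, C, N)`; a bare matrix is treated as one
#'   single-channel image.
#' @param train Use batch statistics (and update running statistics) for
#'   batch normalization; `FALSE` uses the stored running statistics.
#' @return List with `out` (the network output), `caches` (for
#'   [network_backward()]) and `net` (with updated normalization buffers).
#' @export
network_forward <- function(net, x, train = TRUE) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  if (length(dim(x)) == 3) dim(x) <- c(dim(x)[1:2], 1L, dim(x)[3])
  nn_forward(net, x, train = train)
}

#' Backward pass through a network
#'
#' @param net The network used in the forward pass.
#' @param caches Caches returned by [network_forward()].
#' @param g Gradient of the loss with respect to the network output.
#' @return List with `grads` (per-layer parameter gradients) and `gx`
#'   (gradient with respect to the input).
#' @export
network_backward <- function(net, caches, g) nn_backward(net, caches, g)

#' Save / load a model checkpoint
#'
#' A checkpoint bundles the network configurations, weights, normalization
#' buffers and the training seed, plus a YAML sidecar with the declarative
#' config for audit.
#'
#' @param model List with at least `encoder` and `decoder` entries (a
#'   phosphene map and training config may be included).
#' @param path Checkpoint path (`.rds`); a `.yaml` sidecar is written next
#'   to it.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  cfgs <- list(encoder = unclass(model$encoder$config),
               decoder = unclass(model$decoder$config),
               seed = model$seed)
  yaml::write_yaml(cfgs, paste0(sub("\\.rds$", "", path), ".yaml"))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
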