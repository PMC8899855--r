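# Shared fixtures: tiny network configurations for fast training tests and
# independent brute-force oracles.

tiny_encoder_cfg <- function(input_size = 16L, mode = "grid", n = NULL)
  encoder_config(widths = c(2L, 4L, 8L), n_res = 1L, mode = mode,
                 n_phosphenes = n, input_size = input_size)

tiny_decoder_cfg <- function() decoder_config(widths = c(2L, 4L, 8L),
                                              n_res = 1L)

tiny_char_data <- function(n_train = 40L, n_val = 12L, seed = 5L) {
  d <- generate_character_dataset(n_train = n_train, n_val = n_val,
                                  image_size = 16L, glyph_height = 10L,
                                  seed = seed)
  list(train = d$train, val = d$val)
}

tiny_train_cfg <- function(..., seed = 5L)
  train_config(encoder = tiny_encoder_cfg(), decoder = tiny_decoder_cfg(),
               batch_size = 8L, patience = Inf, seed = seed, ...)

# Dense direct convolution of a sparse deposition image with a 2-D kernel
# (zero padding), independent of the package's convolution path.
oracle_blur <- function(img, kernel) {
  H <- nrow(img); W <- ncol(img)
  kh <- (nrow(kernel) - 1) / 2
  out <- matrix(0, H, W)
  nz <- which(img != 0, arr.ind = TRUE)
  for (p in seq_len(nrow(nz))) {
    r0 <- nz[p, 1]; c0 <- nz[p, 2]; v <- img[r0, c0]
    for (dr in -kh:kh) for (dc in -kh:kh) {
      r <- r0 + dr; c <- c0 + dc
      if (r >= 1 && r <= H && c >= 1 && c <= W)
        out[r, c] <- out[r, c] + v * kernel[dr + kh + 1, dc + kh + 1]
    }
  }
  out
}

# Brute-force all-pairs (Mann-Whitney) AUC oracle.
oracle_auc <- function(pred, z) {
  pos <- pred[z == 1]; neg <- pred[z == 0]
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}
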