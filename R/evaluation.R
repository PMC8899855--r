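## Evaluation: image-quality metrics (MSE, SSIM, PSNR, FSIM), electrode
## sparsity, ROC/AUC for boundary prediction, paired t-tests with Bonferroni
## correction, and the conventional-preprocessing baseline (Canny edges
## block-mapped onto the electrode grid).

## ---- image quality ---------------------------------------------------------

psnr_from_mse <- function(mse) ifelse(mse == 0, Inf, -10 * log10(mse))

## 2-D convolution of a single-channel matrix, "valid" or "same".
conv2_mat <- function(m, k, mode = c("valid", "same")) {
  mode <- match.arg(mode)
  pad <- if (mode == "same") (nrow(k) - 1L) %/% 2L else 0L
  x <- array(m, c(dim(m), 1L, 1L))
  w <- array(k, c(dim(k), 1L, 1L))
  y <- cpp_conv2d_fwd(x, w, 0, 1L, as.integer(pad))
  matrix(y, dim(y)[1], dim(y)[2])
}

gauss_kernel <- function(size, sigma) {
  h <- (size - 1) / 2
  g <- stats::dnorm(seq(-h, h), sd = sigma)
  k <- outer(g, g)
  k / sum(k)
}

#' Structural similarity index (SSIM)
#'
#' Standard single-scale SSIM with an 11x11 Gaussian window (sigma 1.5),
#' stability constants `C1 = (0.01 * L)^2`, `C2 = (0.03 * L)^2`, data range
#' `L = 1`.
#'
#' @param x,y Image matrices with values in [0, 1].
#' @return Mean SSIM over the valid window positions.
#' @export
ssim <- function(x, y) {
  stopifnot(identical(dim(x), dim(y)))
  C1 <- 0.01^2; C2 <- 0.03^2
  w <- gauss_kernel(11, 1.5)
  mx <- conv2_mat(x, w); my <- conv2_mat(y, w)
  sxx <- conv2_mat(x * x, w) - mx^2
  syy <- conv2_mat(y * y, w) - my^2
  sxy <- conv2_mat(x * y, w) - mx * my
  num <- (2 * mx * my + C1) * (2 * sxy + C2)
  den <- (mx^2 + my^2 + C1) * (sxx + syy + C2)
  mean(num / den)
}

## ---- FSIM ------------------------------------------------------------------
## Feature similarity index from its published formulation: phase congruency
## (log-Gabor filter bank, 4 scales x 4 orientations) combined with gradient
## magnitude (Scharr), constants T1 = 0.85 and T2 = 160 on a 0-255 intensity
## scale.

log_gabor_bank <- function(H, W, n_scale = 4, n_orient = 4,
                           min_wavelength = 6, mult = 2, sigma_onf = 0.55,
                           d_theta_sigma = 1.2) {
  fx <- ((seq_len(W) - 1) - floor(W / 2)) / W
  fy <- ((seq_len(H) - 1) - floor(H / 2)) / H
  u <- matrix(fx, H, W, byrow = TRUE)
  v <- matrix(fy, H, W)
  radius <- sqrt(u^2 + v^2)
  radius[floor(H / 2) + 1, floor(W / 2) + 1] <- 1
  theta <- atan2(-v, u)
  filters <- vector("list", n_scale * n_orient)
  k <- 1
  for (o in seq_len(n_orient)) {
    angl <- (o - 1) * pi / n_orient
    ds <- sin(theta) * cos(angl) - cos(theta) * sin(angl)
    dc <- cos(theta) * cos(angl) + sin(theta) * sin(angl)
    dtheta <- abs(atan2(ds, dc))
    spread <- exp(-dtheta^2 / (2 * (pi / n_orient * d_theta_sigma)^2))
    for (s in seq_len(n_scale)) {
      wl <- min_wavelength * mult^(s - 1)
      f0 <- 1 / wl
      lg <- exp(-(log(radius / f0))^2 / (2 * log(sigma_onf)^2))
      lg[floor(H / 2) + 1, floor(W / 2) + 1] <- 0
      filters[[k]] <- fftshift_inv(lg * spread)
      k <- k + 1
    }
  }
  list(filters = filters, n_scale = n_scale, n_orient = n_orient)
}

## undo fftshift so filters align with R's unshifted FFT layout
fftshift_inv <- function(m) {
  H <- nrow(m); W <- ncol(m)
  m[c((floor(H / 2) + 1):H, 1:floor(H / 2)),
    c((floor(W / 2) + 1):W, 1:floor(W / 2))]
}

phase_congruency <- function(img, bank) {
  H <- nrow(img); W <- ncol(img)
  IM <- stats::fft(img)
  eps <- 1e-4
  pc_sum <- matrix(0, H, W)
  k <- 1
  for (o in seq_len(bank$n_orient)) {
    sumE <- matrix(0, H, W); sumO <- matrix(0, H, W); sumA <- matrix(0, H, W)
    for (s in seq_len(bank$n_scale)) {
      resp <- stats::fft(IM * bank$filters[[k]], inverse = TRUE) / (H * W)
      e <- Re(resp); oo <- Im(resp)
      sumE <- sumE + e; sumO <- sumO + oo
      sumA <- sumA + sqrt(e^2 + oo^2)
      k <- k + 1
    }
    energy <- sqrt(sumE^2 + sumO^2)
    pc_sum <- pc_sum + energy / (sumA + eps)
  }
  pc_sum / bank$n_orient
}

scharr_gradient <- function(m) {
  kx <- matrix(c(3, 10, 3, 0, 0, 0, -3, -10, -3), 3, 3) / 16
  gx <- conv2_mat(m, kx, "same")
  gy <- conv2_mat(m, t(kx), "same")
  sqrt(gx^2 + gy^2)
}

#' Feature similarity index (FSIM)
#'
#' Combines phase-congruency similarity and gradient-magnitude similarity,
#' weighted by the maximum phase congruency at each pixel.
#'
#' @param x,y Image matrices with values in [0, 1].
#' @return FSIM score in [0, 1].
#' @export
fsim <- function(x, y) {
  stopifnot(identical(dim(x), dim(y)))
  T1 <- 0.85; T2 <- 160
  bank <- log_gabor_bank(nrow(x), ncol(x))
  pc1 <- phase_congruency(x * 255, bank)
  pc2 <- phase_congruency(y * 255, bank)
  g1 <- scharr_gradient(x * 255)
  g2 <- scharr_gradient(y * 255)
  s_pc <- (2 * pc1 * pc2 + T1) / (pc1^2 + pc2^2 + T1)
  s_g <- (2 * g1 * g2 + T2) / (g1^2 + g2^2 + T2)
  pcm <- pmax(pc1, pc2)
  sum(s_pc * s_g * pcm) / sum(pcm)
}

#' Image-quality metrics between reconstructions and references
#'
#' @param x,x_hat Matrices or `(H, W, N)` arrays with values in [0, 1].
#' @param metrics Which metrics to compute.
#' @return List with a per-image data frame (`per_image`) and a named
#'   vector of means (`mean`); a zero-error pair reports PSNR as `Inf`.
#' @export
image_metrics <- function(x, x_hat,
                          metrics = c("mse", "ssim", "psnr", "fsim")) {
  if (!identical(dim2(x), dim2(x_hat)))
    stop("dimension error: shapes differ")
  if (length(dim(x)) == 2) { dim(x) <- c(dim(x), 1L); dim(x_hat) <- dim(x) }
  N <- dim(x)[3]
  per <- data.frame(image = seq_len(N))
  for (m in metrics) per[[m]] <- NA_real_
  for (s in seq_len(N)) {
    a <- x[, , s]; b <- x_hat[, , s]
    if ("mse" %in% metrics) per$mse[s] <- mean((a - b)^2)
    if ("ssim" %in% metrics) per$ssim[s] <- ssim(a, b)
    if ("psnr" %in% metrics) per$psnr[s] <- psnr_from_mse(mean((a - b)^2))
    if ("fsim" %in% metrics) per$fsim[s] <- fsim(a, b)
  }
  list(per_image = per,
       mean = vapply(metrics, function(m) mean(per[[m]]), 1.0))
}

#' Average percentage of active electrodes
#'
#' @param protocols Binary protocol batch (any shape).
#' @return Percentage in [0, 100].
#' @export
sparsity_metric <- function(protocols) {
  if (!all(protocols %in% c(0, 1)))
    stop("protocols must be binary")
  100 * mean(protocols)
}

## ---- ROC / AUC -------------------------------------------------------------

#' ROC curve, AUC and thresholded classification metrics
#'
#' The ROC is swept over all distinct prediction values; AUC by the
#' trapezoid rule.  Point metrics (accuracy, sensitivity, specificity,
#' precision) are computed at `threshold`.
#'
#' @param predictions Numeric predictions in [0, 1].
#' @param targets Binary targets, same length/shape.
#' @param threshold Operating threshold for the point metrics (default 0.5).
#' @return List: `roc` (data frame fpr/tpr/threshold), `auc`,
#'   `accuracy`, `sensitivity`, `specificity`, `precision`, and
#'   `degenerate` (TRUE when the target has a single class, in which case
#'   `auc` is `NA`).
#' @export
roc_auc <- function(predictions, targets, threshold = 0.5) {
  p <- as.vector(predictions); z <- as.vector(targets)
  if (length(p) != length(z)) stop("dimension error: lengths differ")
  if (!all(z %in% c(0, 1))) stop("targets must be binary")
  P <- sum(z == 1); Nn <- sum(z == 0)
  pred_pos <- p >= threshold
  tp <- sum(pred_pos & z == 1); fp <- sum(pred_pos & z == 0)
  fn <- P - tp; tn <- Nn - fp
  out <- list(accuracy = (tp + tn) / length(z),
              sensitivity = if (P > 0) tp / P else NA_real_,
              specificity = if (Nn > 0) tn / Nn else NA_real_,
              precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
  if (P == 0 || Nn == 0) {
    out$degenerate <- TRUE
    out$auc <- NA_real_
    out$roc <- NULL
    warning("single-class target: AUC undefined")
    return(out)
  }
  ord <- order(p, decreasing = TRUE)
  zs <- z[ord]; ps <- p[ord]
  keep <- c(diff(ps) != 0, TRUE)          # group tied thresholds
  ctp <- cumsum(zs == 1)[keep]
  cfp <- cumsum(zs == 0)[keep]
  tpr <- c(0, ctp / P); fpr <- c(0, cfp / Nn)
  out$roc <- data.frame(threshold = c(Inf, ps[keep]), fpr = fpr, tpr = tpr)
  out$auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  out$degenerate <- FALSE
  out
}

#' Paired t-test with Bonferroni correction
#'
#' Classical paired t statistic on per-minibatch metric values, declared
#' significant at `alpha / n_comparisons`.
#'
#' @param a,b Equal-length paired metric vectors.
#' @param n_comparisons Number of comparisons in the family (default 1).
#' @param alpha Family-wise significance level (default 0.05).
#' @return List: `t`, `p`, `significant`, `alpha_adjusted`, `degenerate`
#'   (TRUE when the pairwise differences have zero variance).
#' @export
paired_ttest_bonferroni <- function(a, b, n_comparisons = 1L, alpha = 0.05) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  alpha_adj <- alpha / n_comparisons
  if (stats::sd(d) == 0) {
    ## zero-variance differences: t is 0 (identical vectors) or unbounded
    if (mean(d) == 0)
      return(list(t = 0, p = 1, significant = FALSE,
                  alpha_adjusted = alpha_adj, degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, p = NA_real_, significant = NA,
                alpha_adjusted = alpha_adj, degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       significant = tt$p.value < alpha_adj, alpha_adjusted = alpha_adj,
       degenerate = FALSE)
}

## ---- Canny baseline --------------------------------------------------------

#' Canny edge detection
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, double thresholding and hysteresis.
#'
#' @param image Grayscale matrix in [0, 1].
#' @param low,high Hysteresis thresholds on gradient magnitude (defaults
#'   0.1 / 0.2 for [0, 1] images).
#' @param sigma Smoothing sigma in pixels (default 1).
#' @return Binary edge map.
#' @export
canny_edges <- function(image, low = 0.1, high = 0.2, sigma = 1) {
  sm <- conv2_mat(image, gauss_kernel(2 * ceiling(3 * sigma) + 1, sigma),
                  "same")
  sx <- matrix(c(1, 2, 1, 0, 0, 0, -1, -2, -1), 3, 3)
  gx <- conv2_mat(sm, sx, "same")
  gy <- conv2_mat(sm, t(sx), "same")
  mag <- sqrt(gx^2 + gy^2)
  H <- nrow(mag); W <- ncol(mag)
  ang <- atan2(gy, gx) %% pi
  sector <- floor((ang + pi / 8) / (pi / 4)) %% 4   # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  pad <- matrix(0, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- mag
  at <- function(dr, dc) pad[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  n1 <- matrix(0, H, W); n2 <- matrix(0, H, W)
  ## gradient direction -> compare across the edge
  n1[sector == 0] <- at(0, 1)[sector == 0];  n2[sector == 0] <- at(0, -1)[sector == 0]
  n1[sector == 1] <- at(-1, 1)[sector == 1]; n2[sector == 1] <- at(1, -1)[sector == 1]
  n1[sector == 2] <- at(1, 0)[sector == 2];  n2[sector == 2] <- at(-1, 0)[sector == 2]
  n1[sector == 3] <- at(1, 1)[sector == 3];  n2[sector == 3] <- at(-1, -1)[sector == 3]
  thin <- mag >= n1 & mag >= n2
  strong <- thin & mag >= high
  weak <- thin & mag >= low & mag < high
  ## hysteresis: grow strong edges into 8-connected weak pixels
  repeat {
    sp <- matrix(FALSE, H + 2, W + 2)
    sp[2:(H + 1), 2:(W + 1)] <- strong
    nb <- matrix(FALSE, H, W)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nb <- nb | sp[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
    }
    add <- weak & nb & !strong
    if (!any(add)) break
    strong <- strong | add
  }
  strong * 1
}

#' Conventional-preprocessing baseline: Canny edges on the electrode grid
#'
#' Computes a Canny edge map at the image's resolution and blocks it onto
#' the electrode lattice: an electrode is active iff its image block
#' contains at least one edge pixel.  The resulting protocol feeds the
#' standard simulator; in the baseline condition only the decoder is
#' trained on these percepts.
#'
#' @param image Grayscale matrix in [0, 1].
#' @param low,high Canny hysteresis thresholds.
#' @param map A `phr_regular_map` providing the electrode lattice shape.
#' @param sigma Canny smoothing sigma.
#' @return Binary stimulation protocol matrix of shape `map$grid_shape`.
#' @export
canny_spv_baseline <- function(image, low = 0.1, high = 0.2, map,
                               sigma = 1) {
  edges <- canny_edges(image, low, high, sigma)
  gs <- map$grid_shape
  H <- nrow(edges); W <- ncol(edges)
  if (H %% gs[1] != 0 || W %% gs[2] != 0)
    stop("image size must be a multiple of the electrode grid")
  bh <- H / gs[1]; bw <- W / gs[2]
  blk <- array(edges, c(bh, gs[1], bw, gs[2]))
  proto <- apply(blk, c(2, 4), max)
  proto * 1
}
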