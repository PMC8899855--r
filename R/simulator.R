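## Differentiable phosphene simulator.
##
## Two phosphene mappings are supported:
##   * a regular (jittered) rectangular grid of equal-size phosphenes, the
##     standard simulated-prosthetic-vision setup: each active electrode
##     deposits its gain at a prespecified pixel and the result is convolved
##     with a Gaussian kernel;
##   * a custom map of n freely placed, eccentricity-dependent Gaussian blobs
##     (cortical-magnification style), where the percept is the weighted sum
##     of n precomputed basis images.
## Both are linear in the stimulation protocol, so the exact gradient is a
## fixed linear operator (constant Jacobian).

#' Build a regular (jittered) phosphene grid map
#'
#' Phosphene \code{(i, j)} (0-based) is nominally centred at
#' \code{spacing/2 + i*spacing} pixels from the top-left canvas corner.  Each
#' centre is jittered by a uniform random offset of at most
#' \code{jitter_fraction * spacing} per axis, and each phosphene receives a
#' random brightness gain.  Centres and gains are frozen at build time.
#'
#' @param grid_shape Integer 2-vector, electrode grid rows/cols (default 32x32).
#' @param canvas_size Canvas side in pixels (default 256).
#' @param spacing Phosphene spacing in pixels (default 8).
#' @param jitter_fraction Maximum centre distortion as a fraction of
#'   `spacing` per axis (default 0.25).
#' @param gain_range Length-2 numeric, uniform range of per-phosphene gains
#'   (default `c(0.5, 1.5)`).
#' @param sigma Gaussian kernel standard deviation in pixels (default 1.5).
#' @param seed Integer seed; the map is reproducible from it.
#' @return An object of class `phr_regular_map`.
#' @export
build_regular_grid_map <- function(grid_shape = c(32L, 32L),
                                   canvas_size = 256L, spacing = 8,
                                   jitter_fraction = 0.25,
                                   gain_range = c(0.5, 1.5), sigma = 1.5,
                                   seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape * spacing > canvas_size))
    stop("dimension error: grid (", grid_shape[1], "x", grid_shape[2],
         ") at spacing ", spacing, " exceeds canvas ", canvas_size)
  if (jitter_fraction < 0) stop("jitter_fraction must be >= 0")
  if (!(gain_range[1] > 0 && gain_range[1] <= gain_range[2]))
    stop("gain_range must satisfy 0 < lo <= hi")

  n <- prod(grid_shape)
  ij <- expand.grid(i = seq_len(grid_shape[1]) - 1L,
                    j = seq_len(grid_shape[2]) - 1L)
  nominal <- cbind(row = spacing / 2 + ij$i * spacing,
                   col = spacing / 2 + ij$j * spacing)
  jg <- with_seed(seed, list(
    jit = matrix(stats::runif(2 * n, -jitter_fraction, jitter_fraction) *
                   spacing, n, 2),
    gains = stats::runif(n, gain_range[1], gain_range[2])))
  centers <- nominal + jg$jit
  ## nearest-pixel deposition (0-based continuous -> 1-based pixel index)
  px <- pmin(pmax(round(centers - 0.5) + 1, 1), canvas_size)

  half <- ceiling(3 * sigma)
  g1 <- stats::dnorm(seq(-half, half), sd = sigma)
  g1 <- g1 / sum(g1)
  kernel <- outer(g1, g1)                      # sums to 1

  structure(list(grid_shape = grid_shape, canvas_size = as.integer(canvas_size),
                 spacing = spacing, jitter_fraction = jitter_fraction,
                 gain_range = gain_range, sigma = sigma, seed = seed,
                 centers = centers, centers_px = px, gains = jg$gains,
                 kernel = kernel, kernel1d = g1),
            class = "phr_regular_map")
}

## Coerce a protocol to (rows, cols, N); accepts matrix, 3-D, or (r, c, 1, N).
proto_to_3d <- function(protocol, grid_shape) {
  d <- dim(protocol)
  if (is.null(d)) stop("dimension error: protocol must be a matrix or array")
  if (length(d) == 4 && d[3] == 1) { dim(protocol) <- d[c(1, 2, 4)]; d <- dim(protocol) }
  if (length(d) == 2) { dim(protocol) <- c(d, 1L); d <- dim(protocol) }
  if (length(d) != 3 || d[1] != grid_shape[1] || d[2] != grid_shape[2])
    stop("dimension error: protocol shape does not match map grid ",
         grid_shape[1], "x", grid_shape[2])
  protocol
}

#' Simulate phosphene vision for a regular grid map
#'
#' Three steps: each electrode's value (times its gain) is deposited at its
#' prespecified pixel; the canvas is convolved with the map's Gaussian kernel.
#' The operation is linear in the protocol, hence differentiable with a
#' constant Jacobian (see [simulate_regular_grad()]).
#'
#' @param protocol Binary (or relaxed real-valued) stimulation protocol:
#'   matrix `grid_shape`, or array with a trailing batch dimension.
#' @param map A `phr_regular_map`.
#' @return A `(canvas, canvas, N)` array of simulated percepts (class
#'   `phr_spv`); single-image input yields `N = 1`.
#' @export
simulate_regular <- function(protocol, map) {
  stopifnot(inherits(map, "phr_regular_map"))
  p <- proto_to_3d(protocol, map$grid_shape)
  N <- dim(p)[3]
  S <- map$canvas_size
  idx <- (map$centers_px[, 2] - 1L) * S + map$centers_px[, 1]
  canvas <- array(0, c(S, S, N))
  for (n in seq_len(N)) {
    v <- as.vector(p[, , n]) * map$gains
    acc <- rowsum(v, idx)                    # collisions accumulate
    plane <- numeric(S * S)
    plane[as.integer(rownames(acc))] <- acc
    canvas[, , n] <- plane
  }
  out <- cpp_sepconv_same(canvas, map$kernel1d)
  structure(out, class = "phr_spv")
}

#' Gradient of [simulate_regular()] with respect to the protocol
#'
#' The simulator is linear, so the backward pass is its transpose: blur the
#' upstream gradient with the (symmetric) kernel, sample at each phosphene's
#' deposition pixel, and scale by the gain.
#'
#' @param g Upstream gradient, `(canvas, canvas, N)`.
#' @param map A `phr_regular_map`.
#' @return Gradient array of shape `(rows, cols, N)`.
#' @export
simulate_regular_grad <- function(g, map) {
  d <- dim(g)
  if (length(d) == 2) dim(g) <- c(d, 1L)
  N <- dim(g)[3]
  S <- map$canvas_size
  gb <- cpp_sepconv_same(array(g, c(S, S, N)), map$kernel1d)
  idx <- (map$centers_px[, 2] - 1L) * S + map$centers_px[, 1]
  out <- array(0, c(map$grid_shape, N))
  for (n in seq_len(N)) {
    plane <- gb[, , n]
    out[, , n] <- matrix(plane[idx] * map$gains, map$grid_shape[1])
  }
  out
}

#' Sample a custom eccentricity-dependent phosphene map
#'
#' Phosphenes live in the lower-left visual-field quadrant (the canvas covers
#' the unit square bounded by corners (0, -1) and (-1, 0), fixation at the
#' origin, i.e. the top-right canvas corner).  Polar angle
#' `phi_i ~ U(pi, 3*pi/2)`; eccentricity is drawn via `x_i ~ U(0, 1)` through
#' the cortical-magnification-style density `x + 2*x^2`, normalized by its
#' maximum (3) so that `r_i` lies in `[0, 1]`; phosphene size is
#' `sigma_i = 2*r_i + 1` pixels, so eccentric phosphenes are larger.  Each
#' basis image `P_i` is a peak-1 Gaussian blob, stored as a sparse column
#' (support truncated at 3 sigma).
#'
#' @param n Number of phosphenes (paper-scale experiments use 650, 488, 325).
#' @param canvas_size Canvas side in pixels (default 256).
#' @param seed Integer seed.
#' @return An object of class `phr_custom_map` with the sparse basis matrix
#'   `P` (`canvas^2` rows, `n` columns) and per-phosphene parameters.
#' @export
sample_custom_map <- function(n, canvas_size = 256L, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  S <- as.integer(canvas_size)
  draws <- with_seed(seed, list(phi = stats::runif(n, pi, 3 * pi / 2),
                                x = stats::runif(n)))
  ecc <- (draws$x + 2 * draws$x^2) / 3          # normalized to [0, 1]
  sigma <- 2 * ecc + 1                          # pixels
  cx <- ecc * cos(draws$phi)                    # in [-1, 0]
  cy <- ecc * sin(draws$phi)                    # in [-1, 0]
  col_px <- round((cx + 1) * (S - 1)) + 1       # x = 0 -> right edge
  row_px <- round(-cy * (S - 1)) + 1            # y = 0 -> top edge
  map <- list(n = as.integer(n), canvas_size = S, phi = draws$phi,
              x = draws$x, ecc = ecc, sigma = sigma,
              center_row = row_px, center_col = col_px, seed = seed)
  map$P <- custom_basis_matrix(row_px, col_px, sigma, S)
  structure(map, class = "phr_custom_map")
}

## Sparse (canvas^2 x n) matrix of peak-1 Gaussian blobs truncated at 3 sigma.
custom_basis_matrix <- function(row_px, col_px, sigma, S) {
  n <- length(row_px)
  ii <- vector("list", n); vv <- vector("list", n)
  for (i in seq_len(n)) {
    h <- ceiling(3 * sigma[i])
    r <- pmin(pmax((row_px[i] - h):(row_px[i] + h), 1L), S)
    r <- unique(r)
    cl <- pmin(pmax((col_px[i] - h):(col_px[i] + h), 1L), S)
    cl <- unique(cl)
    dr <- r - row_px[i]; dc <- cl - col_px[i]
    blob <- exp(-outer(dr^2, dc^2, "+") / (2 * sigma[i]^2))
    ii[[i]] <- as.vector(outer(r, (cl - 1L) * S, "+"))
    vv[[i]] <- as.vector(blob)
  }
  Matrix::sparseMatrix(i = unlist(ii),
                       j = rep.int(seq_len(n), vapply(ii, length, 1L)),
                       x = unlist(vv), dims = c(S * S, n))
}

#' Simulate phosphene vision for a custom map
#'
#' The percept is the pixel-wise weighted sum of the map's basis images,
#' `SPV = sum_i w_i P_i`; linear in the weights, so differentiable with a
#' constant Jacobian (see [simulate_custom_grad()]).
#'
#' @param weights Stimulation protocol: length-`n` vector or `(n, N)` matrix
#'   of binary (or relaxed) electrode activations.
#' @param map A `phr_custom_map`.
#' @return `(canvas, canvas, N)` array (class `phr_spv`).
#' @export
simulate_custom <- function(weights, map) {
  stopifnot(inherits(map, "phr_custom_map"))
  w <- if (is.null(dim(weights))) matrix(weights, ncol = 1) else weights
  if (nrow(w) != map$n)
    stop("dimension error: ", nrow(w), " weights for a map of ", map$n,
         " phosphenes")
  S <- map$canvas_size
  out <- array(as.matrix(map$P %*% w), c(S, S, ncol(w)))
  structure(out, class = "phr_spv")
}

#' Gradient of [simulate_custom()] with respect to the weights
#' @param g Upstream gradient, `(canvas, canvas, N)`.
#' @param map A `phr_custom_map`.
#' @return `(n, N)` gradient matrix.
#' @export
simulate_custom_grad <- function(g, map) {
  d <- dim(g)
  N <- if (length(d) == 3) d[3] else 1L
  gm <- matrix(g, nrow = map$canvas_size^2, ncol = N)
  as.matrix(Matrix::crossprod(map$P, gm))
}

## ---- serialization ---------------------------------------------------------

#' Write a phosphene map to a plain tabular file
#'
#' One row per phosphene (index, centre row/col pixel, gain, sigma) preceded
#' by a `#`-prefixed config header; readable back with
#' [read_phosphene_map()].
#'
#' @param map A `phr_regular_map` or `phr_custom_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phosphene_map <- function(map, path) {
  if (inherits(map, "phr_regular_map")) {
    hdr <- c(sprintf("# type: regular"),
             sprintf("# grid_shape: %d %d", map$grid_shape[1], map$grid_shape[2]),
             sprintf("# canvas_size: %d", map$canvas_size),
             sprintf("# spacing: %.10g", map$spacing),
             sprintf("# jitter_fraction: %.10g", map$jitter_fraction),
             sprintf("# gain_range: %.10g %.10g", map$gain_range[1],
                     map$gain_range[2]),
             sprintf("# sigma: %.10g", map$sigma),
             sprintf("# seed: %d", map$seed))
    tab <- data.frame(index = seq_len(nrow(map$centers_px)),
                      center_row_px = map$centers_px[, 1],
                      center_col_px = map$centers_px[, 2],
                      gain = map$gains, sigma_px = map$sigma)
  } else if (inherits(map, "phr_custom_map")) {
    hdr <- c("# type: custom",
             sprintf("# n: %d", map$n),
             sprintf("# canvas_size: %d", map$canvas_size),
             sprintf("# seed: %d", map$seed))
    tab <- data.frame(index = seq_len(map$n),
                      center_row_px = map$center_row,
                      center_col_px = map$center_col,
                      gain = 1, sigma_px = map$sigma)
  } else stop("not a phosphene map")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phosphene map written by [write_phosphene_map()]
#' @param path File path.
#' @return A `phr_regular_map` or `phr_custom_map`.
#' @export
read_phosphene_map <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^# %s: ", key), "",
                           grep(sprintf("^# %s:", key), hdr, value = TRUE))
  type <- get("type")
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t")
  if (type == "regular") {
    m <- build_regular_grid_map(
      grid_shape = as.integer(strsplit(get("grid_shape"), " ")[[1]]),
      canvas_size = as.integer(get("canvas_size")),
      spacing = as.numeric(get("spacing")),
      jitter_fraction = as.numeric(get("jitter_fraction")),
      gain_range = as.numeric(strsplit(get("gain_range"), " ")[[1]]),
      sigma = as.numeric(get("sigma")), seed = as.integer(get("seed")))
    ## the table is authoritative (centres were rounded to pixels on write)
    m$centers_px <- cbind(tab$center_row_px, tab$center_col_px)
    m$gains <- tab$gain
    m
  } else {
    S <- as.integer(get("canvas_size"))
    map <- list(n = nrow(tab), canvas_size = S, phi = NULL, x = NULL,
                ecc = (tab$sigma_px - 1) / 2, sigma = tab$sigma_px,
                center_row = tab$center_row_px, center_col = tab$center_col_px,
                seed = as.integer(get("seed")))
    map$P <- custom_basis_matrix(tab$center_row_px, tab$center_col_px,
                                 tab$sigma_px, S)
    structure(map, class = "phr_custom_map")
  }
}

#' Write an image (e.g. a simulated percept) as PNG
#' @param img Numeric matrix or `(H, W)` slice; values are clipped to [0, 1]
#'   unless `rescale = TRUE`, which maps the value range onto [0, 1].
#' @param path Output path.
#' @param rescale Rescale to full dynamic range before writing.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path, rescale = FALSE) {
  m <- as.matrix(img)
  if (rescale && diff(range(m)) > 0) m <- (m - min(m)) / diff(range(m))
  png::writePNG(pmin(pmax(m, 0), 1), path)
  invisible(path)
}
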