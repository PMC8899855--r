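## Synthetic datasets.
##
## * Character images: 128x128 binary images with one randomly positioned
##   lowercase letter, drawn in one of 47 "fonts".  Letters are rendered by a
##   deterministic procedural stroke renderer (segments and elliptic arcs in
##   a glyph box, stamped with a round pen); a font is a parameter set
##   (stroke width, slant, aspect, size jitter), so the dataset is fully
##   reproducible with no font files and no graphics device.
## * Labeled scenes: textured ellipses/polygons on a textured background with
##   an integer semantic label map per image, a download-free stand-in for a
##   natural-image segmentation dataset.
## * A converter from semantic label maps to binary boundary maps.

## ---- glyph geometry --------------------------------------------------------
## Coordinates in [0,1]^2, y up.  Baseline 0.25, x-height 0.65, ascender 1.0,
## descender 0.0.  seg(x1,y1,x2,y2); arc(cx,cy,rx,ry, a1,a2) in degrees CCW.

seg <- function(x1, y1, x2, y2) list(t = "s", p = c(x1, y1, x2, y2))
arc <- function(cx, cy, rx, ry, a1, a2) list(t = "a", p = c(cx, cy, rx, ry, a1, a2))

glyph_strokes <- local({
  bowl <- arc(0.45, 0.45, 0.25, 0.2, 0, 360)
  list(
    a = list(bowl, seg(0.7, 0.25, 0.7, 0.65)),
    b = list(seg(0.2, 0.25, 0.2, 1.0), arc(0.45, 0.45, 0.25, 0.2, 0, 360)),
    c = list(arc(0.45, 0.45, 0.25, 0.2, 40, 320)),
    d = list(seg(0.7, 0.25, 0.7, 1.0), bowl),
    e = list(arc(0.45, 0.45, 0.25, 0.2, -30, 300), seg(0.2, 0.45, 0.7, 0.45)),
    f = list(seg(0.45, 0.25, 0.45, 0.85), arc(0.6, 0.85, 0.15, 0.12, 90, 180),
             seg(0.25, 0.65, 0.65, 0.65)),
    g = list(bowl, seg(0.7, 0.1, 0.7, 0.65), arc(0.45, 0.1, 0.25, 0.1, 180, 360)),
    h = list(seg(0.2, 0.25, 0.2, 1.0), arc(0.45, 0.5, 0.25, 0.15, 0, 180),
             seg(0.7, 0.25, 0.7, 0.5)),
    i = list(seg(0.45, 0.25, 0.45, 0.65), seg(0.45, 0.8, 0.45, 0.82)),
    j = list(seg(0.55, 0.1, 0.55, 0.65), arc(0.4, 0.1, 0.15, 0.1, 270, 360),
             seg(0.55, 0.8, 0.55, 0.82)),
    k = list(seg(0.2, 0.25, 0.2, 1.0), seg(0.2, 0.45, 0.65, 0.65),
             seg(0.38, 0.53, 0.65, 0.25)),
    l = list(seg(0.45, 0.25, 0.45, 1.0)),
    m = list(seg(0.15, 0.25, 0.15, 0.65), arc(0.3, 0.5, 0.15, 0.15, 0, 180),
             seg(0.45, 0.25, 0.45, 0.5), arc(0.6, 0.5, 0.15, 0.15, 0, 180),
             seg(0.75, 0.25, 0.75, 0.5)),
    n = list(seg(0.2, 0.25, 0.2, 0.65), arc(0.45, 0.5, 0.25, 0.15, 0, 180),
             seg(0.7, 0.25, 0.7, 0.5)),
    o = list(bowl),
    p = list(seg(0.2, 0.0, 0.2, 0.65), arc(0.45, 0.45, 0.25, 0.2, 0, 360)),
    q = list(bowl, seg(0.7, 0.0, 0.7, 0.65)),
    r = list(seg(0.25, 0.25, 0.25, 0.65), arc(0.45, 0.42, 0.2, 0.2, 50, 180)),
    s = list(arc(0.45, 0.55, 0.2, 0.11, 20, 260),
             arc(0.45, 0.34, 0.2, 0.11, 200, 440)),
    t = list(seg(0.45, 0.35, 0.45, 0.9), seg(0.25, 0.65, 0.65, 0.65),
             arc(0.6, 0.35, 0.15, 0.1, 180, 270)),
    u = list(seg(0.2, 0.35, 0.2, 0.65), arc(0.45, 0.35, 0.25, 0.12, 180, 360),
             seg(0.7, 0.25, 0.7, 0.65)),
    v = list(seg(0.2, 0.65, 0.45, 0.25), seg(0.45, 0.25, 0.7, 0.65)),
    w = list(seg(0.15, 0.65, 0.28, 0.25), seg(0.28, 0.25, 0.45, 0.55),
             seg(0.45, 0.55, 0.62, 0.25), seg(0.62, 0.25, 0.75, 0.65)),
    x = list(seg(0.2, 0.65, 0.7, 0.25), seg(0.2, 0.25, 0.7, 0.65)),
    y = list(seg(0.2, 0.65, 0.45, 0.25), seg(0.7, 0.65, 0.3, 0.0)),
    z = list(seg(0.2, 0.65, 0.7, 0.65), seg(0.7, 0.65, 0.2, 0.25),
             seg(0.2, 0.25, 0.7, 0.25)))
})

## Deterministic style parameters for font id 1..n_fonts.
font_style <- function(font_id) {
  with_seed(97561L + font_id, list(
    stroke = stats::runif(1, 0.06, 0.16),      # pen diameter, glyph units
    slant = stats::runif(1, -0.22, 0.22),      # x-shear per unit y
    width = stats::runif(1, 0.75, 1.15),       # horizontal scale
    height = stats::runif(1, 0.88, 1.08)))     # vertical scale
}

#' Render one lowercase character as a binary bitmap
#'
#' @param char Single lowercase letter a-z.
#' @param font_id Integer style id (deterministic parameter set).
#' @param height_px Nominal glyph box height in pixels (default 48).
#' @return Binary matrix (rows x cols), 1 = ink; rows top-down.
#' @export
render_glyph <- function(char, font_id = 1L, height_px = 48L) {
  strokes <- glyph_strokes[[char]]
  if (is.null(strokes)) stop("no glyph for character: ", char)
  st <- font_style(font_id)
  H <- max(8L, round(height_px * st$height))
  W <- max(8L, round(height_px * 0.85 * st$width))
  pen <- max(1, st$stroke * height_px)
  ## sample points along every primitive
  pts <- lapply(strokes, function(sk) {
    if (sk$t == "s") {
      p <- sk$p
      len <- sqrt((p[3] - p[1])^2 + (p[4] - p[2])^2)
      tt <- seq(0, 1, length.out = max(2L, ceiling(len * H / 0.4)))
      cbind(p[1] + tt * (p[3] - p[1]), p[2] + tt * (p[4] - p[2]))
    } else {
      p <- sk$p
      aa <- seq(p[5], p[6], length.out = max(8L, ceiling(abs(p[6] - p[5]) *
                                                           max(p[3], p[4]) * H / 20)))
      aa <- aa * pi / 180
      cbind(p[1] + p[3] * cos(aa), p[2] + p[4] * sin(aa))
    }
  })
  xy <- do.call(rbind, pts)
  ## slant shear about the baseline, then scale to pixels
  xs <- xy[, 1] + st$slant * (xy[, 2] - 0.25)
  px <- (xs - min(xs)) / max(1e-9, diff(range(xs))) * (W - pen - 1) + pen / 2 + 0.5
  py <- (1 - xy[, 2]) * (H - pen - 1) + pen / 2 + 0.5   # y up -> rows down
  img <- matrix(0L, H, W)
  rad <- pen / 2
  off <- expand.grid(dr = -ceiling(rad):ceiling(rad),
                     dc = -ceiling(rad):ceiling(rad))
  off <- off[off$dr^2 + off$dc^2 <= max(rad, 0.71)^2, , drop = FALSE]
  rr <- round(py); cc <- round(px)
  for (k in seq_len(nrow(off))) {
    r <- rr + off$dr[k]; c <- cc + off$dc[k]
    ok <- r >= 1 & r <= H & c >= 1 & c <= W
    img[cbind(r[ok], c[ok])] <- 1L
  }
  img
}

#' Generate the random-character dataset
#'
#' Binary images, each containing one lowercase character at a uniformly
#' random position fully inside the canvas.  Characters and fonts are chosen
#' uniformly; the 47 font styles are split disjointly between training (38)
#' and validation (9) so the validation set probes generalization to unseen
#' letter shapes.
#'
#' @param n_train,n_val Number of training / validation images (defaults
#'   1000 and 234).
#' @param image_size Canvas side in pixels (default 128).
#' @param glyph_height Nominal glyph height in pixels (default 3/8 of the
#'   canvas side).
#' @param n_fonts Total font styles (default 47).
#' @param n_train_fonts Font styles reserved for training (default 38).
#' @param seed Integer seed; datasets are pixel-identical under the same
#'   seed.
#' @return List with `train` and `val` arrays `(H, W, N)`, and `meta`
#'   (data frame: split, char, font).
#' @export
generate_character_dataset <- function(n_train = 1000L, n_val = 234L,
                                       image_size = 128L,
                                       glyph_height = round(image_size * 3 / 8),
                                       n_fonts = 47L, n_train_fonts = 38L,
                                       seed = 1L) {
  if (n_train_fonts >= n_fonts)
    stop("need at least one validation font (n_train_fonts < n_fonts)")
  fonts_train <- seq_len(n_train_fonts)
  fonts_val <- seq(n_train_fonts + 1L, n_fonts)
  letters_lc <- names(glyph_strokes)
  gen_split <- function(n, fonts, split_seed) {
    imgs <- array(0, c(image_size, image_size, n))
    meta <- data.frame(char = character(n), font = integer(n))
    with_seed(split_seed, {
      for (s in seq_len(n)) {
        ch <- sample(letters_lc, 1)
        fo <- if (length(fonts) == 1) fonts else sample(fonts, 1)
        g <- render_glyph(ch, fo, glyph_height)
        gh <- nrow(g); gw <- ncol(g)
        if (gh > image_size || gw > image_size)
          stop("glyph larger than canvas")
        r0 <- sample.int(image_size - gh + 1L, 1)
        c0 <- sample.int(image_size - gw + 1L, 1)
        imgs[r0:(r0 + gh - 1L), c0:(c0 + gw - 1L), s] <- g
        meta$char[s] <- ch; meta$font[s] <- fo
      }
    })
    list(imgs = imgs, meta = meta)
  }
  tr <- gen_split(n_train, fonts_train, seed)
  va <- gen_split(n_val, fonts_val, seed + 1000003L)
  meta <- rbind(cbind(split = "train", tr$meta), cbind(split = "validation",
                                                       va$meta))
  list(train = tr$imgs, val = va$imgs, meta = meta,
       fonts_train = fonts_train, fonts_val = fonts_val)
}

## ---- synthetic labeled scenes ---------------------------------------------

## Low-frequency texture: coarse random grid, bilinear-upsampled.
smooth_noise <- function(size, cells, lo, hi) {
  g <- matrix(stats::runif((cells + 1)^2, lo, hi), cells + 1)
  at <- seq(1, cells + 1, length.out = size)
  i0 <- pmin(floor(at), cells); f <- at - i0
  a <- g[i0, i0]; b <- g[i0 + 1, i0]; cc <- g[i0, i0 + 1]; d <- g[i0 + 1, i0 + 1]
  fr <- matrix(f, size, size); fc <- matrix(f, size, size, byrow = TRUE)
  a * (1 - fr) * (1 - fc) + b * fr * (1 - fc) + cc * (1 - fr) * fc + d * fr * fc
}

## Geometry priors for scene objects (shared with the test-suite oracle).
SCENE_RADIUS_RANGE <- c(0.08, 0.22)   # half-axes, fraction of canvas side

#' Generate labeled synthetic scenes
#'
#' Grayscale scenes of textured ellipses and convex quadrilaterals on a
#' textured background, with an integer semantic label map per image
#' (background = 1, objects = 2, 3, ...; later objects occlude earlier
#' ones).  Object half-axes are uniform on `SCENE_RADIUS_RANGE` times the
#' canvas side; object count is uniform on `1..max_objects`.
#'
#' @param n Number of scenes.
#' @param canvas Canvas side in pixels (default 128).
#' @param max_objects Maximum objects per scene (default 4).
#' @param seed Integer seed.
#' @return List with `images` `(H, W, N)` in [0, 1] and integer `labels`
#'   of the same shape.
#' @export
generate_synthetic_scenes <- function(n, canvas = 128L, max_objects = 4L,
                                      seed = 1L) {
  if (max_objects < 0) stop("max_objects must be >= 0")
  S <- as.integer(canvas)
  imgs <- array(0, c(S, S, n))
  labs <- array(1L, c(S, S, n))
  xg <- matrix(seq_len(S), S, S)          # row coordinate
  yg <- matrix(seq_len(S), S, S, byrow = TRUE)
  with_seed(seed, {
    for (s in seq_len(n)) {
      img <- smooth_noise(S, 4, 0.05, 0.45)
      lab <- matrix(1L, S, S)
      k <- if (max_objects == 0) 0L else sample.int(max_objects, 1)
      for (o in seq_len(k)) {
        cx <- stats::runif(1, 0.15, 0.85) * S
        cy <- stats::runif(1, 0.15, 0.85) * S
        rx <- stats::runif(1, SCENE_RADIUS_RANGE[1], SCENE_RADIUS_RANGE[2]) * S
        ry <- stats::runif(1, SCENE_RADIUS_RANGE[1], SCENE_RADIUS_RANGE[2]) * S
        th <- stats::runif(1, 0, pi)
        xr <- (xg - cx) * cos(th) + (yg - cy) * sin(th)
        yr <- -(xg - cx) * sin(th) + (yg - cy) * cos(th)
        if (stats::runif(1) < 0.5) {
          inside <- (xr / rx)^2 + (yr / ry)^2 <= 1
        } else {                          # rectangle, same half-axes
          inside <- abs(xr) <= rx & abs(yr) <= ry
        }
        tex <- stats::runif(1, 0.45, 0.95) + smooth_noise(S, 6, -0.08, 0.08)
        img[inside] <- pmin(pmax(tex[inside], 0), 1)
        lab[inside] <- o + 1L
      }
      imgs[, , s] <- img
      labs[, , s] <- lab
    }
  })
  list(images = imgs, labels = labs)
}

#' Convert a semantic label map to a binary boundary map
#'
#' A pixel is a boundary pixel (value 1) iff any of its 4-neighbours carries
#' a different label; both sides of an inter-category edge are marked.
#'
#' @param label_map Integer matrix or `(H, W, N)` array of labels.
#' @return Binary map(s) of the same shape.
#' @export
labels_to_boundary_map <- function(label_map) {
  if (any(label_map != round(label_map)))
    stop("label map must be integer-valued")
  one <- function(m) {
    H <- nrow(m); W <- ncol(m)
    b <- matrix(FALSE, H, W)
    dv <- m[-1, , drop = FALSE] != m[-H, , drop = FALSE]
    b[-1, ] <- b[-1, ] | dv; b[-H, ] <- b[-H, ] | dv
    dh <- m[, -1, drop = FALSE] != m[, -W, drop = FALSE]
    b[, -1] <- b[, -1] | dh; b[, -W] <- b[, -W] | dh
    b * 1
  }
  d <- dim(label_map)
  if (length(d) == 2) return(one(label_map))
  out <- array(0, d)
  for (s in seq_len(d[3])) out[, , s] <- one(label_map[, , s])
  out
}

#' Read an image/label-map segmentation dataset from disk
#'
#' Expects parallel PNG files: `<dir>/images/*.png` (grayscale, or RGB
#' averaged to gray) and `<dir>/annotations/*.png` with integer labels
#' encoded in the red channel (ADE20k-style layout).
#'
#' @param dir Dataset directory.
#' @param size Optional side length; images are nearest-neighbour resampled
#'   to `size` x `size`.
#' @return List with `images` and `labels` arrays `(H, W, N)`.
#' @export
read_segmentation_dataset <- function(dir, size = NULL) {
  imf <- sort(list.files(file.path(dir, "images"), "\\.png$",
                         full.names = TRUE))
  laf <- sort(list.files(file.path(dir, "annotations"), "\\.png$",
                         full.names = TRUE))
  if (length(imf) == 0 || length(imf) != length(laf))
    stop("dataset layout: need matching images/ and annotations/ PNGs")
  rd <- function(f, lab) {
    a <- png::readPNG(f)
    m <- if (length(dim(a)) == 3) {
      if (lab) a[, , 1] else apply(a[, , 1:min(3, dim(a)[3])], 1:2, mean)
    } else a
    if (!is.null(size)) {
      ri <- round(seq(1, nrow(m), length.out = size))
      ci <- round(seq(1, ncol(m), length.out = size))
      m <- m[ri, ci]
    }
    if (lab) round(m * 255) else m
  }
  n <- length(imf)
  i1 <- rd(imf[1], FALSE)
  imgs <- array(0, c(nrow(i1), ncol(i1), n))
  labs <- array(0L, c(nrow(i1), ncol(i1), n))
  for (s in seq_len(n)) {
    imgs[, , s] <- rd(imf[s], FALSE)
    labs[, , s] <- rd(laf[s], TRUE)
  }
  list(images = imgs, labels = labs)
}

#' Write a generated dataset as PNG pairs plus a manifest
#'
#' @param data List with `images` (and optionally `labels` or `targets`)
#'   as `(H, W, N)` arrays.
#' @param dir Output directory (created).
#' @param split Split name recorded in the manifest.
#' @return The manifest data frame, invisibly.
#' @export
write_dataset_png <- function(data, dir, split = "train") {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  has_t <- !is.null(data$labels) || !is.null(data$targets)
  tgt <- if (!is.null(data$labels)) data$labels else data$targets
  if (has_t)
    dir.create(file.path(dir, "annotations"), recursive = TRUE,
               showWarnings = FALSE)
  n <- dim(data$images)[3]
  man <- data.frame(id = seq_len(n), split = split,
                    image = file.path("images", sprintf("%05d.png", seq_len(n))),
                    target = if (has_t)
                      file.path("annotations", sprintf("%05d.png", seq_len(n)))
                    else NA_character_)
  for (s in seq_len(n)) {
    png::writePNG(pmin(pmax(data$images[, , s], 0), 1),
                  file.path(dir, man$image[s]))
    if (has_t)
      png::writePNG(pmin(pmax(tgt[, , s] / 255, 0), 1),
                    file.path(dir, man$target[s]))
  }
  utils::write.csv(man, file.path(dir, paste0("manifest_", split, ".csv")),
                   row.names = FALSE)
  invisible(man)
}
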