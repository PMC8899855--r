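test_that("character dataset is binary, placed inside the canvas, reproducible", {
  d <- generate_character_dataset(n_train = 20, n_val = 8, image_size = 64,
                                  seed = 31)
  expect_equal(dim(d$train), c(64, 64, 20))
  expect_equal(dim(d$val), c(64, 64, 8))
  expect_true(all(d$train %in% c(0, 1)))
  expect_true(all(d$val %in% c(0, 1)))
  ## exactly one glyph per image, with sane ink coverage
  fr <- apply(d$train, 3, mean)
  expect_true(all(fr > 0.002 & fr < 0.5))
  d2 <- generate_character_dataset(n_train = 20, n_val = 8, image_size = 64,
                                   seed = 31)
  expect_identical(d$train, d2$train)
  expect_identical(d$val, d2$val)
  d3 <- generate_character_dataset(n_train = 20, n_val = 8, image_size = 64,
                                   seed = 32)
  expect_false(identical(d$train, d3$train))
})

test_that("font styles split disjointly between train and validation", {
  d <- generate_character_dataset(n_train = 30, n_val = 10, image_size = 32,
                                  glyph_height = 16, seed = 2)
  expect_length(d$fonts_train, 38)
  expect_length(d$fonts_val, 9)
  expect_length(intersect(d$fonts_train, d$fonts_val), 0)
  expect_true(all(d$meta$font[d$meta$split == "train"] %in% d$fonts_train))
  expect_true(all(d$meta$font[d$meta$split == "validation"] %in% d$fonts_val))
  expect_error(generate_character_dataset(5, 5, n_fonts = 10,
                                          n_train_fonts = 10),
               "validation font")
  ## the default validation count reproduces the standard evaluation size
  expect_equal(formals(generate_character_dataset)$n_val, 234L)
})

test_that("glyph renderer produces distinct deterministic letters", {
  g1 <- render_glyph("a", 3, 24)
  g2 <- render_glyph("a", 3, 24)
  expect_identical(g1, g2)
  expect_true(all(g1 %in% c(0L, 1L)))
  ## different letters differ, different fonts differ
  gb <- render_glyph("b", 3, 24)
  expect_false(isTRUE(all.equal(dim(g1), dim(gb))) &&
                 identical(g1, gb))
  ga7 <- render_glyph("a", 7, 24)
  expect_false(identical(dim(g1), dim(ga7)) && identical(g1, ga7))
  expect_error(render_glyph("A", 1), "no glyph")
})

test_that("synthetic scenes carry consistent label maps", {
  sc <- generate_synthetic_scenes(12, canvas = 48, max_objects = 4, seed = 9)
  expect_equal(dim(sc$images), c(48, 48, 12))
  expect_true(all(sc$images >= 0 & sc$images <= 1))
  nlab <- apply(sc$labels, 3, function(m) length(unique(as.vector(m))))
  expect_true(all(nlab >= 1 & nlab <= 5))        # background + <= max_objects
  ## background-only scenes have a constant label map
  s0 <- generate_synthetic_scenes(3, canvas = 32, max_objects = 0, seed = 1)
  expect_true(all(apply(s0$labels, 3, function(m) all(m == m[1]))))
  expect_identical(generate_synthetic_scenes(12, 48, 4, seed = 9)$images,
                   sc$images)
})

test_that("object coverage matches the generator's geometry priors", {
  ## single-object scenes; oracle = Monte-Carlo expectation of the object
  ## area under the documented priors (half ellipse pi*rx*ry, half rectangle
  ## 4*rx*ry, half-axes uniform on SCENE_RADIUS_RANGE of the canvas side)
  sc <- generate_synthetic_scenes(300, canvas = 48, max_objects = 1, seed = 77)
  obj_frac <- mean(sc$labels > 1)
  rr <- phosphenr:::SCENE_RADIUS_RANGE
  set.seed(78)
  rx <- runif(20000, rr[1], rr[2]); ry <- runif(20000, rr[1], rr[2])
  shape_area <- ifelse(runif(20000) < 0.5, pi, 4) * rx * ry
  expected <- mean(shape_area)
  ## border clipping and rasterization shave a little area off
  expect_gt(obj_frac, 0.7 * expected)
  expect_lt(obj_frac, 1.1 * expected)
})

test_that("label-to-boundary conversion marks 4-neighbour label changes", {
  ## uniform map: no boundary
  expect_equal(labels_to_boundary_map(matrix(3L, 5, 5)), matrix(0, 5, 5))
  ## two vertical halves: the two middle columns
  m <- matrix(rep(c(1, 1, 2, 2), each = 4), 4, 4)
  b <- labels_to_boundary_map(m)
  expect_equal(b, cbind(0, 1, 1, 0)[rep(1, 4), ])
  ## random maps vs a brute-force neighbourhood oracle
  set.seed(41)
  for (rep in 1:4) {
    lm <- matrix(sample(1:3, 36, replace = TRUE), 6, 6)
    oracle <- matrix(0, 6, 6)
    for (r in 1:6) for (cc in 1:6)
      for (dd in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r2 <- r + dd[1]; c2 <- cc + dd[2]
        if (r2 >= 1 && r2 <= 6 && c2 >= 1 && c2 <= 6 &&
            lm[r2, c2] != lm[r, cc]) oracle[r, cc] <- 1
      }
    expect_equal(labels_to_boundary_map(lm), oracle)
  }
  ## applying the operator to its own (binary) output stays well-defined
  bb <- labels_to_boundary_map(labels_to_boundary_map(m))
  expect_true(all(bb %in% c(0, 1)))
  expect_error(labels_to_boundary_map(matrix(1.5, 2, 2)), "integer")
})

test_that("boundary class weight follows the inverse-ratio rule", {
  bm <- array(0, c(10, 10, 2)); bm[1:3, , 1] <- 1
  expect_equal(boundary_class_weight(bm), 1 - mean(bm))
  ## scene-derived weight lands near the canonical 0.925 regime
  sc <- generate_synthetic_scenes(40, canvas = 64, seed = 13)
  w <- boundary_class_weight(labels_to_boundary_map(sc$labels))
  expect_gt(w, 0.85); expect_lt(w, 0.99)
})

test_that("datasets round-trip through PNG pairs and a manifest", {
  sc <- generate_synthetic_scenes(3, canvas = 24, seed = 5)
  dir <- tempfile("ds")
  man <- write_dataset_png(sc, dir, split = "train")
  expect_equal(nrow(man), 3)
  expect_true(all(file.exists(file.path(dir, man$image))))
  expect_true(all(file.exists(file.path(dir, man$target))))
  rd <- read_segmentation_dataset(dir)
  expect_equal(dim(rd$images), dim(sc$images))
  expect_equal(rd$labels[, , 1], sc$labels[, , 1])
  ## 8-bit PNG quantization bounds the absolute error by half a level
  expect_lt(max(abs(rd$images[, , 2] - sc$images[, , 2])), 1 / 255)
})
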