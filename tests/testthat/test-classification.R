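make_scene <- function(px) {
  # px: list of RGB triples laid out on a tiny 2 x 2 raster
  b <- array(0, c(2, 2, 3))
  for (k in seq_along(px)) {
    i <- (k - 1) %% 2 + 1; j <- (k - 1) %/% 2 + 1
    b[i, j, ] <- px[[k]]
  }
  rgb_scene(b, 0.01)
}

test_that("yellow rule applies the strict RGB thresholds", {
  sc <- make_scene(list(c(0.95, 0.95, 0.05),  # yellow
                        c(0.90, 0.95, 0.05),  # boundary R: excluded
                        c(0.95, 0.95, 0.10),  # boundary B: excluded
                        c(0.35, 0.60, 0.25))) # sward
  m <- classify_yellow(sc)
  expect_identical(as.vector(m$mask), c(TRUE, FALSE, FALSE, FALSE))

  # all-green scene: empty mask
  p <- small_params()
  scg <- render_scene(point_set(), point_set(kind = "mound"), p)
  expect_equal(sum(classify_yellow(scg)$mask), 0)

  # out-of-range bands are a scaling error
  bad <- rgb_scene(array(128, c(1, 1, 3)) / 100, 0.01)
  expect_error(classify_yellow(bad), "scaled")
})

test_that("brown window calibration is a per-band percentile envelope", {
  # degenerate training: exact window at the training colour
  b <- array(0, c(10, 10, 3))
  b[, , 1] <- 0.5; b[, , 2] <- 0.3; b[, , 3] <- 0.2
  sc <- rgb_scene(b, 0.01)
  tr <- data.frame(x = runif(20, 0, 0.1), y = runif(20, 0, 0.1))
  w <- calibrate_brown_window(sc, tr)
  expect_equal(w$r, c(0.5, 0.5)); expect_equal(w$g, c(0.3, 0.3))
  expect_equal(w$b, c(0.2, 0.2))

  # noisy scene: window contains the true triple
  p <- scene_params(quadrat_width = 20, quadrat_height = 12,
                    noise_sd = 0.01)
  m <- point_set(10, 6, kind = "mound"); m$radius <- 0.2
  scn <- render_scene(point_set(), m, p, seed = 1)
  trn <- data.frame(x = rnorm(100, 10, 0.05), y = rnorm(100, 6, 0.05))
  wn <- calibrate_brown_window(scn, trn)
  expect_true(wn$r[1] <= 0.45 && 0.45 <= wn$r[2])
  expect_true(wn$g[1] <= 0.30 && 0.30 <= wn$g[2])
  expect_true(wn$b[1] <= 0.20 && 0.20 <= wn$b[2])

  # disjoint training colours give a valid but wide (flagged) window
  b2 <- array(0.9, c(2, 2, 3)); b2[1, 1, ] <- c(0.1, 0.1, 0.1)
  sc2 <- rgb_scene(b2, 0.01)
  tr2 <- data.frame(x = rep(c(0.005, 0.015), 6), y = rep(c(0.015, 0.005), 6))
  expect_warning(w2 <- calibrate_brown_window(sc2, tr2), "wide")
  expect_true(all(vapply(w2[c("r", "g", "b")], diff, numeric(1)) >= 0))

  expect_error(calibrate_brown_window(sc, NULL), "training")
})

test_that("brown classification uses closed intervals on all bands", {
  w <- structure(list(r = c(0.4, 0.5), g = c(0.25, 0.35), b = c(0.15, 0.25),
                      n_training = 20, probs = c(0.01, 0.99)),
                 class = "brown_window")
  sc <- make_scene(list(c(0.45, 0.30, 0.20),  # window centre
                        c(0.95, 0.95, 0.05),  # flower: outside
                        c(0.40, 0.25, 0.15),  # edges: inside (closed)
                        c(0.51, 0.30, 0.20))) # just outside R
  m <- classify_brown(sc, w)
  expect_identical(as.vector(m$mask), c(TRUE, FALSE, TRUE, FALSE))
})

test_that("component filter removes buttercups and is monotone", {
  m <- matrix(FALSE, 10, 10)
  m[2, 2:3] <- TRUE                       # 2-px buttercup dot
  m[6:8, 6:8] <- TRUE; m[6, 8] <- FALSE; m[8, 6] <- FALSE  # 7-px flower
  msk <- pixel_mask(m, "yellow", 0.01)

  expect_identical(filter_small_components(msk, 1)$mask, m)
  f4 <- filter_small_components(msk, 4)
  expect_equal(sum(f4$mask), 7)                 # flower kept, dot gone
  expect_equal(sum(f4$mask[2, ]), 0)
  expect_equal(sum(filter_small_components(msk, 8)$mask), 0)

  sizes <- sapply(1:10, function(k) sum(filter_small_components(msk, k)$mask))
  expect_true(all(diff(sizes) <= 0))            # monotone in min_pixels
})

test_that("flower heads are counted as yellow area over 7 cm2", {
  m7 <- pixel_mask(matrix(c(rep(TRUE, 7), rep(FALSE, 9)), 4, 4), "yellow", 0.01)
  expect_equal(count_flower_heads(m7), 1.0)     # 7 cm2 -> one head
  m0 <- pixel_mask(matrix(FALSE, 4, 4), "yellow", 0.01)
  expect_equal(count_flower_heads(m0), 0)
  m70 <- pixel_mask(matrix(TRUE, 7, 10), "yellow", 0.01)
  expect_equal(count_flower_heads(m70), 10.0)   # linearity
  expect_equal(count_flower_heads(m7, resolution = 0.02), 4.0)  # 28 cm2
  expect_error(count_flower_heads(m7, resolution = 0), "resolution")
})

test_that("mound points are component centroids with conserved area", {
  p <- small_params()
  m <- point_set(10, 6, kind = "mound"); m$radius <- 0.15
  sc <- render_scene(point_set(), m, p)
  w <- calibrate_brown_window(sc, data.frame(x = rep(10, 10),
                                             y = seq(5.9, 6.1, length = 10)))
  br <- classify_brown(sc, w)
  pts <- extract_mound_points(br)
  expect_equal(nrow(pts), 1)
  expect_lt(abs(pts$x - 10), 0.011)
  expect_lt(abs(pts$y - 6), 0.011)

  # empty mask
  e <- extract_mound_points(pixel_mask(matrix(FALSE, 5, 5), "brown", 0.01))
  expect_equal(nrow(e), 0)

  # two disjoint mounds: two points, areas partition the brown area
  m2 <- point_set(c(5, 15), c(6, 6), kind = "mound"); m2$radius <- 0.1
  sc2 <- render_scene(point_set(), m2, p)
  br2 <- classify_brown(sc2, w)
  pts2 <- extract_mound_points(br2)
  expect_equal(nrow(pts2), 2)
  expect_equal(sum(pts2$area_m2), sum(br2$mask) * 0.01^2)
})
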