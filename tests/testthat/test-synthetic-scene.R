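test_that("scene parameters are validated", {
  expect_s3_class(scene_params(), "scene_params")
  expect_error(scene_params(resolution = 0), "resolution")
  expect_error(scene_params(depletion_delta = 1.2), "depletion_delta")
  expect_error(scene_params(colonization_beta = c(1, 2)), "length 4")
  expect_error(scene_params(mound_radius_range = c(0.3, 0.1)), "increasing")
  p <- scene_params()
  expect_equal(round(p$quadrat_height / p$resolution), 6000)
  expect_equal(round(p$quadrat_width / p$resolution), 8000)
})

test_that("flower pattern realizes a Thomas process with the stated mean", {
  p <- small_params()
  # zero-intensity process is empty
  p0 <- small_params(flower_parent_intensity = 0)
  expect_equal(nrow(generate_flower_pattern(p0, seed = 1)), 0)

  # degenerate scatter: offspring coincide with a parent location
  pd <- small_params(flower_cluster_sd = 0, flower_parent_intensity = 0.02)
  fl <- generate_flower_pattern(pd, seed = 2)
  expect_lte(length(unique(paste(fl$x, fl$y))),
             length(unique(fl$x)) + 1L)  # as many locations as parents
  expect_true(all(fl$x >= 0 & fl$x < 20 & fl$y >= 0 & fl$y < 12))

  # Monte-Carlo mean within 3 standard errors of kappa * A * mu
  set.seed(3)
  counts <- replicate(500, nrow(generate_flower_pattern(p)))
  expected <- p$flower_parent_intensity * 20 * 12 * p$flower_mean_offspring
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("colonization draw follows the logistic ground truth", {
  p <- small_params(colonization_beta = c(-50, 0, 0, 0))
  fl <- generate_flower_pattern(p, seed = 4)
  gt <- assign_colonization(fl, p, seed = 5)
  expect_length(gt$seed_tiles, 0)
  expect_equal(nrow(gt$mound_points), 0)

  # beta = 0: colonization frequency ~ 0.5
  p2 <- scene_params(quadrat_width = 40, quadrat_height = 40, noise_sd = 0,
                     colonization_beta = c(0, 0, 0, 0))
  fl2 <- generate_flower_pattern(p2, seed = 6)
  gt2 <- assign_colonization(fl2, p2, seed = 7)
  freq <- mean(gt2$tile_probs$colonized)
  expect_lt(abs(freq - 0.5), 3 * sqrt(0.25 / nrow(gt2$tile_probs)))

  # all realized tiles have positive probability; points inside the quadrat
  expect_true(all(gt2$tile_probs$p[gt2$tile_probs$colonized] > 0))
  m <- gt2$mound_points
  expect_true(all(m$x >= 0 & m$x < 40 & m$y >= 0 & m$y < 40))

  # positive anomaly coefficient: empirical colonization frequency is
  # strictly increasing across anomaly deciles (large direct simulation)
  d <- simulate_colonization_tiles(n_quadrats = 50, tiles_per_campaign = 1000,
                                   beta = c(0, 1.5, 0, 0), quadrat_sd = 0,
                                   seed = 8)
  dec <- cut(d$anom, quantile(d$anom, 0:10 / 10), include.lowest = TRUE)
  freqs <- tapply(d$col, dec, mean)
  expect_true(all(diff(freqs) > 0))
})

test_that("depletion kernel thins flowers with the stated retention", {
  p <- small_params()
  fl <- generate_flower_pattern(p, seed = 9)
  mounds <- point_set(10, 6, kind = "mound")

  p0 <- small_params(depletion_delta = 0)
  expect_identical(apply_depletion(fl, mounds, p0, seed = 10), fl)

  # full thinning at contact
  p1 <- small_params(depletion_delta = 1)
  at0 <- point_set(rep(10, 500), rep(6, 500))
  expect_equal(nrow(apply_depletion(at0, mounds, p1, seed = 11)), 0)

  # retention at d = range/2 with delta = 0.8 is 0.6 (closed form)
  p8 <- small_params(depletion_delta = 0.8, depletion_range = 4)
  half <- point_set(rep(12, 10000), rep(6, 10000))  # d = 2 m
  kept <- nrow(apply_depletion(half, mounds, p8, seed = 12)) / 10000
  expect_lt(abs(kept - 0.6), 3 * sqrt(0.6 * 0.4 / 10000))

  # conservation: output is a subset of input
  out <- apply_depletion(fl, mounds, p8, seed = 13)
  expect_true(all(paste(out$x, out$y) %in% paste(fl$x, fl$y)))
  expect_lte(nrow(out), nrow(fl))
})

test_that("renderer produces classifiable scenes with stated geometry", {
  p <- small_params()
  # no points: nothing passes the yellow rule
  sc0 <- render_scene(point_set(), point_set(kind = "mound"), p)
  expect_equal(sum(classify_yellow(sc0)$mask), 0)

  # one 3 cm flower at 1 cm/px covers 5-9 pixels
  sc1 <- render_scene(point_set(5.004, 5.004), point_set(kind = "mound"), p)
  n_yellow <- sum(classify_yellow(sc1)$mask)
  expect_gte(n_yellow, 5); expect_lte(n_yellow, 9)

  # one mound of radius 10 cm: brown area within 10 % of pi r^2
  m <- point_set(10, 6, kind = "mound"); m$radius <- 0.10
  sc2 <- render_scene(point_set(), m, p)
  w <- calibrate_brown_window(sc2, data.frame(x = rep(10, 12),
                                              y = seq(5.95, 6.05, length = 12)))
  area <- sum(classify_brown(sc2, w)$mask) * p$resolution^2
  expect_lt(abs(area - pi * 0.1^2) / (pi * 0.1^2), 0.10)

  # sub-pixel flowers raise the undetectability warning
  pc <- small_params(resolution = 0.05)
  expect_warning(render_scene(point_set(5, 5), point_set(kind = "mound"), pc),
                 "undetectable")
})

test_that("two-year series is deterministic and carries its ground truth", {
  p <- small_params(colonization_beta = c(-2.5, 1.8, 0.0115, -0.0195))
  s1 <- simulate_series(p, seed = 14, render = FALSE)
  s2 <- simulate_series(p, seed = 14, render = FALSE)
  expect_identical(s1, s2)

  # no colonization: October scenes contain no mounds
  pz <- small_params(colonization_beta = c(-50, 0, 0, 0))
  sz <- simulate_series(pz, seed = 15, render = FALSE)
  expect_equal(nrow(sz$dates$october_y1$mounds), 0)
  expect_equal(nrow(sz$dates$october_y2$mounds), 0)

  # flower population only ever shrinks year-over-year (depletion),
  # and strictly so in expectation when colonies are active
  losses <- sapply(1:10, function(k) {
    s <- simulate_series(p, seed = 100 + k, render = FALSE)
    nrow(s$truth$flowers_y1) - nrow(s$truth$flowers_y2)
  })
  expect_true(all(losses >= 0))
  expect_gt(mean(losses), 0)

  # rendered determinism on a tiny quadrat
  pt <- scene_params(quadrat_width = 6, quadrat_height = 4)
  r1 <- simulate_series(pt, seed = 16)
  r2 <- simulate_series(pt, seed = 16)
  expect_identical(r1$dates$may_y1$scene$bands, r2$dates$may_y1$scene$bands)
})
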