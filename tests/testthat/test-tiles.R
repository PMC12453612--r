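test_that("tile grid partitions the quadrat exactly", {
  g <- build_tile_grid(80, 60, 2)
  expect_equal(g$n_tiles, 1200)
  expect_equal(build_tile_grid(2, 2, 2)$n_tiles, 1)
  expect_error(build_tile_grid(80, 61, 2), "divide")
})

test_that("tile cover aggregates and conserves pixel counts", {
  p <- small_params()
  fl <- generate_flower_pattern(p, seed = 20)
  gt <- assign_colonization(fl, p, seed = 21)
  sc <- render_scene(fl, gt$mound_points, p)
  w <- calibrate_brown_window(sc, gt$mound_points[, c("x", "y")])
  br <- classify_brown(sc, w)
  g <- build_tile_grid(20, 12)
  cov <- tile_mound_cover(br, g)
  # conservation: tile sums equal whole-quadrat totals
  px_per_tile <- (2 / 0.01)^2
  expect_equal(sum(cov$cover) * px_per_tile, sum(br$mask))
  expect_true(all(cov$cover >= 0 & cov$cover <= 1))

  y <- filter_small_components(classify_yellow(sc), 4)
  fd <- tile_flower_density(y, g)
  expect_equal(sum(fd$flower_heads), count_flower_heads(y))
  # quadrat-mean identity
  expect_equal(mean(fd$d_t), fd$d_q[1])

  # misaligned raster is an error
  expect_error(tile_mound_cover(br, build_tile_grid(18, 12, 3)), "match|align")
})

test_that("colonization threshold is strict at 2.5 % cover", {
  expect_true(tile_colonized(0.026))
  expect_false(tile_colonized(0.025))
  expect_false(tile_colonized(0))
  expect_identical(tile_colonized(c(0.01, 0.03)), c(FALSE, TRUE))
  # 1000 of 40,000 pixels is exactly 2.5 %: not colonized
  expect_false(tile_colonized(1000 / 40000))
})

test_that("anomaly index matches its anchors and excludes empty quadrats", {
  expect_equal(dandelion_anomaly(5, 1), 5^0.25 - 1)
  expect_lt(abs(dandelion_anomaly(5, 1) - 0.4953), 5e-4)
  expect_equal(dandelion_anomaly(3, 3), 0)
  expect_equal(dandelion_anomaly(0, 2), -1)
  # monotone in d_t at fixed d_q, for several d_q
  for (dq in c(0.5, 2, 10)) {
    a <- dandelion_anomaly(seq(0, 20, by = 0.5), dq)
    expect_true(all(diff(a) > 0))
    expect_equal(dandelion_anomaly(dq, dq), 0)
  }
  expect_warning(a0 <- dandelion_anomaly(1, 0), "undefined")
  expect_true(is.na(a0))
  expect_error(dandelion_anomaly(-1, 2), "non-negative")
})

test_that("transition labelling reproduces the printed study arithmetic", {
  # synthetic tables with the published counts: 64,537 March-uncolonized
  # tiles of which 11,734 are colonized by October
  n_total <- 70000L
  n_march <- n_total - 64537L
  march <- data.frame(tile = seq_len(n_total),
                      colonized = c(rep(TRUE, n_march),
                                    rep(FALSE, 64537L)))
  october <- data.frame(tile = seq_len(n_total),
                        colonized = c(rep(TRUE, n_march),
                                      rep(TRUE, 11734L),
                                      rep(FALSE, 64537L - 11734L)))
  lab <- label_new_colonization(march, october)
  expect_equal(nrow(lab), 64537L)
  expect_equal(sum(lab$col), 11734L)
  expect_equal(round(100 * mean(lab$col), 1), 18.2)
  expect_equal(sum(lab$col == 0L), 52803L)
  expect_false(any(march$tile[march$colonized] %in% lab$tile))

  # no October mounds anywhere: all responses zero
  none <- data.frame(tile = seq_len(n_total), colonized = FALSE)
  expect_equal(sum(label_new_colonization(march, none)$col), 0)

  # grid mismatch
  expect_error(label_new_colonization(march, october[1:10, ]), "grid")
})

test_that("reuse labelling matches the published reuse fraction", {
  n <- 9000L
  both <- c(rep(TRUE, 7851L), rep(FALSE, n - 7851L))
  oct1 <- data.frame(tile = seq_len(n), colonized = both)
  mar2 <- data.frame(tile = seq_len(n), colonized = both)
  oct2 <- data.frame(tile = seq_len(n),
                     colonized = c(rep(TRUE, 2785L), rep(FALSE, n - 2785L)))
  lab <- label_reuse(oct1, mar2, oct2)
  expect_equal(nrow(lab), 7851L)
  expect_equal(sum(lab$reuse), 2785L)
  expect_equal(round(100 * mean(lab$reuse)), 35)

  # colonized in Oct-Y1 but not Mar-Y2: excluded
  mar2b <- mar2; mar2b$colonized[1] <- FALSE
  expect_equal(nrow(label_reuse(oct1, mar2b, oct2)), 7850L)

  # full persistence: all reuse = 1
  expect_true(all(label_reuse(oct1, mar2, oct1)$reuse == 1L))
})

test_that("growth rate is the log ratio of yearly flower counts", {
  expect_equal(compute_dpgr(10, 10), 0)
  expect_equal(compute_dpgr(10, 20), log(2))
  expect_equal(compute_dpgr(20, 10), -log(2))
  expect_equal(compute_dpgr(10, 20), -compute_dpgr(20, 10))
  expect_true(is.na(compute_dpgr(0, 5)))
  expect_true(is.na(compute_dpgr(5, 0)))
  # flowering-stage correction shifts the rate by the log correction ratio
  expect_equal(compute_dpgr(10, 10, correction_y2 = 2), log(2))
})

test_that("series tile table recovers the ground-truth colonized set", {
  p <- small_params(colonization_beta = c(-2, 1.8, 0.0115, -0.0195))
  ser <- simulate_series(p, seed = 30)
  tab <- tile_table_from_series(ser, quadrat_id = "QA")
  g <- build_tile_grid(p$quadrat_width, p$quadrat_height)
  expect_equal(nrow(tab), g$n_tiles)
  for (nm in c("october_y1", "march_y2", "october_y2")) {
    truth <- truth_tile_cover(ser$dates[[nm]]$mounds, p)
    expect_identical(tab[[paste0("col_", nm)]], truth$colonized)
  }
  # flower recovery within rasterization tolerance
  expect_lt(abs(sum(tab$flowers_may_y1) / nrow(ser$truth$flowers_y1) - 1),
            0.15)
})
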