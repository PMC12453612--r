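test_that("AIC identity holds for every fitted model", {
  d <- simulate_colonization_tiles(n_quadrats = 4, tiles_per_campaign = 200,
                                   seed = 40)
  f1 <- fit_colonization_model(d)
  expect_equal(f1$aic, -2 * f1$loglik + 2 * f1$df)

  r <- simulate_reuse_tiles(n_quadrats = 4, tiles_per_quadrat = 200, seed = 41)
  f2 <- fit_reuse_model(r)
  expect_equal(f2$aic, -2 * f2$loglik + 2 * f2$df)

  g <- simulate_dpgr_tiles(n_quadrats = 4, tiles_per_quadrat = 300, seed = 42)
  f3 <- fit_dpgr_model(g)
  expect_equal(f3$aic, -2 * f3$loglik + 2 * f3$df)
})

test_that("structural coefficients are recovered from simulated tiles", {
  d <- simulate_colonization_tiles(seed = 43)
  f <- fit_colonization_model(d)
  co <- f$coefficients
  expect_lt(abs(co["anom", 1] - 1.8), 1.96 * co["anom", 2] * 1.6)
  expect_equal(sign(co["anom:d_q", 1]), -1)

  r <- simulate_reuse_tiles(seed = 44)   # n = 8000
  fr <- fit_reuse_model(r)
  cr <- fr$coefficients
  expect_equal(sign(cr["d_t", 1]), -1)   # negative tile-density effect
  expect_lt(abs(cr["d_t", 1] - (-0.0263)), 3 * cr["d_t", 2])

  g <- simulate_dpgr_tiles(seed = 45)
  fg <- fit_dpgr_model(g)
  cg <- fg$coefficients
  expect_lt(abs(cg["log(cover_pct + 1)", 1] - (-0.3074)),
            3 * cg["log(cover_pct + 1)", 2])
})

test_that("degenerate designs are flagged", {
  d <- simulate_colonization_tiles(n_quadrats = 3, tiles_per_campaign = 100,
                                   seed = 46)
  # constant response: slope coefficients near zero, warning on levels
  d$col <- 0L
  expect_warning(
    expect_warning(expect_error(fit_colonization_model(d), NA), "converge"),
    "outcome")

  r <- simulate_reuse_tiles(n_quadrats = 3, tiles_per_quadrat = 100, seed = 47)
  r$d_q <- 5
  expect_warning(fit_reuse_model(r), "collinear")

  g <- simulate_dpgr_tiles(n_quadrats = 3, tiles_per_quadrat = 100, seed = 48)
  g$cover_pct <- 0
  expect_error(fit_dpgr_model(g), "identifiable")
})

test_that("explained variance is deviance-based and bounded", {
  d <- simulate_colonization_tiles(n_quadrats = 4, tiles_per_campaign = 300,
                                   seed = 49)
  f <- glm(col ~ anom, family = binomial(), data = d)
  expect_equal(explained_variance(f), 1 - f$deviance / f$null.deviance)
  f0 <- glm(col ~ 1, family = binomial(), data = d)
  expect_equal(explained_variance(f0), 0)
  # property: in [0, 1] across replicate fits
  evs <- sapply(1:20, function(k) {
    dd <- simulate_colonization_tiles(n_quadrats = 3,
                                      tiles_per_campaign = 150,
                                      seed = 500 + k)
    fit_colonization_model(dd)$explained_variance
  })
  expect_true(all(evs >= 0 & evs <= 1))
})

test_that("ladders and forward selection rank models by AIC", {
  d <- simulate_colonization_tiles(n_quadrats = 6, tiles_per_campaign = 400,
                                   seed = 50)
  lad <- colonization_ladder(d)
  expect_equal(nrow(lad), 9)
  expect_equal(min(lad$delta_aic, na.rm = TRUE), 0)

  # single candidate model
  one <- aic_ladder(d, list("only" = col ~ anom + quadrat))
  expect_equal(one$delta_aic, 0)

  # strong effect: null loses by more than 10 AIC
  expect_gt(lad$aic[lad$model == "col ~ 1 + Q"] -
              lad$aic[lad$model == "col ~ anom * d_q + Q"], 10)

  # greedy forward search picks up the dominant anomaly effect and stops at
  # the AIC minimum of its visited path
  fs <- forward_stepwise_aic(d, "col",
                             c("anom", "d_t", "d_q", "anom:d_q", "anom:d_t"))
  expect_true(grepl("anom", fs$selected, fixed = TRUE))
  expect_equal(min(fs$path$delta_aic, na.rm = TRUE), 0)
  sel_row <- fs$path$aic[gsub(" ", "", fs$path$model) ==
                           gsub(" ", "", fs$selected)]
  expect_equal(min(fs$path$aic, na.rm = TRUE), min(sel_row))

  # non-converging candidates are recorded, not dropped
  lad2 <- aic_ladder(d, list(ok = col ~ anom + quadrat,
                             broken = col ~ nonexistent_column))
  expect_equal(nrow(lad2), 2)
  expect_true(is.na(lad2$aic[2]))
})

test_that("prediction curves behave as the fitted surface dictates", {
  # flat truth: fitted curve stays near 0.5 everywhere
  set.seed(51)
  d0 <- data.frame(quadrat = rep(c("A", "B"), each = 2000),
                   anom = rnorm(4000), d_q = runif(4000, 2, 12),
                   col = rbinom(4000, 1, 0.5))
  f0 <- fit_colonization_model(d0)
  cv0 <- predict_response_curves(f0, d0)
  expect_true(all(abs(cv0$p - 0.5) < 0.1))

  # positive slope, no interaction: strictly increasing curve
  set.seed(52)
  d1 <- data.frame(quadrat = rep(c("A", "B"), each = 3000),
                   anom = rnorm(6000), d_q = runif(6000, 2, 12))
  d1$col <- rbinom(6000, 1, plogis(-1 + 1.5 * d1$anom))
  f1 <- fit_colonization_model(d1)
  cv1 <- predict_response_curves(f1, d1)
  for (q in unique(cv1$anchor_q))
    expect_true(all(diff(cv1$p[cv1$anchor_q == q]) > 0))

  # negative interaction: anomaly effect (curve spread) is larger at the
  # low-density anchor than at the high-density anchor
  d2 <- simulate_colonization_tiles(seed = 53)   # beta_int = -0.0195 < 0
  f2 <- fit_colonization_model(d2)
  cv2 <- predict_response_curves(f2, d2)
  spread <- tapply(cv2$p, cv2$anchor_q, function(p) diff(range(p)))
  expect_gt(spread[["0.1"]], spread[["0.9"]])

  # invariance to quadrat relabelling
  d3 <- d1; d3$quadrat <- ifelse(d1$quadrat == "A", "Z", "M")
  cv3 <- predict_response_curves(fit_colonization_model(d3), d3)
  expect_equal(cv3$p, cv1$p, tolerance = 1e-8)
})
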