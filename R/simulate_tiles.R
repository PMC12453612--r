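#' @importFrom stats rlnorm rgamma formula
NULL

#' Simulate tile tables directly from the habitat-selection models
#'
#' Fast generators that skip rendering and classification and draw tile
#' records straight from the structural models, for parameter-recovery and
#' model-selection experiments at study-like sample sizes.
#'
#' `simulate_colonization_tiles()` draws, for each quadrat and each of two
#' year-transitions (the surveys pool two annual campaigns, which is also
#' what makes the quadrat-mean density separable from the fixed quadrat
#' factor), a quadrat-year mean density `d_q` (lognormal, median 8 heads/m^2,
#' spanning roughly 1-60 as observed), per-tile densities `d_t` from a
#' gamma distribution with that mean (clustered flowers make tile densities
#' strongly right-skewed), the fourth-root anomaly, a quadrat intercept
#' offset, and the colonization outcome from
#' `plogis(b0 + q_effect + b1 anom + b2 d_q + b3 anom d_q)`.
#'
#' @param n_quadrats Number of quadrats (each contributes two transitions).
#' @param tiles_per_campaign Uncolonized tiles entering the subset per
#'   quadrat-transition.
#' @param beta Length-4 colonization coefficients
#'   (intercept, anomaly, `d_q`, interaction).
#' @param quadrat_sd SD of quadrat intercept offsets on the logit scale.
#' @param d_q_meanlog,d_q_sdlog Lognormal parameters of quadrat-year mean
#'   density.
#' @param gamma_shape Shape of the tile-density gamma distribution.
#' @param seed Optional integer seed.
#' @return `data.frame` with `quadrat`, `year`, `d_t`, `d_q`, `anom`, `p`,
#'   `col`; the generating coefficients are attached as attribute `beta`.
#' @export
simulate_colonization_tiles <- function(n_quadrats = 20,
                                        tiles_per_campaign = 600,
                                        beta = c(-2, 1.8, 0.0115, -0.0195),
                                        quadrat_sd = 0.3,
                                        d_q_meanlog = log(8), d_q_sdlog = 1,
                                        gamma_shape = 0.7,
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(beta) == 4L)
  q_eff <- rnorm(n_quadrats, 0, quadrat_sd)
  rows <- vector("list", n_quadrats * 2L)
  k <- 0L
  for (q in seq_len(n_quadrats)) {
    for (yr in 1:2) {
      d_q <- rlnorm(1, d_q_meanlog, d_q_sdlog)
      d_t <- rgamma(tiles_per_campaign, shape = gamma_shape,
                    rate = gamma_shape / d_q)
      anom <- (d_t / d_q)^0.25 - 1
      lp <- beta[1] + q_eff[q] + beta[2] * anom + beta[3] * d_q +
        beta[4] * anom * d_q
      p <- plogis(lp)
      k <- k + 1L
      rows[[k]] <- data.frame(quadrat = sprintf("Q%02d", q), year = yr,
                              d_t = d_t, d_q = d_q, anom = anom, p = p,
                              col = rbinom(tiles_per_campaign, 1L, p))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "beta") <- beta
  out
}

#' @rdname simulate_colonization_tiles
#' @param tiles_per_quadrat Colonized-in-both-surveys tiles per quadrat
#'   entering the reuse subset.
#' @details `simulate_reuse_tiles()` draws the reuse outcome from
#'   `plogis(b0 + q_effect + b1 d_t + b2 d_t d_q)` on the colonized-tile
#'   subset (single campaign; `d_q` enters only through the interaction, its
#'   main effect being absorbed by the quadrat factor).
#' @export
simulate_reuse_tiles <- function(n_quadrats = 16,
                                 tiles_per_quadrat = 500,
                                 beta = c(-0.6, -0.0263, 9e-4),
                                 quadrat_sd = 0.3,
                                 d_q_meanlog = log(8), d_q_sdlog = 1,
                                 gamma_shape = 0.7,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(beta) == 3L)
  q_eff <- rnorm(n_quadrats, 0, quadrat_sd)
  rows <- vector("list", n_quadrats)
  for (q in seq_len(n_quadrats)) {
    d_q <- rlnorm(1, d_q_meanlog, d_q_sdlog)
    d_t <- rgamma(tiles_per_quadrat, shape = gamma_shape,
                  rate = gamma_shape / d_q)
    anom <- (d_t / d_q)^0.25 - 1
    p <- plogis(beta[1] + q_eff[q] + beta[2] * d_t + beta[3] * d_t * d_q)
    rows[[q]] <- data.frame(quadrat = sprintf("Q%02d", q),
                            d_t = d_t, d_q = d_q, anom = anom, p = p,
                            reuse = rbinom(tiles_per_quadrat, 1L, p))
  }
  out <- do.call(rbind, rows)
  attr(out, "beta") <- beta
  out
}

#' @rdname simulate_colonization_tiles
#' @param slope,intercept Structural coefficients of the growth model
#'   `dpgr = intercept + slope * log(cover_pct + 1) + q_effect + noise`.
#' @param cover_zero_prob Fraction of tiles with zero mound cover.
#' @param noise_sd Residual SD of the tile growth rate.
#' @details `simulate_dpgr_tiles()` draws March mound cover (percent; a
#'   zero-inflated lognormal, median ~2 % among occupied tiles as observed
#'   for quadrat-level cover) and the tile growth rate from the log-linear
#'   model.
#' @export
simulate_dpgr_tiles <- function(n_quadrats = 20,
                                tiles_per_quadrat = 1200,
                                slope = -0.3074, intercept = 0.32,
                                quadrat_sd = 0.3,
                                cover_zero_prob = 0.6,
                                noise_sd = 0.8,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q_eff <- rnorm(n_quadrats, 0, quadrat_sd)
  rows <- vector("list", n_quadrats)
  for (q in seq_len(n_quadrats)) {
    zero <- runif(tiles_per_quadrat) < cover_zero_prob
    cover <- ifelse(zero, 0, pmin(rlnorm(tiles_per_quadrat, log(2), 1), 100))
    dpgr <- intercept + q_eff[q] + slope * log(cover + 1) +
      rnorm(tiles_per_quadrat, 0, noise_sd)
    rows[[q]] <- data.frame(quadrat = sprintf("Q%02d", q),
                            cover_pct = cover, dpgr = dpgr)
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- c(intercept = intercept, slope = slope)
  out
}
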