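#' @useDynLib volescape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rpois rnorm runif rbinom plogis quantile
NULL

# ---------------------------------------------------------------------------
# Point-process generators
# ---------------------------------------------------------------------------

#' Generate a clustered dandelion flower pattern
#'
#' Realizes a Thomas cluster process: Poisson parents of intensity
#' `flower_parent_intensity`, each with a Poisson number of flowers
#' (mean `flower_mean_offspring`) scattered with isotropic Gaussian
#' standard deviation `flower_cluster_sd`, clipped to the quadrat.
#' Parents are simulated in a window extended by six cluster standard
#' deviations so the expected clipped count equals
#' `kappa * area * mu` up to a negligible edge term.
#'
#' @param params A [scene_params()] object.
#' @param seed Optional integer seed; `NULL` continues the current RNG stream.
#' @return A [point_set()] of flowers.
#' @export
generate_flower_pattern <- function(params, seed = NULL) {
  validate_scene_params(params)
  if (!is.null(seed)) set.seed(seed)
  W <- params$quadrat_width; H <- params$quadrat_height
  sd <- params$flower_cluster_sd
  m <- 6 * sd
  kappa <- params$flower_parent_intensity
  n_par <- rpois(1L, kappa * (W + 2 * m) * (H + 2 * m))
  if (n_par == 0L) return(point_set(kind = "flower"))
  px <- runif(n_par, -m, W + m)
  py <- runif(n_par, -m, H + m)
  n_off <- rpois(n_par, params$flower_mean_offspring)
  if (sum(n_off) == 0L) return(point_set(kind = "flower"))
  x <- rep(px, n_off) + rnorm(sum(n_off), 0, sd)
  y <- rep(py, n_off) + rnorm(sum(n_off), 0, sd)
  keep <- x >= 0 & x < W & y >= 0 & y < H
  point_set(x[keep], y[keep], kind = "flower")
}

#' Generate buttercup distractor points
#'
#' Homogeneous Poisson pattern of small (~2 cm^2) yellow flowers that the
#' component-size filter of the classifier must reject.
#'
#' @inheritParams generate_flower_pattern
#' @return A [point_set()] of buttercups.
#' @export
generate_buttercups <- function(params, seed = NULL) {
  validate_scene_params(params)
  if (!is.null(seed)) set.seed(seed)
  W <- params$quadrat_width; H <- params$quadrat_height
  n <- rpois(1L, params$buttercup_intensity * W * H)
  point_set(runif(n, 0, W), runif(n, 0, H), kind = "buttercup")
}

# per-tile flower metrics computed from ground-truth points
points_tile_metrics <- function(flowers, grid) {
  s <- grid$tile_size
  nx <- grid$n_x; ny <- grid$n_y
  cnt <- numeric(nx * ny)
  if (nrow(flowers)) {
    ix <- pmin(floor(flowers$x / s), nx - 1)
    iy <- pmin(floor(flowers$y / s), ny - 1)
    cnt <- tabulate(as.integer(iy * nx + ix + 1), nbins = nx * ny)
  }
  d_t <- cnt / s^2
  d_q <- mean(d_t)
  data.frame(tile = seq_len(nx * ny),
             tile_x = rep(seq_len(nx), times = ny),
             tile_y = rep(seq_len(ny), each = nx),
             n_flowers = cnt, d_t = d_t, d_q = d_q,
             anom = if (d_q > 0) dandelion_anomaly(d_t, d_q)
                    else rep(NA_real_, length(d_t)))
}

# scatter n mound centres uniformly in a disc of given radius around (cx, cy),
# truncated to the quadrat by rejection
scatter_colony <- function(n, cx, cy, radius, W, H) {
  xs <- numeric(0); ys <- numeric(0)
  guard <- 0L
  while (length(xs) < n && guard < 1000L) {
    k <- 2L * (n - length(xs)) + 4L
    r <- radius * sqrt(runif(k)); th <- runif(k, 0, 2 * pi)
    x <- cx + r * cos(th); y <- cy + r * sin(th)
    ok <- x >= 0 & x < W & y >= 0 & y < H
    xs <- c(xs, x[ok]); ys <- c(ys, y[ok])
    guard <- guard + 1L
  }
  cbind(xs[seq_len(n)], ys[seq_len(n)])
}

#' Draw vole colonization of quadrat tiles from the habitat-selection logit
#'
#' Computes per-tile dandelion metrics (tile density, quadrat mean density and
#' the fourth-root anomaly) from the flower points, evaluates the colonization
#' probability `p = plogis(b0 + b1 Anom + b2 Dq + b3 Anom x Dq)`, draws
#' colonized tiles independently, and places one colony (a cluster of
#' `mounds_per_colony` earth mounds scattered in a disc of `territory_radius`)
#' centred on each colonized tile. Tiles with an undefined anomaly (quadrat
#' with no flowers at all) use an anomaly of 0 in the linear predictor.
#'
#' @inheritParams generate_flower_pattern
#' @param flower_points A [point_set()] of flowers.
#' @param exclude_tiles Integer tile indices never colonized in this draw
#'   (e.g. tiles already holding a colony in the earlier survey).
#' @return A `ground_truth` object: `flower_points`, `mound_points` (with
#'   colony ids and `radius`), `tile_probs` (tile metrics, probability and
#'   realized outcome), `seed_tiles` and `params`.
#' @export
assign_colonization <- function(flower_points, params, seed = NULL,
                                exclude_tiles = integer()) {
  validate_scene_params(params)
  if (!is.null(seed)) set.seed(seed)
  grid <- build_tile_grid(params$quadrat_width, params$quadrat_height)
  tm <- points_tile_metrics(flower_points, grid)
  b <- params$colonization_beta
  anom_lp <- ifelse(is.na(tm$anom), 0, tm$anom)
  lp <- b[1] + b[2] * anom_lp + b[3] * tm$d_q + b[4] * anom_lp * tm$d_q
  tm$p <- plogis(lp)
  eligible <- !(tm$tile %in% exclude_tiles)
  tm$colonized <- FALSE
  tm$colonized[eligible] <- rbinom(sum(eligible), 1L, tm$p[eligible]) == 1L
  seed_tiles <- tm$tile[tm$colonized]

  W <- params$quadrat_width; H <- params$quadrat_height
  s <- grid$tile_size
  mx <- my <- mr <- numeric(0); mc <- integer(0)
  for (k in seq_along(seed_tiles)) {
    t <- seed_tiles[k]
    cx <- (tm$tile_x[t] - 0.5) * s
    cy <- (tm$tile_y[t] - 0.5) * s
    n_m <- sample(params$mounds_per_colony[1]:params$mounds_per_colony[2], 1L)
    xy <- scatter_colony(n_m, cx, cy, params$territory_radius, W, H)
    mx <- c(mx, xy[, 1]); my <- c(my, xy[, 2])
    mr <- c(mr, runif(n_m, params$mound_radius_range[1],
                      params$mound_radius_range[2]))
    mc <- c(mc, rep(k, n_m))
  }
  mounds <- point_set(mx, my, kind = "mound", colony_id = mc)
  mounds$radius <- mr
  structure(list(flower_points = flower_points, mound_points = mounds,
                 tile_probs = tm, seed_tiles = seed_tiles, params = params),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth: %d flowers, %d mounds in %d colonies, %d/%d tiles colonized>\n",
              nrow(x$flower_points), nrow(x$mound_points),
              length(unique(x$mound_points$colony_id[!is.na(x$mound_points$colony_id)])),
              length(x$seed_tiles), nrow(x$tile_probs)))
  invisible(x)
}

#' Thin flowers near mounds (resource depletion kernel)
#'
#' Each flower is retained independently with probability
#' `r(d) = 1 - delta * max(0, 1 - d / range)` where `d` is the distance to
#' the nearest mound: full deficit `delta` at contact, no effect beyond
#' `range` (default 4 m, the distance to which depletion is detectable in
#' the field data). Never adds points; with `delta = 0` or no mounds the
#' input is returned unchanged.
#'
#' @inheritParams assign_colonization
#' @param mound_points A [point_set()] of mounds (empty allowed).
#' @return The retained subset of `flower_points`.
#' @export
apply_depletion <- function(flower_points, mound_points, params, seed = NULL) {
  validate_scene_params(params)
  if (!is.null(seed)) set.seed(seed)
  if (params$depletion_delta == 0 || nrow(mound_points) == 0L ||
      nrow(flower_points) == 0L)
    return(flower_points)
  d <- distance_to_mounds(flower_points, mound_points)
  r <- 1 - params$depletion_delta * pmax(0, 1 - d / params$depletion_range)
  flower_points[runif(nrow(flower_points)) < r, ]
}

# ---------------------------------------------------------------------------
# Rendering
# ---------------------------------------------------------------------------

# logical raster of a union of discs, pixel-centre rule
rasterize_discs <- function(x, y, radius, nr, nc, res, height) {
  m <- matrix(FALSE, nr, nc)
  for (k in seq_along(x)) {
    r <- radius[k]
    j0 <- max(1L, floor((x[k] - r) / res) + 1L)
    j1 <- min(nc, floor((x[k] + r) / res) + 1L)
    i0 <- max(1L, floor((height - y[k] - r) / res) + 1L)
    i1 <- min(nr, floor((height - y[k] + r) / res) + 1L)
    if (j0 > j1 || i0 > i1) next
    jj <- j0:j1; ii <- i0:i1
    cx <- (jj - 0.5) * res
    cy <- height - (ii - 0.5) * res
    hit <- outer((cy - y[k])^2, (cx - x[k])^2, `+`) <= r^2
    m[ii, jj] <- m[ii, jj] | hit
  }
  m
}

# fixed 7-pixel cross stamp (4-connected) centred on the flower pixel
stamp7_offsets <- cbind(
  di = c(0L, -1L, 1L, 0L, 0L, -1L, 1L),
  dj = c(0L, 0L, 0L, -1L, 1L, -1L, 1L)
)

rasterize_stamp7 <- function(x, y, nr, nc, res, height) {
  m <- matrix(FALSE, nr, nc)
  if (!length(x)) return(m)
  i <- pmin(pmax(floor((height - y) / res) + 1L, 1L), nr)
  j <- pmin(pmax(floor(x / res) + 1L, 1L), nc)
  for (k in seq_len(nrow(stamp7_offsets))) {
    ii <- i + stamp7_offsets[k, 1L]; jj <- j + stamp7_offsets[k, 2L]
    ok <- ii >= 1L & ii <= nr & jj >= 1L & jj <= nc
    m[cbind(ii[ok], jj[ok])] <- TRUE
  }
  m
}

#' Render a synthetic orthomosaic
#'
#' Paints green sward, brown mound discs, small yellow buttercup dots and
#' yellow dandelion discs (in that stacking order, dandelions on top) into a
#' 3-band reflectance raster at the scene resolution. Gaussian noise of
#' standard deviation `noise_sd` is added to background and mound pixels and
#' clamped to `[0, 1]`; flowers and buttercups render at their exact
#' saturated colour, as bright flower heads saturate the sensor.
#'
#' @inheritParams assign_colonization
#' @param flowers,mounds,buttercups [point_set()]s; `mounds` may carry a
#'   `radius` column (defaults to the midpoint of `mound_radius_range`).
#' @return An [rgb_scene()].
#' @export
render_scene <- function(flowers, mounds, params, seed = NULL,
                         buttercups = NULL) {
  validate_scene_params(params)
  if (!is.null(seed)) set.seed(seed)
  res <- params$resolution
  nr <- round(params$quadrat_height / res)
  nc <- round(params$quadrat_width / res)
  if (params$flower_diameter / res < 1)
    warning("flower diameter below one pixel: flowers may be undetectable")

  mound_mask <- if (nrow(mounds)) {
    r <- if ("radius" %in% names(mounds)) mounds$radius
         else rep(mean(params$mound_radius_range), nrow(mounds))
    rasterize_discs(mounds$x, mounds$y, r, nr, nc, res, params$quadrat_height)
  } else matrix(FALSE, nr, nc)

  flower_mask <- if (nrow(flowers)) {
    if (params$flower_render == "stamp7")
      rasterize_stamp7(flowers$x, flowers$y, nr, nc, res,
                       params$quadrat_height)
    else
      rasterize_discs(flowers$x, flowers$y,
                      rep(params$flower_diameter / 2, nrow(flowers)),
                      nr, nc, res, params$quadrat_height)
  } else matrix(FALSE, nr, nc)

  # buttercup dot pixels (1-2 px each), identical across bands
  bc_idx <- NULL
  if (!is.null(buttercups) && nrow(buttercups)) {
    bi <- scene_rowcol(buttercups$x, buttercups$y,
                       list(resolution = res,
                            height = params$quadrat_height,
                            width = params$quadrat_width))
    two <- runif(nrow(buttercups)) < 0.5
    dj <- sample(c(-1L, 1L), sum(two), replace = TRUE)
    bi2 <- bi[two, , drop = FALSE]
    bi2[, 2L] <- pmin(pmax(bi2[, 2L] + dj, 1L), nc)
    bc_idx <- rbind(bi, bi2)
  }

  bands <- array(0, c(nr, nc, 3L))
  for (b in 1:3) {
    v <- matrix(params$background_rgb[b], nr, nc)
    v[mound_mask] <- params$brown_rgb[b]
    if (params$noise_sd > 0)
      v <- v + rnorm(nr * nc, 0, params$noise_sd)
    if (!is.null(bc_idx)) v[bc_idx] <- params$flower_rgb[b]
    v[flower_mask] <- params$flower_rgb[b]
    bands[, , b] <- pmin(pmax(v, 0), 1)
  }
  rgb_scene(bands, res)
}

#' Tile cover of the ground-truth mound geometry
#'
#' Rasterizes the mound discs with the same pixel-centre rule as the
#' renderer and aggregates to tile cover fractions, giving the reference
#' colonized-tile set that a noise-free classification must recover exactly.
#'
#' @inheritParams render_scene
#' @return `data.frame` with `tile`, `tile_x`, `tile_y`, `cover`,
#'   `colonized` (cover > 2.5 %).
#' @export
truth_tile_cover <- function(mounds, params) {
  validate_scene_params(params)
  res <- params$resolution
  nr <- round(params$quadrat_height / res)
  nc <- round(params$quadrat_width / res)
  r <- if (nrow(mounds) && "radius" %in% names(mounds)) mounds$radius
       else rep(mean(params$mound_radius_range), nrow(mounds))
  m <- if (nrow(mounds))
    rasterize_discs(mounds$x, mounds$y, r, nr, nc, res,
                    params$quadrat_height)
  else matrix(FALSE, nr, nc)
  msk <- pixel_mask(m, "brown", res)
  grid <- build_tile_grid(params$quadrat_width, params$quadrat_height)
  cov <- tile_mound_cover(msk, grid)
  cov$colonized <- tile_colonized(cov$cover)
  cov
}

# ---------------------------------------------------------------------------
# Survey series
# ---------------------------------------------------------------------------

#' Simulate a two-year drone survey of one quadrat
#'
#' Emits the six survey dates (March, May, October of two years) with a
#' persistent flower population, colonization events between March and
#' October of each year (drawn from the colonization logit on tiles not
#' already colonized), over-winter persistence of colonies, burrow
#' reuse/abandonment between years (drawn from the reuse logit on the
#' colony's seed-tile dandelion density in year 2), and flower depletion
#' applied around colonies active before the second May. A single RNG
#' stream, seeded once, drives every draw in a fixed order, so identical
#' parameters and seed give bit-identical output.
#'
#' @inheritParams generate_flower_pattern
#' @param render If `TRUE`, each date also carries a rendered [rgb_scene()];
#'   ground truth is generated either way.
#' @return A `vole_series`: list with `dates` (named list per survey date of
#'   `flowers`, `buttercups`, `mounds`, `scene`), `truth` (Q1 colonization
#'   tables per year, Q2 reuse table, year-2 flower set) and `params`.
#' @export
simulate_series <- function(params, seed = NULL, render = TRUE) {
  validate_scene_params(params)
  if (!is.null(seed)) set.seed(seed)

  flowers_y1 <- generate_flower_pattern(params)
  butter_y1 <- generate_buttercups(params)

  gt_march1 <- assign_colonization(flowers_y1, params)
  march1_tiles <- gt_march1$seed_tiles
  gt_oct1 <- assign_colonization(flowers_y1, params,
                                 exclude_tiles = march1_tiles)
  n_col_m1 <- max(0L, length(march1_tiles))
  mounds_oct1 <- rbind(gt_march1$mound_points,
                       within(gt_oct1$mound_points,
                              colony_id <- colony_id + n_col_m1))
  class(mounds_oct1) <- c("point_set", "data.frame")

  # colonies persist over winter; depletion acts before the second May
  mounds_march2 <- mounds_oct1
  flowers_y2 <- apply_depletion(flowers_y1, mounds_march2, params)
  butter_y2 <- generate_buttercups(params)

  # burrow reuse: per colony, from year-2 dandelion density at its seed tile
  grid <- build_tile_grid(params$quadrat_width, params$quadrat_height)
  tm2 <- points_tile_metrics(flowers_y2, grid)
  colony_ids <- sort(unique(mounds_march2$colony_id))
  reuse_truth <- NULL
  kept <- colony_ids
  if (length(colony_ids)) {
    ctile <- vapply(colony_ids, function(cid) {
      w <- mounds_march2$colony_id == cid
      x <- mean(mounds_march2$x[w]); y <- mean(mounds_march2$y[w])
      ix <- pmin(floor(x / grid$tile_size), grid$n_x - 1)
      iy <- pmin(floor(y / grid$tile_size), grid$n_y - 1)
      as.integer(iy * grid$n_x + ix + 1)
    }, integer(1))
    d_t <- tm2$d_t[ctile]; d_q <- tm2$d_q[ctile]
    rb <- params$reuse_beta
    p_reuse <- plogis(rb[1] + rb[2] * d_t + rb[3] * d_t * d_q)
    reused <- rbinom(length(colony_ids), 1L, p_reuse) == 1L
    kept <- colony_ids[reused]
    reuse_truth <- data.frame(colony_id = colony_ids, tile = ctile,
                              d_t = d_t, d_q = d_q, p = p_reuse,
                              reused = reused)
  }
  mounds_kept <- mounds_march2[mounds_march2$colony_id %in% kept, ]

  march2_cover_tiles <- unique(c(
    if (!is.null(reuse_truth)) reuse_truth$tile else integer()))
  gt_oct2 <- assign_colonization(
    flowers_y2, params,
    exclude_tiles = unique(c(march1_tiles, gt_oct1$seed_tiles)))
  n_before <- if (length(colony_ids)) max(colony_ids) else 0L
  mounds_oct2 <- rbind(mounds_kept,
                       within(gt_oct2$mound_points,
                              colony_id <- colony_id + n_before))
  class(mounds_oct2) <- c("point_set", "data.frame")

  empty <- point_set(kind = "flower")
  dates <- list(
    march_y1   = list(flowers = empty, buttercups = NULL,
                      mounds = gt_march1$mound_points),
    may_y1     = list(flowers = flowers_y1, buttercups = butter_y1,
                      mounds = gt_march1$mound_points),
    october_y1 = list(flowers = empty, buttercups = NULL,
                      mounds = mounds_oct1),
    march_y2   = list(flowers = empty, buttercups = NULL,
                      mounds = mounds_march2),
    may_y2     = list(flowers = flowers_y2, buttercups = butter_y2,
                      mounds = mounds_march2),
    october_y2 = list(flowers = empty, buttercups = NULL,
                      mounds = mounds_oct2)
  )
  if (render) {
    for (nm in names(dates)) {
      dates[[nm]]$scene <- render_scene(dates[[nm]]$flowers,
                                        dates[[nm]]$mounds, params,
                                        buttercups = dates[[nm]]$buttercups)
    }
  }
  structure(list(
    dates = dates,
    truth = list(colonization_y1 = gt_oct1$tile_probs,
                 colonization_y2 = gt_oct2$tile_probs,
                 march_y1_tiles = march1_tiles,
                 reuse = reuse_truth,
                 flowers_y1 = flowers_y1, flowers_y2 = flowers_y2),
    params = params), class = "vole_series")
}

#' @export
print.vole_series <- function(x, ...) {
  cat("<vole_series: 6 survey dates>\n")
  for (nm in names(x$dates)) {
    d <- x$dates[[nm]]
    cat(sprintf("  %-11s %6d flowers, %5d mounds%s\n", nm,
                nrow(d$flowers), nrow(d$mounds),
                if (!is.null(d$scene)) " [rendered]" else ""))
  }
  invisible(x)
}
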