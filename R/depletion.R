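#' Distance from each flower to its nearest mound
#'
#' Exact Euclidean nearest-neighbour distance, computed in blocks of the
#' full distance matrix (point sets here are at most a few thousand points).
#'
#' @param flowers,mounds [point_set()]s; `mounds` must be non-empty.
#' @return Numeric vector, one distance per flower.
#' @export
distance_to_mounds <- function(flowers, mounds) {
  if (nrow(mounds) == 0L)
    stop("no mounds: distance profile undefined", call. = FALSE)
  if (nrow(flowers) == 0L) return(numeric(0))
  out <- numeric(nrow(flowers))
  step <- 2000L
  mx <- mounds$x; my <- mounds$y
  for (s in seq(1L, nrow(flowers), by = step)) {
    e <- min(s + step - 1L, nrow(flowers))
    dx <- outer(flowers$x[s:e], mx, `-`)
    dy <- outer(flowers$y[s:e], my, `-`)
    d2 <- dx * dx + dy * dy
    out[s:e] <- sqrt(do.call(pmin, as.data.frame(d2)))
  }
  out
}

#' Logarithmic buffer edges
#'
#' `n` consecutive distance buffers from `d_min` to `d_max` with constant
#' ratio between edges: `r_k = d_min * (d_max / d_min)^(k/n)`, `k = 0..n`.
#' The defaults give the 20 buffers from 5 cm to 5 m (edge ratio
#' `100^(1/20) ~ 1.2589`).
#'
#' @param d_min,d_max Inner and outer bounds in metres (`0 < d_min < d_max`).
#' @param n Number of buffers.
#' @return Numeric vector of `n + 1` edges.
#' @export
make_log_buffers <- function(d_min = 0.05, d_max = 5, n = 20) {
  if (!(is.finite(d_min) && is.finite(d_max) && d_min > 0 && d_max > d_min))
    stop("require 0 < d_min < d_max", call. = FALSE)
  if (n < 1) stop("need at least one buffer", call. = FALSE)
  d_min * (d_max / d_min)^(seq(0, n) / n)
}

#' Construct a fine-scale subplot
#'
#' @param flowers,mounds [point_set()]s clipped to the extent.
#' @param extent Side length in metres (subplots are 20 m x 20 m windows
#'   centred on one colony).
#' @param subplot_id Identifier.
#' @return Object of class `subplot_data`.
#' @export
subplot_data <- function(flowers, mounds, extent = 20, subplot_id = "S1") {
  stopifnot(extent > 0)
  ok <- function(p) all(p$x >= 0 & p$x <= extent & p$y >= 0 & p$y <= extent)
  if (!ok(flowers) || !ok(mounds))
    stop("points fall outside the subplot extent", call. = FALSE)
  structure(list(flowers = flowers, mounds = mounds, extent = extent,
                 subplot_id = subplot_id),
            class = "subplot_data")
}

#' Simulate fine-scale subplots around colonies
#'
#' Each subplot is a 20 m x 20 m window with one vole colony at its centre
#' (15-30 mounds scattered in the territory disc) and a homogeneous Poisson
#' flower pattern thinned by the depletion kernel. The subplot's depletion
#' deficit is drawn around `depletion_delta` with SD `subplot_delta_sd`
#' (truncated to `[0, 1]`), creating between-subplot heterogeneity that the
#' GAM's random intercept absorbs.
#'
#' @param n_subplots Number of subplots (the field campaign mapped 46).
#' @param params A [scene_params()].
#' @param flower_intensity Flowers per m^2 before thinning.
#' @param extent Subplot side (m).
#' @param seed Optional integer seed.
#' @return List of `subplot_data`.
#' @export
simulate_subplots <- function(n_subplots = 46, params = scene_params(),
                              flower_intensity = 3, extent = 20,
                              seed = NULL) {
  validate_scene_params(params)
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n_subplots)
  for (s in seq_len(n_subplots)) {
    n_m <- sample(params$mounds_per_colony[1]:params$mounds_per_colony[2], 1L)
    xy <- scatter_colony(n_m, extent / 2, extent / 2,
                         params$territory_radius, extent, extent)
    mounds <- point_set(xy[, 1], xy[, 2], kind = "mound", colony_id = s)
    mounds$radius <- runif(n_m, params$mound_radius_range[1],
                           params$mound_radius_range[2])
    n_f <- rpois(1L, flower_intensity * extent^2)
    flowers <- point_set(runif(n_f, 0, extent), runif(n_f, 0, extent),
                         kind = "flower")
    delta_s <- min(1, max(0, rnorm(1, params$depletion_delta,
                                   params$subplot_delta_sd)))
    p2 <- params; p2$depletion_delta <- delta_s
    flowers <- apply_depletion(flowers, mounds, p2)
    out[[s]] <- subplot_data(flowers, mounds, extent,
                             subplot_id = sprintf("S%02d", s))
  }
  out
}

# distance-to-nearest-mound field rasterized at `resolution` over the
# (square) subplot extent
distance_field <- function(mounds, extent, resolution) {
  n <- round(extent / resolution)
  cx <- (seq_len(n) - 0.5) * resolution
  d2min <- NULL
  for (k in seq_len(nrow(mounds))) {
    d2 <- outer((cx - mounds$y[k])^2, (cx - mounds$x[k])^2, `+`)
    d2min <- if (is.null(d2min)) d2 else pmin(d2min, d2)
  }
  sqrt(d2min)
}

#' Depletion profile of one subplot
#'
#' For each logarithmic buffer, counts flower heads whose
#' distance-to-nearest-mound falls in the annulus and divides the resulting
#' density by the subplot mean density:
#' `DD = (count / annulus area) / (total flowers / extent area)`.
#' The annulus area is the area of the distance-field band clipped to the
#' extent (default), computed by rasterizing the nearest-mound distance at
#' `resolution`; `area_method = "ring"` instead uses the naive sum of
#' per-mound ring areas (no overlap or edge correction), provided for
#' comparison. Flowers nearer than the innermost edge are assigned to the
#' innermost buffer, whose area band likewise starts at distance 0, keeping
#' the profile normalized (DD ~ 1 under no depletion).
#'
#' @param subplot A [subplot_data()].
#' @param buffers Edge vector from [make_log_buffers()].
#' @param area_method `"field"` (distance-field band, clipped) or `"ring"`.
#' @param resolution Rasterization step (m) of the distance field.
#' @return `data.frame` of buffer records: `subplot_id`, `buffer`,
#'   `r_inner`, `r_outer`, `dm` (geometric mean of the edges),
#'   `flower_count`, `area_m2`, `dd`.
#' @export
depletion_profile <- function(subplot, buffers = make_log_buffers(),
                              area_method = c("field", "ring"),
                              resolution = 0.01) {
  stopifnot(inherits(subplot, "subplot_data"))
  area_method <- match.arg(area_method)
  nb <- length(buffers) - 1L
  n_tot <- nrow(subplot$flowers)
  if (n_tot == 0L)
    stop("subplot has no flowers: depletion profile undefined", call. = FALSE)
  d <- distance_to_mounds(subplot$flowers, subplot$mounds)

  lower <- buffers[-length(buffers)]; upper <- buffers[-1]
  lower[1] <- 0  # sub-innermost-edge flowers fold into buffer 1
  counts <- vapply(seq_len(nb), function(k)
    sum(d > lower[k] & d <= upper[k]), numeric(1))

  if (area_method == "field") {
    df <- distance_field(subplot$mounds, subplot$extent, resolution)
    areas <- vapply(seq_len(nb), function(k)
      sum(df > lower[k] & df <= upper[k]), numeric(1)) * resolution^2
  } else {
    n_m <- nrow(subplot$mounds)
    areas <- n_m * pi * (upper^2 - lower^2)
  }

  mean_density <- n_tot / subplot$extent^2
  dd <- ifelse(areas > 0, (counts / areas) / mean_density, NA_real_)
  data.frame(subplot_id = subplot$subplot_id, buffer = seq_len(nb),
             r_inner = buffers[-length(buffers)], r_outer = upper,
             dm = sqrt(buffers[-length(buffers)] * upper),
             flower_count = counts, area_m2 = areas, dd = dd)
}

#' @rdname depletion_profile
#' @param subplots List of [subplot_data()].
#' @param ... Passed on to `depletion_profile()`.
#' @export
depletion_profiles <- function(subplots, buffers = make_log_buffers(), ...) {
  do.call(rbind, lapply(subplots, depletion_profile, buffers = buffers, ...))
}

#' Simulate buffer records directly from the depletion model
#'
#' Record-level generator for model-selection experiments: buffer records
#' are drawn straight from the structure of the best fine-scale model —
#' a depletion curve that is linear in log distance up to the depletion
#' range (1 at and beyond it), plus a Gaussian subplot random intercept and
#' residual noise. Skips the point-pattern path entirely.
#'
#' @param n_subplots Number of subplots.
#' @param buffers Edge vector from [make_log_buffers()].
#' @param delta Depth of depletion at the innermost distance.
#' @param range_m Distance (m) at which the curve reaches 1.
#' @param subplot_sd SD of subplot random intercepts.
#' @param noise_sd Residual SD of a buffer record.
#' @param seed Optional integer seed.
#' @return Buffer records (`subplot_id`, `buffer`, `dm`, `dd`) with the
#'   true curve attached as attribute `truth_curve` (a function of dm).
#' @export
simulate_depletion_records <- function(n_subplots = 46,
                                       buffers = make_log_buffers(),
                                       delta = 0.8, range_m = 4,
                                       subplot_sd = 0.15, noise_sd = 0.15,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nb <- length(buffers) - 1L
  dm <- sqrt(buffers[-length(buffers)] * buffers[-1])
  d0 <- dm[1]
  truth <- function(d)
    1 - delta * pmax(0, pmin(1, log(range_m / d) / log(range_m / d0)))
  b_s <- rnorm(n_subplots, 0, subplot_sd)
  out <- do.call(rbind, lapply(seq_len(n_subplots), function(s) {
    data.frame(subplot_id = sprintf("S%02d", s), buffer = seq_len(nb),
               dm = dm,
               dd = truth(dm) + b_s[s] + rnorm(nb, 0, noise_sd))
  }))
  attr(out, "truth_curve") <- truth
  out
}

#' Fit the depletion GAM
#'
#' Penalized cubic-spline smooth of the depletion ratio on log distance,
#' Gaussian likelihood, with a ridge-penalized random intercept per subplot
#' (`dd ~ s(log_dm) + s(subplot, bs = "re")`), smoothing parameters by REML.
#' The fitted curve (random effect excluded, pointwise ~95 % interval) is
#' evaluated on a log-regular distance grid.
#'
#' @param records Buffer records from [depletion_profiles()].
#' @param k Basis dimension of the distance smooth.
#' @param n_grid Number of curve evaluation points.
#' @return A `depletion_fit`: list with the `mgcv::gam` object, the curve
#'   `data.frame` (`dm`, `fit`, `se`, `lower`, `upper`), the AIC, and the
#'   estimated measurable range (largest distance at which the pointwise
#'   interval still excludes 1 from below).
#' @export
fit_depletion_gam <- function(records, k = 10, n_grid = 200) {
  records <- records[!is.na(records$dd), , drop = FALSE]
  if (length(unique(records$subplot_id)) < 5L)
    warning("fewer than 5 subplots: random-effect variance weakly identified")
  if (length(unique(records$dm)) < 10L)
    stop("need at least 10 distinct distances", call. = FALSE)
  dat <- data.frame(dd = records$dd, log_dm = log(records$dm),
                    subplot = factor(records$subplot_id))
  m <- mgcv::gam(dd ~ s(log_dm, k = k, bs = "cr") + s(subplot, bs = "re"),
                 data = dat, method = "REML")
  grid <- data.frame(log_dm = seq(min(dat$log_dm), max(dat$log_dm),
                                  length.out = n_grid),
                     subplot = dat$subplot[1])
  pr <- predict(m, newdata = grid, se.fit = TRUE, exclude = "s(subplot)")
  curve <- data.frame(dm = exp(grid$log_dm),
                      fit = as.numeric(pr$fit), se = as.numeric(pr$se.fit))
  curve$lower <- curve$fit - 1.96 * curve$se
  curve$upper <- curve$fit + 1.96 * curve$se
  below <- curve$upper < 1
  range_m <- if (any(below)) max(curve$dm[below]) else NA_real_
  structure(list(gam = m, curve = curve, aic = AIC(m),
                 edf = sum(m$edf), measurable_range_m = range_m),
            class = "depletion_fit")
}

#' @export
print.depletion_fit <- function(x, ...) {
  cat(sprintf("<depletion_fit: AIC = %.1f, edf = %.1f, depletion measurable to %.2f m>\n",
              x$aic, x$edf,
              if (is.na(x$measurable_range_m)) NA else x$measurable_range_m))
  invisible(x)
}

#' AIC ladder of the fine-scale depletion models
#'
#' Fits the five candidate structures compared in the published selection
#' panel: subplot factor only, smooth of raw distance, smooth of log
#' distance, and the two distance smooths with a subplot random intercept.
#'
#' @param records Buffer records from [depletion_profiles()].
#' @param k Basis dimension of the distance smooths.
#' @return An `aic_table`.
#' @export
depletion_ladder <- function(records, k = 10) {
  records <- records[!is.na(records$dd), , drop = FALSE]
  dat <- data.frame(dd = records$dd, dm = records$dm,
                    log_dm = log(records$dm),
                    subplot = factor(records$subplot_id))
  specs <- list(
    "dd ~ subplot"                      = dd ~ subplot,
    "dd ~ s(dm)"                        = dd ~ s(dm, k = k, bs = "cr"),
    "dd ~ s(log(dm))"                   = dd ~ s(log_dm, k = k, bs = "cr"),
    "dd ~ s(dm) + s(subplot, re)"       =
      dd ~ s(dm, k = k, bs = "cr") + s(subplot, bs = "re"),
    "dd ~ s(log(dm)) + s(subplot, re)"  =
      dd ~ s(log_dm, k = k, bs = "cr") + s(subplot, bs = "re")
  )
  rows <- lapply(names(specs), function(nm) {
    m <- tryCatch(mgcv::gam(specs[[nm]], data = dat, method = "REML"),
                  error = function(e) NULL)
    if (is.null(m))
      return(data.frame(model = nm, df = NA_real_, aic = NA_real_,
                        explained_variance = NA_real_))
    data.frame(model = nm, df = sum(m$edf), aic = AIC(m),
               explained_variance = explained_variance(m))
  })
  out <- do.call(rbind, rows)
  out$delta_aic <- out$aic - min(out$aic, na.rm = TRUE)
  out <- out[, c("model", "df", "aic", "delta_aic", "explained_variance")]
  class(out) <- c("aic_table", "data.frame")
  out
}
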