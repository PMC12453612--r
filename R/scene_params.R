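#' Parameters of a synthetic meadow scene
#'
#' Bundles every knob of the synthetic-scene generator: quadrat geometry,
#' the clustered dandelion point process, buttercup distractors, vole colony
#' geometry, the colonization logit, the flower-thinning (depletion) kernel,
#' and rendering colours. Defaults describe the monitored system: an
#' 80 m x 60 m meadow quadrat imaged at 1 cm/pixel, dandelion flower heads of
#' ~3 cm diameter (~7 cm^2), colonies of 15-30 earth mounds on a territory of
#' roughly 50 m^2, and flower depletion extending to about 4 m around mounds.
#'
#' @param quadrat_width,quadrat_height Quadrat dimensions in metres.
#' @param resolution Ground resolution in metres per pixel.
#' @param flower_parent_intensity Intensity of Thomas-process parents
#'   (parents / m^2). The expected flower density is
#'   `flower_parent_intensity * flower_mean_offspring`.
#' @param flower_mean_offspring Mean number of flowers per parent cluster.
#' @param flower_cluster_sd Isotropic Gaussian scatter (m) of flowers around
#'   their parent; dandelion density varies on the scale of a few square
#'   metres, hence a default of 1.5 m.
#' @param flower_diameter Flower head diameter in metres (3 cm, ~7 cm^2).
#' @param buttercup_intensity Intensity (flowers / m^2) of the smaller yellow
#'   buttercup distractors (~2 cm^2 each).
#' @param colony_count Number of colonies used by the stand-alone subplot
#'   generator (quadrat series derive colony numbers from the logit instead).
#' @param mounds_per_colony Integer range (length 2) of mounds per colony.
#' @param mound_radius_range Range (m) of mound radii.
#' @param territory_radius Radius (m) of the disc over which a colony's
#'   mounds scatter; 4 m gives a territory of ~50 m^2.
#' @param depletion_delta Retention deficit at distance 0: a flower touching
#'   a mound is removed with this probability. In `[0, 1]`.
#' @param depletion_range Distance (m) beyond which flowers are unaffected.
#' @param subplot_delta_sd Between-subplot standard deviation of the
#'   depletion deficit used by the fine-scale subplot generator (creates the
#'   subplot heterogeneity that the random-effect term of the depletion GAM
#'   absorbs).
#' @param colonization_beta Length-4 coefficient vector (intercept, anomaly,
#'   quadrat density, anomaly x quadrat density) of the colonization logit.
#' @param reuse_beta Length-3 coefficient vector (intercept, tile density,
#'   tile density x quadrat density) of the burrow-reuse logit.
#' @param background_rgb,brown_rgb,flower_rgb RGB triples in `[0, 1]` used by
#'   the renderer for sward, bare earth and flowers.
#' @param noise_sd Gaussian pixel noise (reflectance units) added to
#'   background and mound pixels; flowers render at their exact colour
#'   (bright saturated discs). Set to 0 for a lossless scene.
#' @param flower_render `"disc"` rasterizes each flower as the set of pixels
#'   whose centre falls in the 3 cm disc (5-9 pixels at 1 cm); `"stamp7"`
#'   stamps a fixed 7-pixel cross, making head counts exact when stamps do
#'   not overlap.
#' @param seed Optional integer seed stored with the parameters.
#'
#' @return An object of class `scene_params` (a validated list).
#' @export
scene_params <- function(quadrat_width = 80,
                         quadrat_height = 60,
                         resolution = 0.01,
                         flower_parent_intensity = 0.05,
                         flower_mean_offspring = 60,
                         flower_cluster_sd = 1.5,
                         flower_diameter = 0.03,
                         buttercup_intensity = 0.2,
                         colony_count = 8,
                         mounds_per_colony = c(15L, 30L),
                         mound_radius_range = c(0.05, 0.25),
                         territory_radius = 4,
                         depletion_delta = 0.8,
                         depletion_range = 4,
                         subplot_delta_sd = 0.15,
                         colonization_beta = c(-4, 1.8, 0.0115, -0.0195),
                         reuse_beta = c(-0.6, -0.0263, 9e-4),
                         background_rgb = c(0.35, 0.60, 0.25),
                         brown_rgb = c(0.45, 0.30, 0.20),
                         flower_rgb = c(0.95, 0.95, 0.05),
                         noise_sd = 0.02,
                         flower_render = c("disc", "stamp7"),
                         seed = NULL) {
  flower_render <- match.arg(flower_render)
  p <- list(
    quadrat_width = quadrat_width, quadrat_height = quadrat_height,
    resolution = resolution,
    flower_parent_intensity = flower_parent_intensity,
    flower_mean_offspring = flower_mean_offspring,
    flower_cluster_sd = flower_cluster_sd,
    flower_diameter = flower_diameter,
    buttercup_intensity = buttercup_intensity,
    colony_count = colony_count,
    mounds_per_colony = as.integer(mounds_per_colony),
    mound_radius_range = mound_radius_range,
    territory_radius = territory_radius,
    depletion_delta = depletion_delta,
    depletion_range = depletion_range,
    subplot_delta_sd = subplot_delta_sd,
    colonization_beta = colonization_beta,
    reuse_beta = reuse_beta,
    background_rgb = background_rgb,
    brown_rgb = brown_rgb,
    flower_rgb = flower_rgb,
    noise_sd = noise_sd,
    flower_render = flower_render,
    seed = seed
  )
  class(p) <- "scene_params"
  validate_scene_params(p)
  p
}

validate_scene_params <- function(p) {
  stopifnot(inherits(p, "scene_params"))
  num_ok <- function(x) is.numeric(x) && all(is.finite(x))
  if (!num_ok(p$quadrat_width) || !num_ok(p$quadrat_height) ||
      p$quadrat_width <= 0 || p$quadrat_height <= 0)
    stop("quadrat dimensions must be finite and positive", call. = FALSE)
  if (!num_ok(p$resolution) || p$resolution <= 0)
    stop("resolution must be > 0", call. = FALSE)
  for (f in c("flower_parent_intensity", "flower_mean_offspring",
              "flower_cluster_sd", "flower_diameter", "buttercup_intensity",
              "territory_radius", "depletion_range")) {
    if (!num_ok(p[[f]]) || any(p[[f]] < 0))
      stop(sprintf("'%s' must be finite and non-negative", f), call. = FALSE)
  }
  if (!num_ok(p$depletion_delta) || p$depletion_delta < 0 || p$depletion_delta > 1)
    stop("depletion_delta must lie in [0, 1]", call. = FALSE)
  if (length(p$mounds_per_colony) != 2L ||
      any(p$mounds_per_colony < 1L) || diff(p$mounds_per_colony) < 0)
    stop("mounds_per_colony must be an increasing pair of positive integers",
         call. = FALSE)
  if (length(p$mound_radius_range) != 2L || any(p$mound_radius_range <= 0) ||
      diff(p$mound_radius_range) < 0)
    stop("mound_radius_range must be an increasing pair of positive lengths",
         call. = FALSE)
  if (length(p$colonization_beta) != 4L || !num_ok(p$colonization_beta))
    stop("colonization_beta must be a finite numeric vector of length 4",
         call. = FALSE)
  if (length(p$reuse_beta) != 3L || !num_ok(p$reuse_beta))
    stop("reuse_beta must be a finite numeric vector of length 3", call. = FALSE)
  for (f in c("background_rgb", "brown_rgb", "flower_rgb")) {
    v <- p[[f]]
    if (length(v) != 3L || !num_ok(v) || any(v < 0) || any(v > 1))
      stop(sprintf("'%s' must be an RGB triple in [0, 1]", f), call. = FALSE)
  }
  invisible(p)
}

#' @export
print.scene_params <- function(x, ...) {
  cat(sprintf("Synthetic scene parameters: %g m x %g m quadrat at %g m/pixel\n",
              x$quadrat_width, x$quadrat_height, x$resolution))
  cat(sprintf("  flowers: Thomas process kappa=%g/m2, mu=%g, sigma=%g m (expected %.1f /m2)\n",
              x$flower_parent_intensity, x$flower_mean_offspring,
              x$flower_cluster_sd,
              x$flower_parent_intensity * x$flower_mean_offspring))
  cat(sprintf("  colonies: %d-%d mounds within %g m; depletion delta=%g to %g m\n",
              x$mounds_per_colony[1], x$mounds_per_colony[2],
              x$territory_radius, x$depletion_delta, x$depletion_range))
  cat(sprintf("  colonization logit beta = (%s)\n",
              paste(format(x$colonization_beta), collapse = ", ")))
  invisible(x)
}
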