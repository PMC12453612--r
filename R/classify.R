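#' Classify yellow (dandelion flower) pixels
#'
#' A pixel is yellow when `R > 0.9`, `G > 0.9` and `B < 0.1` (strict
#' inequalities), on reflectances scaled to `[0, 1]`. Buttercup flowers are
#' also yellow and must be removed afterwards by size with
#' [filter_small_components()].
#'
#' @param scene An [rgb_scene()] with bands in `[0, 1]`.
#' @return A [pixel_mask()] labelled `"yellow"`.
#' @export
classify_yellow <- function(scene) {
  stopifnot(inherits(scene, "rgb_scene"))
  b <- scene$bands
  rng <- range(b)
  if (rng[1] < 0 || rng[2] > 1)
    stop("scene bands must be scaled to [0, 1]; divide 8-bit values by 255",
         call. = FALSE)
  m <- b[, , 1] > 0.9 & b[, , 2] > 0.9 & b[, , 3] < 0.1
  pixel_mask(m, "yellow", scene$resolution,
             provenance = list(rule = "R>0.9 & G>0.9 & B<0.1"))
}

#' Calibrate the brown-earth RGB window from training pixels
#'
#' Earth colour varies with soil humidity, so the brown window is fitted per
#' image: for each band, the window is the `[q_low, q_high]` quantile
#' envelope of user-marked bare-earth training pixels.
#'
#' @param scene An [rgb_scene()].
#' @param training_points `data.frame` with metre coordinates `x`, `y` of
#'   pixels known to be bare earth (at least 10 recommended).
#' @param probs Lower/upper quantiles of the envelope (default 1st/99th
#'   percentile).
#' @return A `brown_window`: list with per-band `c(min, max)` and the
#'   training size. Windows wider than 0.5 in any band are flagged with a
#'   warning (training pixels likely heterogeneous).
#' @export
calibrate_brown_window <- function(scene, training_points,
                                   probs = c(0.01, 0.99)) {
  stopifnot(inherits(scene, "rgb_scene"))
  if (is.null(training_points) || nrow(training_points) == 0L)
    stop("brown calibration requires training pixels", call. = FALSE)
  if (nrow(training_points) < 10L)
    warning("fewer than 10 brown training pixels; window may be unstable")
  idx <- scene_rowcol(training_points$x, training_points$y, scene)
  w <- lapply(1:3, function(b) {
    v <- scene$bands[, , b][idx]
    as.numeric(quantile(v, probs, names = FALSE))
  })
  names(w) <- c("r", "g", "b")
  if (any(vapply(w, diff, numeric(1)) > 0.5))
    warning("brown window is very wide; training pixels look heterogeneous")
  structure(c(w, list(n_training = nrow(training_points), probs = probs)),
            class = "brown_window")
}

#' @export
print.brown_window <- function(x, ...) {
  cat(sprintf("<brown_window R[%.3f,%.3f] G[%.3f,%.3f] B[%.3f,%.3f] (n=%d)>\n",
              x$r[1], x$r[2], x$g[1], x$g[2], x$b[1], x$b[2], x$n_training))
  invisible(x)
}

#' Classify brown (earth mound) pixels
#'
#' A pixel is brown when all three bands fall inside the calibrated window
#' (closed intervals).
#'
#' @param scene An [rgb_scene()].
#' @param window A `brown_window` from [calibrate_brown_window()].
#' @return A [pixel_mask()] labelled `"brown"`.
#' @export
classify_brown <- function(scene, window) {
  stopifnot(inherits(scene, "rgb_scene"), inherits(window, "brown_window"))
  b <- scene$bands
  m <- b[, , 1] >= window$r[1] & b[, , 1] <= window$r[2] &
       b[, , 2] >= window$g[1] & b[, , 2] <= window$g[2] &
       b[, , 3] >= window$b[1] & b[, , 3] <= window$b[2]
  pixel_mask(m, "brown", scene$resolution, provenance = list(window = window))
}

#' Remove small connected components from a mask
#'
#' Drops 4-connected components with fewer than `min_pixels` pixels. At 1 cm
#' resolution the default of 4 pixels (>= 4 cm^2) removes buttercup flowers
#' (~2 cm^2) while keeping dandelion flower heads (~7 cm^2). Monotone:
#' increasing `min_pixels` never increases mask area.
#'
#' @param mask A [pixel_mask()].
#' @param min_pixels Minimum component size kept (`1` is the identity).
#' @return The filtered [pixel_mask()].
#' @export
filter_small_components <- function(mask, min_pixels = 4L) {
  stopifnot(inherits(mask, "pixel_mask"), min_pixels >= 1L)
  if (min_pixels == 1L || !any(mask$mask)) return(mask)
  lab <- .label_components_cpp(mask$mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_pixels)
  out <- mask
  out$mask <- matrix(lab %in% keep, nrow(mask$mask), ncol(mask$mask))
  out$provenance$min_pixels <- min_pixels
  out
}

#' Estimate the number of dandelion flower heads from a yellow mask
#'
#' `heads = yellow area in cm^2 / 7`, since each flower head averages
#' 7 cm^2 (3 cm diameter). The fractional value is preserved; rounding is
#' the caller's choice.
#'
#' @param mask A filtered yellow [pixel_mask()].
#' @param resolution Metres per pixel (defaults to the mask's own).
#' @return Flower-head count (real).
#' @export
count_flower_heads <- function(mask, resolution = mask$resolution) {
  stopifnot(inherits(mask, "pixel_mask"))
  if (!is.numeric(resolution) || resolution <= 0)
    stop("resolution must be > 0", call. = FALSE)
  px_cm2 <- (resolution * 100)^2
  sum(mask$mask) * px_cm2 / 7
}

#' Extract mound points from a brown mask
#'
#' One point per 4-connected component, at the unweighted centroid of its
#' pixel centres, with the component area attached.
#'
#' @param mask A brown [pixel_mask()].
#' @return A [point_set()] of kind `"mound"` with an `area_m2` column.
#' @export
extract_mound_points <- function(mask) {
  stopifnot(inherits(mask, "pixel_mask"))
  if (!any(mask$mask))
    return(point_set(kind = "mound", area_m2 = numeric()))
  lab <- .label_components_cpp(mask$mask)
  pos <- which(lab > 0L)
  l <- lab[pos]
  nr <- nrow(mask$mask)
  row <- (pos - 1L) %% nr + 1L
  col <- (pos - 1L) %/% nr + 1L
  res <- mask$resolution
  height <- nr * res
  n <- tabulate(l)
  cx <- (tapply(col, l, mean) - 0.5) * res
  cy <- height - (tapply(row, l, mean) - 0.5) * res
  point_set(as.numeric(cx), as.numeric(cy), kind = "mound",
            area_m2 = n * res^2)
}

#' Write a mask as a plain-text 0/1 grid (CSV)
#'
#' @param mask A [pixel_mask()].
#' @param path Output path.
#' @export
write_mask <- function(mask, path) {
  utils::write.table(mask$mask * 1L, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
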