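#' Planar point set
#'
#' A light container for mapped points: flowers, earth mounds or buttercups,
#' in metres from the quadrat south-west corner (x east, y north).
#'
#' @param x,y Numeric coordinates in metres.
#' @param kind Point label: `"flower"`, `"mound"` or `"buttercup"`.
#' @param colony_id Optional integer colony (or subplot) membership.
#' @param area_m2 Optional per-point area (used for mounds extracted from a
#'   classified mask).
#' @return A `data.frame` of class `point_set` with columns
#'   `x`, `y`, `kind`, `colony_id` (and `area_m2` when supplied).
#' @export
point_set <- function(x = numeric(), y = numeric(),
                      kind = "flower", colony_id = NA_integer_,
                      area_m2 = NULL) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  d <- data.frame(x = as.numeric(x), y = as.numeric(y),
                  kind = rep_len(as.character(kind), n),
                  colony_id = rep_len(as.integer(colony_id), n))
  if (!is.null(area_m2)) d$area_m2 <- rep_len(as.numeric(area_m2), n)
  class(d) <- c("point_set", "data.frame")
  d
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("<point_set: %d points (%s)>\n", nrow(x),
              paste(sprintf("%s: %d", names(table(x$kind)),
                            as.integer(table(x$kind))), collapse = ", ")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

# keep class on row subsetting
#' @export
`[.point_set` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- c("point_set", "data.frame")
  out
}

#' RGB scene raster
#'
#' A 3-band raster of reflectances in `[0, 1]`. Stored as an
#' `nrow x ncol x 3` array; row 1 is the northern edge of the quadrat,
#' column 1 the western edge, and point coordinates are metres from the
#' south-west corner. Pixel `(i, j)` has centre
#' `x = (j - 0.5) * res`, `y = height - (i - 0.5) * res`.
#'
#' @param bands Numeric array `c(nrow, ncol, 3)` with values in `[0, 1]`.
#' @param resolution Metres per pixel.
#' @return An object of class `rgb_scene`.
#' @export
rgb_scene <- function(bands, resolution) {
  stopifnot(is.array(bands), length(dim(bands)) == 3L, dim(bands)[3] == 3L,
            resolution > 0)
  structure(list(bands = bands, resolution = resolution,
                 width = dim(bands)[2] * resolution,
                 height = dim(bands)[1] * resolution),
            class = "rgb_scene")
}

#' @export
print.rgb_scene <- function(x, ...) {
  cat(sprintf("<rgb_scene: %d x %d px (%g m x %g m at %g m/px)>\n",
              nrow(x$bands), ncol(x$bands), x$width, x$height, x$resolution))
  invisible(x)
}

#' @export
dim.rgb_scene <- function(x) dim(x$bands)

#' Convert metre coordinates to pixel (row, col) indices
#'
#' Uses the pixel-centre rule on the scene's half-open pixel grid; points on
#' the far east/north edge fold into the last pixel.
#'
#' @param x,y Coordinates in metres from the south-west corner.
#' @param scene An `rgb_scene` (or anything with `$resolution`, `$height`,
#'   `$width`).
#' @return A two-column integer matrix `(row, col)`.
#' @keywords internal
scene_rowcol <- function(x, y, scene) {
  res <- scene$resolution
  nr <- round(scene$height / res); nc <- round(scene$width / res)
  col <- pmin(pmax(floor(x / res) + 1L, 1L), nc)
  row <- pmin(pmax(floor((scene$height - y) / res) + 1L, 1L), nr)
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Binary pixel mask
#'
#' @param m Logical matrix aligned with its source scene.
#' @param label `"yellow"` or `"brown"`.
#' @param resolution Metres per pixel, inherited from the source scene.
#' @param provenance List recording the thresholds that produced the mask.
#' @return Object of class `pixel_mask`.
#' @export
pixel_mask <- function(m, label, resolution, provenance = list()) {
  stopifnot(is.matrix(m), is.logical(m))
  structure(list(mask = m, label = label, resolution = resolution,
                 provenance = provenance),
            class = "pixel_mask")
}

#' @export
print.pixel_mask <- function(x, ...) {
  cat(sprintf("<pixel_mask [%s]: %d x %d px, %d positive (%.3f%%)>\n",
              x$label, nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

#' Read or write a point set as CSV
#'
#' Columns `x_m, y_m, kind, colony_id` (plus `area_m2` when present).
#'
#' @param p A `point_set`.
#' @param path File path.
#' @export
write_point_set <- function(p, path) {
  d <- as.data.frame(p)
  names(d)[names(d) == "x"] <- "x_m"
  names(d)[names(d) == "y"] <- "y_m"
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_point_set
#' @param path File path.
#' @export
read_point_set <- function(path) {
  d <- utils::read.csv(path)
  point_set(d$x_m, d$y_m, kind = d$kind,
            colony_id = if ("colony_id" %in% names(d)) d$colony_id else NA,
            area_m2 = if ("area_m2" %in% names(d)) d$area_m2 else NULL)
}
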