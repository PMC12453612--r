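#' Build the tile grid of a quadrat
#'
#' Half-open `tile_size x tile_size` tiles covering the quadrat exactly
#' once; an 80 m x 60 m quadrat at 2 m gives the 1200 analysis tiles.
#' Tiles are indexed column-major from the south-west corner:
#' `tile = (tile_y - 1) * n_x + tile_x`.
#'
#' @param quadrat_width,quadrat_height Quadrat dimensions in metres.
#' @param tile_size Tile side in metres; must divide both dimensions (the
#'   design has no partial tiles).
#' @return A `tile_grid`: list with `n_x`, `n_y`, `tile_size`, `n_tiles`.
#' @export
build_tile_grid <- function(quadrat_width, quadrat_height, tile_size = 2) {
  stopifnot(quadrat_width > 0, quadrat_height > 0, tile_size > 0)
  nx <- quadrat_width / tile_size
  ny <- quadrat_height / tile_size
  if (abs(nx - round(nx)) > 1e-9 || abs(ny - round(ny)) > 1e-9)
    stop("tile_size must divide both quadrat dimensions (no partial tiles)",
         call. = FALSE)
  structure(list(n_x = as.integer(round(nx)), n_y = as.integer(round(ny)),
                 tile_size = tile_size,
                 n_tiles = as.integer(round(nx) * round(ny))),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid: %d x %d tiles of %g m (%d tiles)>\n",
              x$n_x, x$n_y, x$tile_size, x$n_tiles))
  invisible(x)
}

# sum an nr x nc matrix over b x b pixel blocks -> (nr/b) x (nc/b)
block_sums <- function(m, b) {
  nr <- nrow(m); nc <- ncol(m)
  storage.mode(m) <- "double"
  dim(m) <- c(b, nr %/% b, nc)
  s <- colSums(m)                      # (nr/b) x nc
  s <- t(s)                            # nc x (nr/b)
  dim(s) <- c(b, nc %/% b, nr %/% b)
  t(colSums(s))                        # (nr/b) x (nc/b)
}

# per-tile pixel sums of a mask, returned as a tile-indexed vector
tile_pixel_sums <- function(mask, grid) {
  b <- grid$tile_size / mask$resolution
  if (abs(b - round(b)) > 1e-9)
    stop("mask resolution does not align with the tile grid", call. = FALSE)
  b <- as.integer(round(b))
  m <- mask$mask
  if (nrow(m) != b * grid$n_y || ncol(m) != b * grid$n_x)
    stop("mask dimensions do not match the tile grid", call. = FALSE)
  s <- block_sums(m, b)                # rows north -> south
  # flip rows so tile_y counts from the south edge, then flatten column-major
  s <- s[grid$n_y:1, , drop = FALSE]
  as.numeric(t(s))
}

#' Per-tile cover of a mask
#'
#' Fraction of each tile's pixels set in the mask (a 2 m tile holds 40,000
#' pixels at 1 cm resolution). Per-tile sums conserve the whole-quadrat
#' total exactly.
#'
#' @param brown_mask A [pixel_mask()] aligned with the grid.
#' @param grid A [build_tile_grid()] grid.
#' @return `data.frame` with `tile`, `tile_x`, `tile_y`, `cover`.
#' @export
tile_mound_cover <- function(brown_mask, grid) {
  stopifnot(inherits(brown_mask, "pixel_mask"), inherits(grid, "tile_grid"))
  px_per_tile <- (grid$tile_size / brown_mask$resolution)^2
  s <- tile_pixel_sums(brown_mask, grid)
  data.frame(tile = seq_len(grid$n_tiles),
             tile_x = rep(seq_len(grid$n_x), times = grid$n_y),
             tile_y = rep(seq_len(grid$n_y), each = grid$n_x),
             cover = s / px_per_tile)
}

#' Per-tile dandelion flower-head counts and densities
#'
#' Converts a filtered yellow mask into per-tile flower-head counts
#' (yellow cm^2 / 7), tile density `D_t` (heads per m^2), the quadrat mean
#' density `D_q` (unweighted mean of tile densities) and the anomaly index.
#'
#' @inheritParams tile_mound_cover
#' @param yellow_mask A filtered yellow [pixel_mask()].
#' @return `data.frame` with `tile`, `tile_x`, `tile_y`, `flower_heads`,
#'   `d_t`, `d_q`, `anom`.
#' @export
tile_flower_density <- function(yellow_mask, grid) {
  stopifnot(inherits(yellow_mask, "pixel_mask"), inherits(grid, "tile_grid"))
  px_cm2 <- (yellow_mask$resolution * 100)^2
  s <- tile_pixel_sums(yellow_mask, grid)
  heads <- s * px_cm2 / 7
  d_t <- heads / grid$tile_size^2
  d_q <- mean(d_t)
  data.frame(tile = seq_len(grid$n_tiles),
             tile_x = rep(seq_len(grid$n_x), times = grid$n_y),
             tile_y = rep(seq_len(grid$n_y), each = grid$n_x),
             flower_heads = heads, d_t = d_t, d_q = d_q,
             anom = if (d_q > 0) dandelion_anomaly(d_t, d_q)
                    else rep(NA_real_, length(d_t)))
}

#' Colonization rule for a tile
#'
#' A tile counts as colonized when earth mounds cover strictly more than
#' 2.5 % of its surface (the cover of 10 small mounds of 5 cm radius).
#'
#' @param cover Mound cover fraction(s) in `[0, 1]`.
#' @param threshold Cover threshold (default 0.025).
#' @return Logical vector.
#' @export
tile_colonized <- function(cover, threshold = 0.025) {
  stopifnot(all(is.na(cover) | (cover >= 0 & cover <= 1)))
  cover > threshold
}

#' Dandelion anomaly index
#'
#' Compares a tile's flower density with the quadrat mean on a fourth-root
#' scale, centred at zero: `Anom = (d_t / d_q)^(1/4) - 1`. A tile at the
#' quadrat mean scores 0; a tile at five times the mean scores
#' `5^(1/4) - 1 = 0.495`; an empty tile scores -1. Undefined (NA, with a
#' warning) when `d_q = 0`; such tiles are excluded from anomaly-based
#' models.
#'
#' @param d_t Tile flower density (heads / m^2).
#' @param d_q Quadrat mean flower density (heads / m^2).
#' @return Numeric anomaly values in `[-1, Inf)`.
#' @export
dandelion_anomaly <- function(d_t, d_q) {
  if (any(d_t < 0, na.rm = TRUE) || any(d_q < 0, na.rm = TRUE))
    stop("densities must be non-negative", call. = FALSE)
  out <- (d_t / d_q)^0.25 - 1
  bad <- !is.na(d_q) & d_q == 0
  if (any(bad)) {
    warning("anomaly undefined where the quadrat mean density is 0")
    out[bad] <- NA_real_
  }
  out
}

#' Label new colonizations between a March and an October survey
#'
#' Restricts to tiles not colonized in March and scores the binary response
#' `col`: 1 if the tile is colonized in the October image, 0 otherwise.
#'
#' @param march,october `data.frame`s with columns `tile` and `colonized`
#'   on the same grid (e.g. from [tile_mound_cover()] + [tile_colonized()]).
#' @return The March-uncolonized subset with a `col` column.
#' @export
label_new_colonization <- function(march, october) {
  if (!identical(march$tile, october$tile))
    stop("March and October tables are not on the same tile grid",
         call. = FALSE)
  keep <- !march$colonized
  out <- march[keep, c("tile", intersect(c("tile_x", "tile_y"), names(march))),
               drop = FALSE]
  out$col <- as.integer(october$colonized[keep])
  out
}

#' Label burrow reuse across years
#'
#' Restricts to tiles colonized in both October of year 1 and March of
#' year 2 and scores `reuse`: 1 if still colonized in October of year 2
#' (reused), 0 if abandoned.
#'
#' @param oct_y1,march_y2,oct_y2 Aligned tile tables with `tile` and
#'   `colonized`.
#' @return The subset with a `reuse` column.
#' @export
label_reuse <- function(oct_y1, march_y2, oct_y2) {
  if (!identical(oct_y1$tile, march_y2$tile) ||
      !identical(oct_y1$tile, oct_y2$tile))
    stop("tile tables are not on the same grid", call. = FALSE)
  keep <- oct_y1$colonized & march_y2$colonized
  out <- oct_y1[keep, c("tile", intersect(c("tile_x", "tile_y"),
                                          names(oct_y1))), drop = FALSE]
  out$reuse <- as.integer(oct_y2$colonized[keep])
  out
}

#' Dandelion population growth rate of a tile
#'
#' `DPGR = ln(flowers in year 2 / flowers in year 1)`, with optional
#' per-year scalar corrections for flowering-stage differences (heads per
#' plant); both default to 1 (no correction). Undefined (NA) when either
#' year has no flowers; such tiles are excluded from the growth model.
#'
#' @param flowers_y1,flowers_y2 Flower-head counts per tile.
#' @param correction_y1,correction_y2 Scalar flowering-stage corrections.
#' @return Numeric DPGR values.
#' @export
compute_dpgr <- function(flowers_y1, flowers_y2,
                         correction_y1 = 1, correction_y2 = 1) {
  stopifnot(correction_y1 > 0, correction_y2 > 0)
  out <- log((flowers_y2 * correction_y2) / (flowers_y1 * correction_y1))
  out[!is.na(flowers_y1) & !is.na(flowers_y2) &
        (flowers_y1 <= 0 | flowers_y2 <= 0)] <- NA_real_
  out
}

#' Assemble the tile table of a simulated survey series
#'
#' Runs the full classification chain (yellow rule, buttercup size filter,
#' per-date brown window calibrated on true mound pixels, 2.5 % colonization
#' rule) on each rendered date of a [simulate_series()] object and joins the
#' results into one record per tile: cover and colonization per date,
#' May densities and anomaly per year, the Q1/Q2 responses and DPGR.
#'
#' @param series A rendered `vole_series`.
#' @param quadrat_id Label stored in the `quadrat` column.
#' @param min_pixels Buttercup size filter passed to
#'   [filter_small_components()].
#' @return `data.frame` with one row per tile.
#' @export
tile_table_from_series <- function(series, quadrat_id = "Q1",
                                   min_pixels = 4L) {
  stopifnot(inherits(series, "vole_series"))
  params <- series$params
  grid <- build_tile_grid(params$quadrat_width, params$quadrat_height)
  if (is.null(series$dates[[1]]$scene))
    stop("series was simulated with render = FALSE", call. = FALSE)

  classify_date <- function(d) {
    sc <- d$scene
    if (nrow(d$mounds)) {
      # calibrate on known mound interiors (field workflow: user-marked px)
      tr <- d$mounds[seq_len(min(50L, nrow(d$mounds))), c("x", "y")]
      win <- calibrate_brown_window(sc, tr)
      brown <- classify_brown(sc, win)
    } else {
      brown <- pixel_mask(matrix(FALSE, nrow(sc$bands), ncol(sc$bands)),
                          "brown", sc$resolution)
    }
    cov <- tile_mound_cover(brown, grid)
    cov$colonized <- tile_colonized(cov$cover)
    cov
  }
  may_density <- function(d) {
    yellow <- filter_small_components(classify_yellow(d$scene), min_pixels)
    tile_flower_density(yellow, grid)
  }

  cov <- lapply(series$dates, classify_date)
  may1 <- may_density(series$dates$may_y1)
  may2 <- may_density(series$dates$may_y2)

  out <- data.frame(quadrat = quadrat_id,
                    tile = may1$tile, tile_x = may1$tile_x,
                    tile_y = may1$tile_y)
  for (nm in names(cov)) {
    out[[paste0("cover_", nm)]] <- cov[[nm]]$cover
    out[[paste0("col_", nm)]] <- cov[[nm]]$colonized
  }
  out$flowers_may_y1 <- may1$flower_heads
  out$flowers_may_y2 <- may2$flower_heads
  out$d_t_y1 <- may1$d_t; out$d_q_y1 <- may1$d_q; out$anom_y1 <- may1$anom
  out$d_t_y2 <- may2$d_t; out$d_q_y2 <- may2$d_q; out$anom_y2 <- may2$anom
  out$dpgr <- compute_dpgr(out$flowers_may_y1, out$flowers_may_y2)
  out
}

#' Write a tile table with Table-1-style column names
#'
#' Renames the analysis columns to the symbols of the model glossary
#' (Q, D_t, D_q, Anom, Col, Reuse, Cover, DPGR) where present.
#'
#' @param tiles Tile `data.frame`.
#' @param path Output CSV path.
#' @export
write_tile_table <- function(tiles, path) {
  ren <- c(quadrat = "Q", d_t = "D_t", d_q = "D_q", anom = "Anom",
           col = "Col", reuse = "Reuse", cover_pct = "Cover", dpgr = "DPGR")
  nm <- names(tiles)
  hit <- nm %in% names(ren)
  nm[hit] <- ren[nm[hit]]
  names(tiles) <- nm
  utils::write.csv(tiles, path, row.names = FALSE)
  invisible(path)
}
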