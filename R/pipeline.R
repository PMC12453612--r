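#' @importFrom stats formula
#' @importFrom utils write.csv packageVersion
NULL

# deterministic per-stage seed derived from the run seed; kept below 2^31
derive_seed <- function(seed, stage_index) {
  as.integer((as.double(seed) * 48271 + stage_index * 104729) %% 2147483647L)
}

#' Run configuration
#'
#' Bundles everything a reproducible end-to-end run needs: input mode,
#' scene parameters, classification and model settings, seed and output
#' directory. Exactly one input mode is active: `"synthetic"` simulates
#' quadrat series, `"tables"` consumes a previously written tile-table CSV.
#'
#' @param mode `"synthetic"` or `"tables"`.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer run seed; every stage derives its own stream from it.
#' @param params A [scene_params()] (synthetic mode).
#' @param n_quadrats Quadrats to simulate (synthetic mode; at least 2 so the
#'   fixed quadrat factor is estimable).
#' @param n_subplots Fine-scale subplots to simulate.
#' @param questions Which analyses to run: subset of `"q1"`, `"q2"`, `"q3"`.
#' @param ladder Also evaluate the full candidate ladders.
#' @param min_pixels Buttercup component-size filter.
#' @param tile_table Path to a tile-table CSV (tables mode).
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("synthetic", "tables"),
                       out_dir = tempfile("volescape_run_"),
                       seed = 1L,
                       params = scene_params(),
                       n_quadrats = 4L,
                       n_subplots = 46L,
                       questions = c("q1", "q2", "q3"),
                       ladder = TRUE,
                       min_pixels = 4L,
                       tile_table = NULL) {
  mode <- match.arg(mode)
  if (mode == "tables" && is.null(tile_table))
    stop("tables mode needs a tile_table path", call. = FALSE)
  questions <- if (length(questions))
    match.arg(questions, c("q1", "q2", "q3"), several.ok = TRUE)
  else character(0)
  structure(list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
                 params = params, n_quadrats = as.integer(n_quadrats),
                 n_subplots = as.integer(n_subplots),
                 questions = questions,
                 ladder = isTRUE(ladder), min_pixels = as.integer(min_pixels),
                 tile_table = tile_table),
            class = "run_config")
}

#' Read a run configuration from a key = value text file
#'
#' Lines of the form `key = value`; `#` starts a comment. Keys prefixed
#' `scene.` set the corresponding [scene_params()] argument; vector values
#' are comma-separated. Unknown keys raise an error.
#'
#' @param path Config file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  parse_val <- function(v) {
    parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else parts
  }
  scene_keys <- grepl("^scene\\.", keys)
  scene_args <- lapply(vals[scene_keys], parse_val)
  names(scene_args) <- sub("^scene\\.", "", keys[scene_keys])
  run_args <- lapply(vals[!scene_keys], parse_val)
  names(run_args) <- keys[!scene_keys]
  bad <- setdiff(names(run_args),
                 c("mode", "out_dir", "seed", "n_quadrats", "n_subplots",
                   "questions", "ladder", "min_pixels", "tile_table"))
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  if ("ladder" %in% names(run_args))
    run_args$ladder <- run_args$ladder %in% c("true", "TRUE", "1", 1)
  run_args$params <- do.call(scene_params, scene_args)
  do.call(run_config, run_args)
}

write_stage_csv <- function(d, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(d, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order — simulate, classify + tile,
#' broad-scale model fits (with optional candidate ladders), fine-scale
#' depletion — writing every intermediate table as CSV plus a JSON manifest
#' recording the stages, output files, MD5 checksums, seed and package
#' version. Record counts after each subsetting step are logged to the
#' console, mirroring the reported dataset sizes of a field campaign.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage logging.
#' @return The manifest, invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  outputs <- character(0)
  stages <- character(0)

  if (config$mode == "synthetic") {
    stages <- c(stages, "simulate", "tiles")
    tiles_all <- vector("list", config$n_quadrats)
    for (q in seq_len(config$n_quadrats)) {
      qid <- sprintf("Q%02d", q)
      say("stage simulate: quadrat %s", qid)
      ser <- simulate_series(config$params,
                             seed = derive_seed(config$seed, q))
      for (nm in c("may_y1", "october_y1")) {
        f <- file.path(config$out_dir,
                       sprintf("points_%s_%s.csv", qid, nm))
        pts <- rbind(ser$dates[[nm]]$flowers, ser$dates[[nm]]$mounds[
          , c("x", "y", "kind", "colony_id")])
        write_point_set(point_set(pts$x, pts$y, pts$kind, pts$colony_id), f)
        outputs <- c(outputs, f)
      }
      tiles_all[[q]] <- tile_table_from_series(ser, quadrat_id = qid,
                                               min_pixels = config$min_pixels)
    }
    tiles <- do.call(rbind, tiles_all)
    outputs <- c(outputs, write_stage_csv(tiles, config$out_dir, "tiles.csv"))
    say("stage tiles: %d tile records from %d quadrats",
        nrow(tiles), config$n_quadrats)
  } else {
    stages <- c(stages, "tables")
    tiles <- utils::read.csv(config$tile_table)
    say("stage tables: %d tile records read", nrow(tiles))
  }

  manifest_fits <- list()
  if ("q1" %in% config$questions) {
    stages <- c(stages, "fit_q1")
    # pool the two annual March -> October transitions (year-varying
    # dandelion density separates d_q from the fixed quadrat factor)
    t1 <- data.frame(quadrat = tiles$quadrat, year = 1L,
                     col = as.integer(tiles$col_october_y1),
                     anom = tiles$anom_y1, d_t = tiles$d_t_y1,
                     d_q = tiles$d_q_y1)[!tiles$col_march_y1, ]
    t2 <- data.frame(quadrat = tiles$quadrat, year = 2L,
                     col = as.integer(tiles$col_october_y2),
                     anom = tiles$anom_y2, d_t = tiles$d_t_y2,
                     d_q = tiles$d_q_y2)[!tiles$col_march_y2, ]
    sub <- rbind(t1, t2)
    sub <- sub[!is.na(sub$anom), ]
    say("stage fit_q1: %d uncolonized tiles, %d colonized by October (%.1f%%)",
        nrow(sub), sum(sub$col), 100 * mean(sub$col))
    fit <- try(fit_colonization_model(sub), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      co <- data.frame(term = rownames(fit$coefficients),
                       fit$coefficients, row.names = NULL, check.names = FALSE)
      outputs <- c(outputs, write_stage_csv(co, config$out_dir, "q1_coefficients.csv"))
      curves <- predict_response_curves(fit, sub)
      outputs <- c(outputs, write_stage_csv(curves, config$out_dir, "q1_curves.csv"))
      manifest_fits$q1 <- list(label = fit$label, aic = fit$aic,
                               explained_variance = fit$explained_variance)
      if (config$ladder)
        outputs <- c(outputs, write_stage_csv(colonization_ladder(sub),
                                              config$out_dir, "q1_ladder.csv"))
    } else say("stage fit_q1 failed: %s", attr(fit, "condition")$message)
  }
  if ("q2" %in% config$questions) {
    stages <- c(stages, "fit_q2")
    keep <- tiles$col_october_y1 & tiles$col_march_y2
    sub <- data.frame(quadrat = tiles$quadrat,
                      reuse = as.integer(tiles$col_october_y2),
                      anom = tiles$anom_y2, d_t = tiles$d_t_y2,
                      d_q = tiles$d_q_y2)[keep, ]
    say("stage fit_q2: %d tiles colonized in both surveys, %d reused (%.1f%%)",
        nrow(sub), sum(sub$reuse), 100 * mean(sub$reuse))
    fit <- try(fit_reuse_model(sub), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      co <- data.frame(term = rownames(fit$coefficients),
                       fit$coefficients, row.names = NULL, check.names = FALSE)
      outputs <- c(outputs, write_stage_csv(co, config$out_dir, "q2_coefficients.csv"))
      manifest_fits$q2 <- list(label = fit$label, aic = fit$aic,
                               explained_variance = fit$explained_variance)
      if (config$ladder)
        outputs <- c(outputs, write_stage_csv(reuse_ladder(sub),
                                              config$out_dir, "q2_ladder.csv"))
    } else say("stage fit_q2 failed: %s", attr(fit, "condition")$message)
  }
  if ("q3" %in% config$questions) {
    stages <- c(stages, "fit_q3", "depletion")
    sub <- data.frame(quadrat = tiles$quadrat, dpgr = tiles$dpgr,
                      cover_pct = 100 * tiles$cover_march_y2)[
      !tiles$col_may_y1 & !is.na(tiles$dpgr), ]
    say("stage fit_q3: %d tiles uncolonized in May year 1 with defined DPGR",
        nrow(sub))
    fit <- try(fit_dpgr_model(sub), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      co <- data.frame(term = rownames(fit$coefficients),
                       fit$coefficients, row.names = NULL, check.names = FALSE)
      outputs <- c(outputs, write_stage_csv(co, config$out_dir, "q3_coefficients.csv"))
      manifest_fits$q3 <- list(label = fit$label, aic = fit$aic,
                               explained_variance = fit$explained_variance)
      if (config$ladder)
        outputs <- c(outputs, write_stage_csv(dpgr_ladder(sub),
                                              config$out_dir, "q3_ladder.csv"))
    } else say("stage fit_q3 failed: %s", attr(fit, "condition")$message)

    say("stage depletion: %d subplots", config$n_subplots)
    sp <- simulate_subplots(config$n_subplots, config$params,
                            seed = derive_seed(config$seed, 1000L))
    rec <- depletion_profiles(sp)
    outputs <- c(outputs, write_stage_csv(rec, config$out_dir,
                                          "depletion_profile.csv"))
    dfit <- fit_depletion_gam(rec)
    outputs <- c(outputs, write_stage_csv(dfit$curve, config$out_dir,
                                          "depletion_curve.csv"))
    if (config$ladder)
      outputs <- c(outputs, write_stage_csv(depletion_ladder(rec),
                                            config$out_dir,
                                            "depletion_ladder.csv"))
    manifest_fits$depletion <- list(aic = dfit$aic,
                                    measurable_range_m = dfit$measurable_range_m)
  }

  manifest <- list(
    package = "volescape",
    version = as.character(utils::packageVersion("volescape")),
    seed = config$seed, mode = config$mode, stages = stages,
    fits = manifest_fits,
    outputs = lapply(outputs, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("run complete: %d output files in %s", length(outputs), config$out_dir)
  invisible(manifest)
}
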