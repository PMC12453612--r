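#' @importFrom stats glm lm binomial gaussian as.formula logLik AIC coef
#'   deviance predict update terms model.matrix
NULL

# wrap a fitted (g)lm into the package's fit container; a degenerate
# (constant-response) fit has no defined explained variance
new_vole_fit <- function(fit, label, data) {
  ev <- tryCatch(explained_variance(fit), error = function(e) NA_real_)
  structure(list(fit = fit, label = label,
                 coefficients = summary(fit)$coefficients,
                 loglik = as.numeric(logLik(fit)),
                 df = attr(logLik(fit), "df"),
                 aic = AIC(fit),
                 explained_variance = ev,
                 n = length(fit$residuals)),
            class = "vole_fit")
}

#' @export
print.vole_fit <- function(x, ...) {
  cat(sprintf("<vole_fit: %s>\n  n = %d, df = %d, AIC = %.1f, explained variance = %.3f\n",
              x$label, x$n, x$df, x$aic, x$explained_variance))
  co <- x$coefficients
  keep <- !grepl("^quadrat", rownames(co))
  print(round(co[keep, , drop = FALSE], 4))
  invisible(x)
}

#' Deviance-based explained variance
#'
#' For GLMs, `1 - residual deviance / null deviance`, where the null model
#' is intercept-only (without the quadrat factor); for ordinary least
#' squares, the usual R-squared. Lies in `[0, 1]` for any converged fit.
#'
#' @param fit A `glm`, `lm`, `gam` or `vole_fit` object.
#' @return Fraction of deviance (variance) explained.
#' @export
explained_variance <- function(fit) {
  if (inherits(fit, "vole_fit")) fit <- fit$fit
  if (inherits(fit, "gam") || inherits(fit, "glm")) {
    if (fit$null.deviance <= 0)
      stop("null deviance is zero: explained variance undefined",
           call. = FALSE)
    return(1 - fit$deviance / fit$null.deviance)
  }
  if (inherits(fit, "lm")) return(summary(fit)$r.squared)
  stop("unsupported fit object", call. = FALSE)
}

check_quadrat_levels <- function(data, response) {
  tab <- table(data$quadrat, data[[response]])
  if (any(rowSums(tab > 0) < 2L))
    warning("some quadrats have a single outcome level; ",
            "their fixed effects are weakly identified")
}

#' Fit the tile colonization model (Q1)
#'
#' Binomial logit GLM of new-colonization on the dandelion anomaly, the
#' quadrat mean density and their interaction, with the quadrat identifier
#' as a fixed categorical: `col ~ anom * d_q + quadrat`. The input is the
#' March-uncolonized subset; rows with undefined anomaly are dropped.
#'
#' @param tiles `data.frame` with columns `col` (0/1), `anom`, `d_q`,
#'   `quadrat`.
#' @return A `vole_fit`.
#' @export
fit_colonization_model <- function(tiles) {
  stopifnot(all(c("col", "anom", "d_q", "quadrat") %in% names(tiles)))
  tiles <- tiles[!is.na(tiles$anom), , drop = FALSE]
  tiles$quadrat <- factor(tiles$quadrat)
  check_quadrat_levels(tiles, "col")
  f <- glm(col ~ anom * d_q + quadrat, family = binomial(), data = tiles)
  # a residual deviance near 0 is a degenerate (constant/saturated) response,
  # not a separation failure
  if (!f$converged && f$deviance > 1e-6)
    stop("colonization model did not converge (possible separation)",
         call. = FALSE)
  new_vole_fit(f, "col ~ anom * d_q + quadrat", tiles)
}

#' Fit the burrow reuse model (Q2)
#'
#' Binomial logit GLM of reuse on the May year-2 tile density and its
#' interaction with the quadrat mean density (no `d_q` main effect, which
#' the fixed quadrat factor absorbs): `reuse ~ d_t + d_t:d_q + quadrat`.
#'
#' @param tiles `data.frame` with columns `reuse` (0/1), `d_t`, `d_q`,
#'   `quadrat`.
#' @return A `vole_fit`.
#' @export
fit_reuse_model <- function(tiles) {
  stopifnot(all(c("reuse", "d_t", "d_q", "quadrat") %in% names(tiles)))
  tiles$quadrat <- factor(tiles$quadrat)
  if (length(unique(tiles$d_q)) == 1L)
    warning("d_q is constant: the d_t:d_q interaction is collinear with d_t")
  check_quadrat_levels(tiles, "reuse")
  f <- glm(reuse ~ d_t + d_t:d_q + quadrat, family = binomial(), data = tiles)
  if (!f$converged && f$deviance > 1e-6)
    stop("reuse model did not converge (possible separation)", call. = FALSE)
  new_vole_fit(f, "reuse ~ d_t + d_t:d_q + quadrat", tiles)
}

#' Fit the dandelion growth-rate model (broad-scale Q3)
#'
#' Ordinary least squares of the tile log growth rate on log mound cover:
#' `dpgr ~ log(cover_pct + 1) + quadrat`, where `cover_pct` is the March
#' year-2 mound cover of the tile in percent. The input is the subset of
#' tiles not colonized in May of year 1 with a defined DPGR.
#'
#' @param tiles `data.frame` with columns `dpgr`, `cover_pct`, `quadrat`.
#' @return A `vole_fit`.
#' @export
fit_dpgr_model <- function(tiles) {
  stopifnot(all(c("dpgr", "cover_pct", "quadrat") %in% names(tiles)))
  tiles <- tiles[!is.na(tiles$dpgr), , drop = FALSE]
  if (length(unique(tiles$cover_pct)) == 1L)
    stop("cover is constant: slope is not identifiable", call. = FALSE)
  tiles$quadrat <- factor(tiles$quadrat)
  f <- lm(dpgr ~ log(cover_pct + 1) + quadrat, data = tiles)
  new_vole_fit(f, "dpgr ~ log(cover_pct + 1) + quadrat", tiles)
}

# fit one formula, returning NA rows on failure rather than dropping it
fit_one_ladder_row <- function(formula, data, family) {
  label <- paste(deparse(formula), collapse = "")
  f <- tryCatch({
    if (is.null(family)) lm(formula, data = data)
    else glm(formula, family = family, data = data)
  }, error = function(e) NULL)
  if (is.null(f) || (inherits(f, "glm") && !f$converged))
    return(data.frame(model = label, df = NA_real_, aic = NA_real_,
                      explained_variance = NA_real_))
  data.frame(model = label, df = attr(logLik(f), "df"), aic = AIC(f),
             explained_variance = explained_variance(f))
}

#' Evaluate an explicit ladder of candidate models
#'
#' Fits each formula on the same data and tabulates degrees of freedom,
#' AIC, delta-AIC relative to the best model and explained variance —
#' the layout of the published model-selection table. Models that fail to
#' converge are recorded with missing AIC, never dropped silently.
#'
#' @param data Model frame.
#' @param formulas Named list (or character vector) of model formulas.
#' @param family A [stats::binomial()]-style family, or `NULL` for ordinary
#'   least squares.
#' @return An `aic_table` `data.frame`: `model`, `df`, `aic`, `delta_aic`,
#'   `explained_variance`, in the given ladder order.
#' @export
aic_ladder <- function(data, formulas, family = binomial()) {
  rows <- lapply(formulas, function(f)
    fit_one_ladder_row(as.formula(f), data, family))
  out <- do.call(rbind, rows)
  if (!is.null(names(formulas))) out$model <- names(formulas)
  rownames(out) <- NULL
  out$delta_aic <- out$aic - min(out$aic, na.rm = TRUE)
  out <- out[, c("model", "df", "aic", "delta_aic", "explained_variance")]
  class(out) <- c("aic_table", "data.frame")
  out
}

#' @export
print.aic_table <- function(x, digits = 1, ...) {
  cat("Model selection table\n")
  y <- as.data.frame(x)
  y$aic <- round(y$aic, digits); y$delta_aic <- round(y$delta_aic, digits)
  y$explained_variance <- round(y$explained_variance, 3)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Forward-stepwise AIC selection
#'
#' Greedy forward search from `response ~ base_terms`: at each step the
#' candidate term whose addition lowers AIC the most is added, until no
#' addition improves AIC. Interaction candidates (containing `:`) are only
#' eligible once their main effects are in the model, except candidates
#' explicitly listed with their own main-effect absent (e.g. `d_t:d_q`).
#' Ties are broken toward fewer parameters (no addition).
#'
#' @param data Model frame.
#' @param response Response column name.
#' @param candidates Character vector of candidate terms, e.g.
#'   `c("anom", "d_t", "d_q", "anom:d_q")`.
#' @param base_terms Terms always present (default the quadrat factor).
#' @param family GLM family, or `NULL` for least squares.
#' @return List with `selected` (formula string) and `path`, an `aic_table`
#'   of every model visited in search order.
#' @export
forward_stepwise_aic <- function(data, response, candidates,
                                 base_terms = "quadrat",
                                 family = binomial()) {
  current <- base_terms
  make_f <- function(tr) as.formula(paste(response, "~",
                                          paste(tr, collapse = " + ")))
  visited <- list()
  row0 <- fit_one_ladder_row(make_f(current), data, family)
  row0$model <- paste(response, "~", paste(current, collapse = " + "))
  visited[[1]] <- row0
  best_aic <- row0$aic
  remaining <- candidates
  repeat {
    main_in <- current[!grepl(":", current)]
    ok <- vapply(remaining, function(tr) {
      parts <- strsplit(tr, ":", fixed = TRUE)[[1]]
      length(parts) == 1L || all(parts %in% main_in) ||
        !any(parts %in% remaining)
    }, logical(1))
    trial <- remaining[ok]
    if (!length(trial)) break
    rows <- lapply(trial, function(tr)
      fit_one_ladder_row(make_f(c(current, tr)), data, family))
    aics <- vapply(rows, function(r) r$aic, numeric(1))
    visited <- c(visited, rows)
    if (all(is.na(aics)) || min(aics, na.rm = TRUE) >= best_aic) break
    j <- which.min(aics)
    current <- c(current, trial[j])
    remaining <- setdiff(remaining, trial[j])
    best_aic <- aics[j]
  }
  path <- do.call(rbind, visited)
  rownames(path) <- NULL
  path$delta_aic <- path$aic - min(path$aic, na.rm = TRUE)
  path <- path[, c("model", "df", "aic", "delta_aic", "explained_variance")]
  class(path) <- c("aic_table", "data.frame")
  list(selected = paste(response, "~", paste(current, collapse = " + ")),
       path = path)
}

#' The published candidate ladders
#'
#' Explicit model lists of the three broad-scale selection panels:
#' colonization (9 models), reuse (6 models) and dandelion growth rate
#' (3 models), each with the quadrat identifier as a fixed term.
#'
#' @param tiles Model frame with the columns the panel needs.
#' @return An `aic_table`.
#' @name model_ladders
NULL

#' @rdname model_ladders
#' @export
colonization_ladder <- function(tiles) {
  tiles <- tiles[!is.na(tiles$anom), , drop = FALSE]
  tiles$quadrat <- factor(tiles$quadrat)
  aic_ladder(tiles, list(
    "col ~ 1 + Q"               = col ~ 1 + quadrat,
    "col ~ anom + Q"            = col ~ anom + quadrat,
    "col ~ d_t + Q"             = col ~ d_t + quadrat,
    "col ~ d_q + Q"             = col ~ d_q + quadrat,
    "col ~ d_t + d_t:d_q + Q"   = col ~ d_t + d_t:d_q + quadrat,
    "col ~ anom + d_t + Q"      = col ~ anom + d_t + quadrat,
    "col ~ anom + d_q + Q"      = col ~ anom + d_q + quadrat,
    "col ~ anom * d_t + Q"      = col ~ anom * d_t + quadrat,
    "col ~ anom * d_q + Q"      = col ~ anom * d_q + quadrat
  ), family = binomial())
}

#' @rdname model_ladders
#' @export
reuse_ladder <- function(tiles) {
  tiles$quadrat <- factor(tiles$quadrat)
  aic_ladder(tiles, list(
    "reuse ~ 1 + Q"             = reuse ~ 1 + quadrat,
    "reuse ~ anom + Q"          = reuse ~ anom + quadrat,
    "reuse ~ d_t + Q"           = reuse ~ d_t + quadrat,
    "reuse ~ d_t + anom + Q"    = reuse ~ d_t + anom + quadrat,
    "reuse ~ d_t * anom + Q"    = reuse ~ d_t * anom + quadrat,
    "reuse ~ d_t + d_t:d_q + Q" = reuse ~ d_t + d_t:d_q + quadrat
  ), family = binomial())
}

#' @rdname model_ladders
#' @export
dpgr_ladder <- function(tiles) {
  tiles <- tiles[!is.na(tiles$dpgr), , drop = FALSE]
  tiles$quadrat <- factor(tiles$quadrat)
  aic_ladder(tiles, list(
    "dpgr ~ 1 + Q"                  = dpgr ~ 1 + quadrat,
    "dpgr ~ cover + Q"              = dpgr ~ cover_pct + quadrat,
    "dpgr ~ log(cover + 1) + Q"     = dpgr ~ log(cover_pct + 1) + quadrat
  ), family = NULL)
}

#' Prediction curves of a fitted habitat model
#'
#' Inverse-logit predictions of a colonization or reuse fit along one
#' predictor, at anchor quantiles (default Q10/Q50/Q90) of a second
#' predictor, over the 1st-99th percentile of the observed predictor.
#' Quadrat effects are averaged on the linear-predictor scale, so the
#' curves are invariant to relabelling of the quadrat factor.
#'
#' @param fit A `vole_fit` from [fit_colonization_model()] or
#'   [fit_reuse_model()].
#' @param data The model frame the fit was estimated on.
#' @param x_var Name of the predictor the curve runs over (e.g. `"anom"`).
#' @param anchor_var Name of the anchored predictor (e.g. `"d_q"`).
#' @param anchor_quantiles Quantiles of `anchor_var` to anchor at.
#' @param range_quantiles Percentile range of `x_var` to span.
#' @param n Number of curve points.
#' @return `data.frame` with `anchor_q`, `anchor_value`, `x`, `p`.
#' @export
predict_response_curves <- function(fit, data, x_var = "anom",
                                    anchor_var = "d_q",
                                    anchor_quantiles = c(0.1, 0.5, 0.9),
                                    range_quantiles = c(0.01, 0.99),
                                    n = 100) {
  stopifnot(inherits(fit, "vole_fit"))
  xs <- seq(quantile(data[[x_var]], range_quantiles[1], na.rm = TRUE),
            quantile(data[[x_var]], range_quantiles[2], na.rm = TRUE),
            length.out = n)
  anchors <- quantile(data[[anchor_var]], anchor_quantiles, na.rm = TRUE)
  qlev <- levels(factor(data$quadrat))
  out <- list()
  for (k in seq_along(anchors)) {
    nd <- expand.grid(x = xs, quadrat = qlev, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
    nd[[x_var]] <- nd$x
    nd[[anchor_var]] <- anchors[k]
    # any remaining predictors of the model are held at their data mean
    need <- setdiff(all.vars(formula(fit$fit)[[3]]),
                    c(x_var, anchor_var, "quadrat"))
    for (v in need) nd[[v]] <- mean(data[[v]], na.rm = TRUE)
    lp <- predict(fit$fit, newdata = nd, type = "link")
    lp_bar <- tapply(lp, rep(seq_along(xs), times = length(qlev)), mean)
    out[[k]] <- data.frame(anchor_q = anchor_quantiles[k],
                           anchor_value = as.numeric(anchors[k]),
                           x = xs, p = plogis(as.numeric(lp_bar)))
  }
  do.call(rbind, out)
}
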