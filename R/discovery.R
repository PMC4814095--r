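#' Rain intensity from annual precipitation and rain days
#'
#' Erosive power proxy: mean annual precipitation divided by the mean
#' annual number of rain days (mm per rain day). Cells with zero
#' precipitation and zero rain days yield 0; positive precipitation with
#' zero rain days is contradictory input and errors, naming the cell.
#'
#' @param annual_precip [raster_layer()] of mm per year.
#' @param rain_days [raster_layer()] of rain days per year.
#' @return A [raster_layer()] of mm per rain day.
#' @export
rain_intensity <- function(annual_precip, rain_days) {
  grid <- stop_unless_aligned(annual_precip, rain_days)
  p <- annual_precip$values; d <- rain_days$values
  bad <- which(!is.na(p) & !is.na(d) & p > 0 & d == 0)
  if (length(bad))
    stop("positive precipitation with zero rain days at cell(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  v <- ifelse(!is.na(p) & !is.na(d) & p == 0 & d == 0, 0, p / d)
  raster_layer(grid, v, name = "rain_intensity")
}

ACCESS_VARS <- c("population_density", "road_density",
                 "dist_large_cities", "dist_medium_cities")

#' Select the accessibility (sampling-bias) model by BIC
#'
#' Fossil sampling concentrates where people can get to. All 2^4 = 16
#' logistic regressions of fossil presence on subsets of the four
#' accessibility proxies (human population density, road density, distance
#' to large and to medium cities; intercept-only included) are fitted and
#' ranked by Bayesian information criterion; the minimum-BIC model is
#' returned, with BIC ties resolved toward the smaller model. The full
#' ranking is kept for export.
#'
#' @param pres_cells Cell indices with at least one fossil (any taxon).
#' @param grid A [grid_spec()].
#' @param accessibility Named list of four [raster_layer()]s:
#'   `population_density`, `road_density`, `dist_large_cities`,
#'   `dist_medium_cities`.
#' @return An object of class `bias_model`: `included_predictors`,
#'   `coefficients` (standardized scale), `bic`, scaling info, and the
#'   `ranking` data.frame (subset, k, loglik, BIC).
#' @export
select_bias_model <- function(pres_cells, grid, accessibility) {
  stopifnot(setequal(names(accessibility), ACCESS_VARS))
  do.call(stop_unless_aligned, unname(accessibility[ACCESS_VARS]))
  pf <- cell_predictor_frame(grid, accessibility[ACCESS_VARS])
  y <- as.numeric(pf$cells %in% pres_cells)
  if (!any(y == 1) || !any(y == 0))
    stop("need at least one presence and one absence cell on land")
  std <- standardize_columns(pf$data, ACCESS_VARS)
  subsets <- unlist(lapply(0:4, function(k)
    utils::combn(ACCESS_VARS, k, simplify = FALSE)), recursive = FALSE)
  cand <- lapply(subsets, function(vars) {
    df <- cbind(data.frame(.y = y), std$data[, vars, drop = FALSE])
    fit <- suppressWarnings(stats::glm(.y ~ ., family = stats::binomial(),
                                       data = df))
    list(vars = vars, fit = fit,
         loglik = as.numeric(stats::logLik(fit)),
         bic = stats::BIC(fit))
  })
  ranking <- data.frame(
    subset = vapply(cand, function(c)
      if (length(c$vars)) paste(c$vars, collapse = "+") else "(intercept)",
      character(1)),
    k = vapply(cand, function(c) length(c$vars) + 1L, integer(1)),
    loglik = vapply(cand, function(c) c$loglik, numeric(1)),
    bic = vapply(cand, function(c) c$bic, numeric(1)))
  # minimum BIC; exact ties go to the smaller model (subsets are already
  # ordered by size, and which.min returns the first minimiser)
  best <- cand[[which.min(ranking$bic)]]
  structure(list(included_predictors = best$vars,
                 coefficients = stats::coef(best$fit),
                 bic = stats::BIC(best$fit),
                 center = std$center, scale = std$scale,
                 ranking = ranking[order(ranking$bic), ],
                 n_candidates = length(cand)),
            class = "bias_model")
}

#' @export
print.bias_model <- function(x, ...) {
  cat("bias_model: ",
      if (length(x$included_predictors))
        paste(x$included_predictors, collapse = " + ") else "(intercept only)",
      sprintf("  (BIC %.1f of %d candidates)\n", x$bic, x$n_candidates))
  invisible(x)
}

#' Predicted per-cell sampling probability under a bias model
#'
#' @param model A `bias_model`.
#' @param grid A [grid_spec()].
#' @param accessibility Named list of the four accessibility layers.
#' @return A [raster_layer()] of sampling probabilities.
#' @export
predict_bias <- function(model, grid, accessibility) {
  pf <- cell_predictor_frame(grid, accessibility[ACCESS_VARS])
  df <- pf$data
  for (v in ACCESS_VARS)
    df[[v]] <- (df[[v]] - model$center[v]) / model$scale[v]
  co <- model$coefficients
  names(co)[1] <- "(Intercept)"
  p <- logistic_prob(co, df)
  vals <- rep(NA_real_, n_cells(grid))
  vals[pf$cells] <- p
  raster_layer(grid, vals, name = "sampling_probability")
}

EROSION_VARS <- c("slope", "rain_intensity", "bare_soil")

#' Fit the bias-corrected fossil-discovery model
#'
#' Logistic regression of all-taxa fossil presence per land cell on three
#' erosion proxies (mean slope, rain intensity, bare-soil cover), with each
#' observation weighted by the reciprocal of its predicted sampling
#' probability so heavily prospected, accessible cells do not dominate the
#' coefficients. Sampling probabilities are floored at `epsilon` to bound
#' the weights, and weights are normalized to mean 1 to preserve the
#' effective sample size. With `sampling_prob = NULL` the fit is unweighted.
#'
#' @param pres_cells Cell indices with at least one fossil (any taxon).
#' @param grid A [grid_spec()].
#' @param slope,rain_int,bare_soil Erosion-proxy [raster_layer()]s
#'   (degrees, mm per rain day, cover fraction).
#' @param sampling_prob Optional [raster_layer()] of per-cell sampling
#'   probabilities from [predict_bias()].
#' @param epsilon Floor for sampling probabilities (default 0.01).
#' @param folds,rounds,seed Cross-validation settings.
#' @return An object of class `discovery_model` with standardized and
#'   raw-scale coefficients, the weights used, and CV `skill`.
#' @export
fit_discovery <- function(pres_cells, grid, slope, rain_int, bare_soil,
                          sampling_prob = NULL, epsilon = 0.01,
                          folds = 5, rounds = 1, seed = 1L) {
  if (epsilon <= 0) stop("epsilon must be positive")
  stop_unless_aligned(slope, rain_int, bare_soil)
  pf <- cell_predictor_frame(grid, list(slope = slope,
                                        rain_intensity = rain_int,
                                        bare_soil = bare_soil))
  y <- as.numeric(pf$cells %in% pres_cells)
  if (!any(y == 1) || !any(y == 0))
    stop("need at least one presence and one absence cell on land")
  w <- rep(1, length(y))
  if (!is.null(sampling_prob)) {
    p_hat <- sampling_prob$values[pf$cells]
    if (any(is.na(p_hat))) stop("sampling probability missing at land cells")
    w <- 1 / pmax(p_hat, epsilon)
    w <- w / mean(w)
  }
  std <- standardize_columns(pf$data, EROSION_VARS)
  fit <- fit_cell_logistic(y, std$data, weights = w,
                           label = "discovery model")
  skill <- cv_cell_logistic(y, std$data, weights = w, folds = folds,
                            rounds = rounds, seed = seed)
  co <- fit$coefficients
  raw <- co
  raw[-1] <- co[-1] / std$scale[names(co)[-1]]
  raw[1] <- co[1] - sum(raw[-1] * std$center[names(co)[-1]])
  structure(list(coefficients = co, coefficients_raw = raw, se = fit$se,
                 center = std$center, scale = std$scale, weights = w,
                 cells = pf$cells, epsilon = epsilon, skill = skill,
                 weighted = !is.null(sampling_prob), ridge = fit$ridge),
            class = "discovery_model")
}

#' @export
print.discovery_model <- function(x, ...) {
  cat("discovery_model (", if (x$weighted) "bias-weighted" else "unweighted",
      ", standardized coefficients):\n", sep = "")
  print(round(x$coefficients, 4))
  cat(sprintf("  CV median TSS %.2f, AUC %.2f\n",
              stats::median(x$skill$tss), stats::median(x$skill$auc)))
  invisible(x)
}

#' Predict discovery suitability over the grid
#'
#' Applies the bias-corrected coefficients with no sampling-bias weights:
#' weights isolate the erosion effects during fitting, but accessibility
#' has no bearing on whether a fossil is physically discoverable, so
#' prediction uses the erosion proxies alone. Rank-rescaled to `[0, 1]`;
#' raw probabilities in the surface's `raw` field.
#'
#' @param model A `discovery_model`.
#' @param slope,rain_int,bare_soil Predictor [raster_layer()]s.
#' @return A rank-rescaled `suitability_surface`.
#' @export
predict_discovery <- function(model, slope, rain_int, bare_soil) {
  grid <- stop_unless_aligned(slope, rain_int, bare_soil)
  pf <- cell_predictor_frame(grid, list(slope = slope,
                                        rain_intensity = rain_int,
                                        bare_soil = bare_soil))
  df <- pf$data
  for (v in EROSION_VARS)
    df[[v]] <- (df[[v]] - model$center[v]) / model$scale[v]
  p <- logistic_prob(model$coefficients, df)
  vals <- rep(NA_real_, n_cells(grid))
  vals[pf$cells] <- p
  out <- rank_rescale(new_surface(grid, vals, slice_age = "discovery"))
  out$raw <- vals
  out
}
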