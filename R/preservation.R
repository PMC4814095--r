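# Shared cell-level logistic machinery for the preservation and discovery
# models: standardized continuous predictors, separation-safe fitting, and
# k-fold skill estimates.

standardize_columns <- function(df, continuous) {
  center <- vapply(df, function(v) 0, numeric(1))
  scale <- vapply(df, function(v) 1, numeric(1))
  for (v in continuous) {
    center[v] <- mean(df[[v]])
    s <- stats::sd(df[[v]])
    scale[v] <- if (is.na(s) || s == 0) 1 else s
    df[[v]] <- (df[[v]] - center[v]) / scale[v]
  }
  list(data = df, center = center, scale = scale)
}

fit_cell_logistic <- function(y, X, weights = NULL, label = "logistic model") {
  df <- cbind(data.frame(.y = y), X)
  if (is.null(weights)) weights <- rep(1, length(y))
  separated <- FALSE
  fam <- if (all(weights == 1)) stats::binomial() else stats::quasibinomial()
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., family = fam, data = df, weights = weights),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separated || !fit$converged) {
    warning("separation in ", label, "; falling back to a ridge-penalised fit")
    Xm <- as.matrix(X)
    rfit <- glmnet::glmnet(Xm, y, family = "binomial", alpha = 0,
                           lambda = 1e-3, weights = weights,
                           standardize = FALSE)
    co <- c(`(Intercept)` = as.numeric(rfit$a0),
            stats::setNames(as.numeric(rfit$beta), colnames(Xm)))
    return(list(coefficients = co, se = rep(NA_real_, length(co)),
                glm = NULL, ridge = TRUE))
  }
  list(coefficients = stats::coef(fit),
       se = summary(fit)$coefficients[, "Std. Error"],
       glm = fit, ridge = FALSE)
}

logistic_prob <- function(coefficients, X) {
  eta <- coefficients[1] +
    as.matrix(X[, names(coefficients)[-1], drop = FALSE]) %*%
    coefficients[-1]
  stats::plogis(as.numeric(eta))
}

cv_cell_logistic <- function(y, X, weights = NULL, folds = 5, rounds = 1,
                             seed = 1L) {
  if (is.null(weights)) weights <- rep(1, length(y))
  out <- list()
  withr_seed(seed, {
    for (r in seq_len(rounds)) {
      f <- sample(rep_len(seq_len(folds), length(y)))
      for (k in seq_len(folds)) {
        te <- f == k
        if (!any(y[te] == 1) || !any(y[te] == 0) ||
            !any(y[!te] == 1) || !any(y[!te] == 0)) next
        fit <- fit_cell_logistic(y[!te], X[!te, , drop = FALSE],
                                 weights[!te])
        p <- logistic_prob(fit$coefficients, X[te, , drop = FALSE])
        sp <- p[y[te] == 1]; sa <- p[y[te] == 0]
        thr <- tss_threshold(sp, sa)
        out[[length(out) + 1]] <- data.frame(
          round = r, fold = k,
          tss = compute_tss(sum(sp >= thr), sum(sp < thr),
                            sum(sa < thr), sum(sa >= thr)),
          auc = compute_auc(sp, sa))
      }
    }
  })
  if (!length(out)) stop("all cross-validation folds were skipped")
  do.call(rbind, out)
}

cell_predictor_frame <- function(grid, layers) {
  df <- as.data.frame(lapply(layers, function(l) l$values))
  ok <- grid$land_mask & !Reduce(`|`, lapply(df, is.na))
  list(data = df[ok, , drop = FALSE], cells = which(ok))
}

#' Fit the geological fossil-preservation model
#'
#' Logistic regression of all-taxa fossil presence/absence per land cell on
#' three geological trap predictors: suitable (sedimentary) rock cover,
#' lake cover, and cave presence. Continuous predictors are standardized
#' before fitting; coefficients are reported on both the standardized and
#' the original scale. Geology is treated as constant over the late
#' Quaternary time span of the fossil data.
#'
#' @param pres_cells Cell indices with at least one fossil (any taxon, any
#'   age quality).
#' @param grid A [grid_spec()].
#' @param rock,lake,cave [raster_layer()]s: rock/lake cover fractions and
#'   binary cave presence.
#' @param folds,rounds,seed Cross-validation settings.
#' @return An object of class `preservation_model` with `coefficients`
#'   (standardized), `coefficients_raw`, standard errors, and CV `skill`.
#' @export
fit_preservation <- function(pres_cells, grid, rock, lake, cave,
                             folds = 5, rounds = 1, seed = 1L) {
  stop_unless_aligned(rock, lake, cave)
  pf <- cell_predictor_frame(grid, list(rock_cover = rock, lake_cover = lake,
                                        cave_presence = cave))
  df <- pf$data
  df$cave_presence <- as.numeric(df$cave_presence != 0)
  y <- as.numeric(pf$cells %in% pres_cells)
  if (!any(y == 1) || !any(y == 0))
    stop("need at least one presence and one absence cell on land")
  std <- standardize_columns(df, c("rock_cover", "lake_cover"))
  fit <- fit_cell_logistic(y, std$data, label = "preservation model")
  skill <- cv_cell_logistic(y, std$data, folds = folds, rounds = rounds,
                            seed = seed)
  co <- fit$coefficients
  raw <- co
  raw[-1] <- co[-1] / std$scale[names(co)[-1]]
  raw[1] <- co[1] - sum(raw[-1] * std$center[names(co)[-1]])
  structure(list(coefficients = co, coefficients_raw = raw, se = fit$se,
                 center = std$center, scale = std$scale, skill = skill,
                 ridge = fit$ridge),
            class = "preservation_model")
}

#' @export
print.preservation_model <- function(x, ...) {
  cat("preservation_model (standardized coefficients):\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  CV median TSS %.2f, AUC %.2f\n",
              stats::median(x$skill$tss), stats::median(x$skill$auc)))
  invisible(x)
}

#' Predict preservation suitability over the grid
#'
#' Per-cell logistic probability under the fitted model, rank-rescaled to
#' `[0, 1]`; the raw probabilities are kept in the surface's `raw` field.
#'
#' @param model A `preservation_model`.
#' @param rock,lake,cave Predictor [raster_layer()]s aligned to one grid.
#' @return A rank-rescaled `suitability_surface`.
#' @export
predict_preservation <- function(model, rock, lake, cave) {
  grid <- stop_unless_aligned(rock, lake, cave)
  pf <- cell_predictor_frame(grid, list(rock_cover = rock, lake_cover = lake,
                                        cave_presence = cave))
  df <- pf$data
  df$cave_presence <- as.numeric(df$cave_presence != 0)
  for (v in c("rock_cover", "lake_cover"))
    df[[v]] <- (df[[v]] - model$center[v]) / model$scale[v]
  p <- logistic_prob(model$coefficients, df)
  vals <- rep(NA_real_, n_cells(grid))
  vals[pf$cells] <- p
  out <- rank_rescale(new_surface(grid, vals, slice_age = "preservation"))
  out$raw <- vals
  out
}
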