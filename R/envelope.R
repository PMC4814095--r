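CLIM_VARS <- c("temperature", "precipitation")

#' Assemble a presence / pseudo-absence occurrence dataset
#'
#' @param taxon Taxon name.
#' @param presences,pseudo_absences `data.frame`s with columns `cell`,
#'   `slice_age`, `temperature`, `precipitation` (as from [match_climate()]).
#'   The same (cell, slice) pair may not appear in both classes.
#' @return An object of class `occurrence_dataset` with the taxon's fossil
#'   age range attached.
#' @export
occurrence_dataset <- function(taxon, presences, pseudo_absences) {
  key <- function(d) paste(d$cell, d$slice_age)
  if (length(intersect(key(presences), key(pseudo_absences))))
    stop("presence and pseudo-absence cells overlap at identical time slices")
  structure(list(taxon = taxon, presences = presences,
                 pseudo_absences = pseudo_absences,
                 age_range = range(presences$slice_age)),
            class = "occurrence_dataset")
}

#' @export
print.occurrence_dataset <- function(x, ...) {
  cat(sprintf("occurrence_dataset '%s': %d presences, %d pseudo-absences, %g-%g ka\n",
              x$taxon, nrow(x$presences), nrow(x$pseudo_absences),
              x$age_range[1], x$age_range[2]))
  invisible(x)
}

#' Sample environmentally constrained pseudo-absences
#'
#' Candidates (typically fossil sites where the focal taxon is absent, so
#' pseudo-absences share the presences' sampling biases) are eligible only
#' when their temperature OR precipitation falls outside the presences'
#' 5th-95th percentile band — keeping pseudo-absences outside the taxon's
#' climate envelope and reducing the risk of false absences. From the
#' eligible pool, `ratio * n_presences` candidates are drawn uniformly
#' without replacement; if fewer are eligible, all of them are returned.
#'
#' @param presences Presence `data.frame` with `temperature`/`precipitation`.
#' @param candidates Candidate `data.frame` with the same climate columns.
#' @param ratio Pseudo-absences per presence (default 10).
#' @param seed Integer RNG seed for the draw.
#' @return The sampled subset of `candidates`.
#' @export
sample_pseudo_absences <- function(presences, candidates, ratio = 10, seed = 1L) {
  if (nrow(presences) == 0) stop("no presences to define the climate envelope")
  stopifnot(ratio > 0)
  qt <- stats::quantile(presences$temperature, c(0.05, 0.95))
  qp <- stats::quantile(presences$precipitation, c(0.05, 0.95))
  eligible <- candidates$temperature < qt[1] | candidates$temperature > qt[2] |
    candidates$precipitation < qp[1] | candidates$precipitation > qp[2]
  pool <- candidates[eligible, , drop = FALSE]
  if (nrow(pool) == 0) stop("no eligible pseudo-absence candidates outside the envelope")
  n_target <- round(ratio * nrow(presences))
  if (nrow(pool) <= n_target) return(pool)
  idx <- withr_seed(seed, sample.int(nrow(pool), n_target))
  pool[sort(idx), , drop = FALSE]
}

# evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

clim_matrix <- function(d) as.matrix(d[, CLIM_VARS, drop = FALSE])

training_ranges <- function(X) {
  apply(X, 2, function(v) c(min = min(v), max = max(v),
                            q5 = unname(stats::quantile(v, 0.05)),
                            q95 = unname(stats::quantile(v, 0.95))))
}

new_envelope_fit <- function(method, parameters, ranges) {
  structure(list(method = method, parameters = parameters,
                 training_ranges = ranges, skill = NULL, tss_weight = NA_real_),
            class = "envelope_fit")
}

#' @export
print.envelope_fit <- function(x, ...) {
  cat(sprintf("envelope_fit: %s (tss_weight = %s)\n", x$method,
              format(x$tss_weight, digits = 3)))
  invisible(x)
}

#' Fit a Bioclim percentile envelope
#'
#' Classic rectilinear envelope: a point's score for one climate variable is
#' twice the smaller tail of its percentile position among the presence
#' values (median scores 1, values at or beyond the presence range score 0),
#' and the overall score is the minimum across variables. Requires no
#' absence data. A variable that is constant among presences scores 1 at
#' that value and 0 elsewhere.
#'
#' @param presences Presence `data.frame` with climate columns.
#' @return An `envelope_fit` of method `"bioclim"`.
#' @export
fit_bioclim <- function(presences) {
  X <- clim_matrix(presences)
  if (nrow(X) < 3) stop("bioclim needs at least 3 presences")
  new_envelope_fit("bioclim",
                   list(values = lapply(as.data.frame(X), sort)),
                   training_ranges(X))
}

bioclim_var_score <- function(x, pres_sorted) {
  n <- length(pres_sorted)
  lo <- pres_sorted[1]; hi <- pres_sorted[n]
  if (lo == hi) return(as.numeric(x == lo))
  # percentile position p = share of presence values <= x; tail-doubled
  p <- findInterval(x, pres_sorted) / n
  s <- 2 * pmin(p, 1 - p)
  s[x < lo | x > hi] <- 0
  s
}

#' Fit a quadratic logistic climate-response model
#'
#' Binomial-logit GLM of presence versus pseudo-absence on temperature,
#' precipitation and their squares (a quadratic response surface, allowing
#' an interior optimum on each axis). Perfect separation triggers a
#' ridge-penalised fallback with a warning.
#'
#' @param presences,pseudo_absences `data.frame`s with climate columns.
#' @return An `envelope_fit` of method `"glm"`.
#' @export
fit_glm <- function(presences, pseudo_absences) {
  if (nrow(presences) == 0 || nrow(pseudo_absences) == 0)
    stop("both classes must be non-empty")
  df <- rbind(cbind(presences[CLIM_VARS], y = 1),
              cbind(pseudo_absences[CLIM_VARS], y = 0))
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ temperature + precipitation +
                 I(temperature^2) + I(precipitation^2),
               family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  params <- list(coef = stats::coef(fit), ridge = NULL)
  if (separated || !fit$converged) {
    warning("separation in climate GLM; falling back to a ridge-penalised fit")
    X <- as.matrix(cbind(df[CLIM_VARS], df[CLIM_VARS]^2))
    rfit <- glmnet::glmnet(X, df$y, family = "binomial", alpha = 0,
                           lambda = 1e-3, standardize = TRUE)
    params <- list(coef = NULL, ridge = rfit)
  }
  ranges <- training_ranges(clim_matrix(rbind(presences[CLIM_VARS],
                                              pseudo_absences[CLIM_VARS])))
  new_envelope_fit("glm", params, ranges)
}

maxent_features <- function(X) {
  cbind(t = X[, 1], p = X[, 2], t2 = X[, 1]^2, p2 = X[, 2]^2,
        tp = X[, 1] * X[, 2])
}

#' Fit a MaxEnt-style penalised presence-background model
#'
#' L1-penalised logistic regression of presence versus background on
#' standardized linear, quadratic and product features of the two climate
#' variables — the penalised-GLM formulation of MaxEnt's feature-class
#' model. Scores are the logistic output rescaled to `[0, 1]` by its
#' minimum/maximum over the background sample.
#'
#' @param presences,pseudo_absences `data.frame`s with climate columns.
#' @param regularization L1 penalty (glmnet lambda); larger values shrink
#'   all feature coefficients toward a flat surface.
#' @return An `envelope_fit` of method `"maxent_like"`.
#' @export
fit_maxent_like <- function(presences, pseudo_absences, regularization = 0.01) {
  if (nrow(presences) == 0 || nrow(pseudo_absences) == 0)
    stop("both classes must be non-empty")
  if (regularization < 0) stop("regularization must be non-negative")
  Xp <- clim_matrix(presences); Xb <- clim_matrix(pseudo_absences)
  F_all <- maxent_features(rbind(Xp, Xb))
  ctr <- colMeans(F_all)
  scl <- apply(F_all, 2, stats::sd)
  scl[scl == 0] <- 1
  Fs <- scale(F_all, ctr, scl)
  y <- rep(1:0, c(nrow(Xp), nrow(Xb)))
  fit <- glmnet::glmnet(Fs, y, family = "binomial", alpha = 1,
                        lambda = max(regularization, 1e-8),
                        standardize = FALSE)
  eta_bg <- as.numeric(stats::predict(fit, Fs[y == 0, , drop = FALSE]))
  pr_bg <- stats::plogis(eta_bg)
  new_envelope_fit(
    "maxent_like",
    list(fit = fit, center = ctr, scale = scl,
         bg_min = min(pr_bg), bg_max = max(pr_bg)),
    training_ranges(rbind(Xp, Xb)))
}

#' Score climates under a fitted envelope model
#'
#' @param object An `envelope_fit`.
#' @param newdata `data.frame` or matrix with `temperature` and
#'   `precipitation` columns.
#' @param ... Unused.
#' @return Numeric suitability scores in `[0, 1]`.
#' @export
predict.envelope_fit <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata[, CLIM_VARS, drop = FALSE]
       else clim_matrix(newdata)
  switch(object$method,
    bioclim = {
      vals <- object$parameters$values
      pmin(bioclim_var_score(X[, 1], vals$temperature),
           bioclim_var_score(X[, 2], vals$precipitation))
    },
    glm = {
      if (!is.null(object$parameters$coef)) {
        b <- object$parameters$coef
        eta <- b[1] + b[2] * X[, 1] + b[3] * X[, 2] +
          b[4] * X[, 1]^2 + b[5] * X[, 2]^2
        stats::plogis(as.numeric(eta))
      } else {
        Xq <- cbind(X, X^2)
        as.numeric(stats::predict(object$parameters$ridge, Xq,
                                  type = "response"))
      }
    },
    maxent_like = {
      p <- object$parameters
      Fs <- scale(maxent_features(X), p$center, p$scale)
      pr <- stats::plogis(as.numeric(stats::predict(p$fit, Fs)))
      den <- p$bg_max - p$bg_min
      if (den <= 0) return(rep(0.5, nrow(X)))
      pmin(1, pmax(0, (pr - p$bg_min) / den))
    },
    stop("unknown envelope method: ", object$method))
}

fit_envelope_method <- function(method, presences, pseudo_absences, ...) {
  switch(method,
    bioclim = fit_bioclim(presences),
    glm = fit_glm(presences, pseudo_absences),
    maxent_like = fit_maxent_like(presences, pseudo_absences, ...),
    stop("unknown envelope method: ", method))
}

#' True skill statistic from a confusion matrix
#'
#' TSS = sensitivity + specificity - 1: the proportion of presences
#' predicted correctly plus the proportion of absences predicted correctly,
#' minus one. Ranges over `[-1, 1]`; 0 is no better than chance, and unlike
#' kappa it is insensitive to prevalence.
#'
#' @param tp,fn,tn,fp Confusion-matrix counts.
#' @return TSS value.
#' @export
compute_tss <- function(tp, fn, tn, fp) {
  if (tp + fn < 1) stop("no observed presences")
  if (tn + fp < 1) stop("no observed absences")
  tp / (tp + fn) + tn / (tn + fp) - 1
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a randomly chosen presence outscores a randomly chosen
#' absence, with ties counting one half — computed from midranks rather
#' than an explicit threshold sweep.
#'
#' @param scores_presence,scores_absence Numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(scores_presence, scores_absence) {
  n1 <- length(scores_presence); n2 <- length(scores_absence)
  if (n1 == 0 || n2 == 0) stop("both score lists must be non-empty")
  r <- rank(c(scores_presence, scores_absence), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Cross-validate an envelope model
#'
#' Two schemes: `"spatio_temporal"` pools all presences and pseudo-absences
#' and runs repeated k-fold cross-validation with random folds, so training
#' and test data differ in both space and time; `"temporal_only"` holds out
#' one time slice per round (as many rounds as slices holding presences), a
#' stricter test of transferability through time. Each evaluation reports
#' the TSS at the TSS-maximising threshold and the AUC on the held-out data.
#'
#' @param dataset An [occurrence_dataset()].
#' @param method One of `"bioclim"`, `"glm"`, `"maxent_like"`.
#' @param scheme Validation scheme (see above).
#' @param folds Folds for the spatio-temporal scheme (default 5).
#' @param rounds Repetitions of the k-fold split (default 100).
#' @param seed Integer RNG seed for fold assignment.
#' @return `data.frame` with columns `round`, `fold`, `tss`, `auc`; skipped
#'   rounds (no held-out members of a class) are dropped with a message.
#' @export
cross_validate <- function(dataset, method,
                           scheme = c("spatio_temporal", "temporal_only"),
                           folds = 5, rounds = 100, seed = 1L) {
  scheme <- match.arg(scheme)
  pres <- dataset$presences; pa <- dataset$pseudo_absences
  eval_split <- function(train_p, train_a, test_p, test_a) {
    fit <- fit_envelope_method(method, train_p, train_a)
    sp <- predict(fit, test_p); sa <- predict(fit, test_a)
    thr <- tss_threshold(sp, sa)
    tss <- compute_tss(sum(sp >= thr), sum(sp < thr),
                       sum(sa < thr), sum(sa >= thr))
    c(tss = tss, auc = compute_auc(sp, sa))
  }
  out <- list()
  if (scheme == "spatio_temporal") {
    withr_seed(seed, {
      for (r in seq_len(rounds)) {
        fp <- sample(rep_len(seq_len(folds), nrow(pres)))
        fa <- sample(rep_len(seq_len(folds), nrow(pa)))
        for (k in seq_len(folds)) {
          if (!any(fp == k) || !any(fa == k) ||
              all(fp == k) || all(fa == k)) {
            message("fold ", k, " of round ", r, " skipped (empty class)")
            next
          }
          s <- eval_split(pres[fp != k, ], pa[fa != k, ],
                          pres[fp == k, ], pa[fa == k, ])
          out[[length(out) + 1]] <- data.frame(round = r, fold = k,
                                               tss = s[["tss"]], auc = s[["auc"]])
        }
      }
    })
  } else {
    slice_ages <- sort(unique(pres$slice_age))
    if (length(slice_ages) < 2)
      stop("temporal-only validation needs presences in at least 2 time slices")
    for (i in seq_along(slice_ages)) {
      a <- slice_ages[i]
      hp <- pres$slice_age == a; ha <- pa$slice_age == a
      if (!any(ha) || all(ha)) {
        message("slice ", a, " ka skipped (no held-out or no training pseudo-absences)")
        next
      }
      s <- eval_split(pres[!hp, ], pa[!ha, ], pres[hp, , drop = FALSE],
                      pa[ha, , drop = FALSE])
      out[[length(out) + 1]] <- data.frame(round = i, fold = 1,
                                           tss = s[["tss"]], auc = s[["auc"]])
    }
  }
  if (!length(out)) stop("all cross-validation rounds were skipped")
  do.call(rbind, out)
}

#' Fit the three-model climate-envelope ensemble for one taxon
#'
#' Fits Bioclim, the quadratic GLM and the MaxEnt-style model on the full
#' dataset, cross-validates each (spatio-temporal scheme), and stores each
#' model's median TSS as its ensemble weight.
#'
#' @param dataset An [occurrence_dataset()].
#' @param methods Character vector of methods to include.
#' @param folds,rounds,seed Passed to [cross_validate()].
#' @return Named list of `envelope_fit`s with `skill` and `tss_weight` set.
#' @export
fit_envelope_ensemble <- function(dataset,
                                  methods = c("bioclim", "glm", "maxent_like"),
                                  folds = 5, rounds = 100, seed = 1L) {
  fits <- lapply(seq_along(methods), function(i) {
    m <- methods[i]
    fit <- fit_envelope_method(m, dataset$presences, dataset$pseudo_absences)
    fit$skill <- cross_validate(dataset, m, "spatio_temporal",
                                folds = folds, rounds = rounds,
                                seed = seed + i)
    fit$tss_weight <- stats::median(fit$skill$tss)
    fit
  })
  names(fits) <- methods
  fits
}

new_surface <- function(grid, values, extrapolation = NULL, slice_age = NA) {
  if (is.null(extrapolation)) extrapolation <- rep(FALSE, n_cells(grid))
  structure(list(grid = grid, values = values,
                 extrapolation = extrapolation, slice_age = slice_age),
            class = "suitability_surface")
}

#' @export
print.suitability_surface <- function(x, ...) {
  v <- x$values[x$grid$land_mask]
  cat(sprintf("suitability_surface (%s): %d land cells, range [%.3f, %.3f], %d extrapolated\n",
              as.character(x$slice_age), sum(x$grid$land_mask),
              min(v, na.rm = TRUE), max(v, na.rm = TRUE),
              sum(x$extrapolation[x$grid$land_mask])))
  invisible(x)
}

#' Project a TSS-weighted ensemble onto one climate slice
#'
#' Per-cell ensemble suitability is the weighted mean of the member models'
#' scores, each weighted by its (non-negative) median cross-validated TSS;
#' negative-skill models drop out. Cells whose temperature or precipitation
#' falls outside every-variable training (min, max) of the contributing
#' models are flagged as extrapolation.
#'
#' @param fits List of `envelope_fit`s with `tss_weight` set.
#' @param slice A [climate_slice()].
#' @return A `suitability_surface` for that slice.
#' @export
project_ensemble <- function(fits, slice) {
  w <- pmax(vapply(fits, function(f) f$tss_weight, numeric(1)), 0)
  if (all(w <= 0)) stop("all ensemble weights are non-positive")
  grid <- slice$temperature$grid
  tv <- slice$temperature$values; pv <- slice$precipitation$values
  ok <- grid$land_mask & !is.na(tv) & !is.na(pv)
  X <- cbind(temperature = tv[ok], precipitation = pv[ok])
  num <- 0
  for (i in seq_along(fits)) {
    if (w[i] <= 0) next
    num <- num + w[i] * predict(fits[[i]], X)
  }
  vals <- rep(NA_real_, n_cells(grid))
  vals[ok] <- num / sum(w)
  active <- fits[w > 0]
  rng <- sapply(CLIM_VARS, function(v) {
    mins <- vapply(active, function(f) f$training_ranges["min", v], numeric(1))
    maxs <- vapply(active, function(f) f$training_ranges["max", v], numeric(1))
    c(min(mins), max(maxs))
  })
  extrap <- rep(FALSE, n_cells(grid))
  extrap[ok] <- X[, 1] < rng[1, "temperature"] | X[, 1] > rng[2, "temperature"] |
    X[, 2] < rng[1, "precipitation"] | X[, 2] > rng[2, "precipitation"]
  new_surface(grid, vals, extrap, slice$age_ka)
}

#' Average ensemble projections over the taxon's lifetime
#'
#' Keeps the slices at and older than the taxon's youngest fossil (the taxon
#' is assumed extinct after that), takes the per-cell arithmetic mean of
#' their suitabilities, marks a cell as extrapolated if any included slice
#' flagged it, and rank-rescales the result to `[0, 1]`.
#'
#' @param surfaces List of per-slice `suitability_surface`s.
#' @param youngest_fossil_age Youngest reliable fossil age (ka).
#' @return A multi-temporal `suitability_surface` (rank-rescaled).
#' @export
multi_temporal_average <- function(surfaces, youngest_fossil_age = 0) {
  if (length(surfaces) == 0) stop("no surfaces to average")
  keep <- vapply(surfaces, function(s) s$slice_age >= youngest_fossil_age,
                 logical(1))
  surfaces <- surfaces[keep]
  if (length(surfaces) == 0) stop("no slices at or older than the youngest fossil")
  grid <- surfaces[[1]]$grid
  V <- vapply(surfaces, function(s) s$values, numeric(n_cells(grid)))
  E <- vapply(surfaces, function(s) s$extrapolation, logical(n_cells(grid)))
  avg <- rowMeans(as.matrix(V))
  out <- new_surface(grid, avg, rowSums(as.matrix(E)) > 0, "multi-temporal")
  rank_rescale(out)
}
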