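#' Pipeline run configuration
#'
#' Defaults reproduce the published analysis settings: ten pseudo-absences
#' per presence, a 2-SD slice-selection window, 100 rounds of 5-fold
#' cross-validation for the envelope models, 1000 random sets in the
#' independent validation, and equal combination weights.
#'
#' @param pseudo_absence_ratio Pseudo-absences per presence (default 10).
#' @param k_sd Slice-selection window in age-SD units (default 2).
#' @param cv_rounds Rounds of k-fold CV for the envelope models (default
#'   100).
#' @param cv_folds Folds (default 5).
#' @param cell_cv_rounds Rounds of k-fold CV for the preservation and
#'   discovery models (default 1, i.e. one five-fold pass).
#' @param n_random_sets Random sets for KS/TSS validation (default 1000).
#' @param weights Combination weights for climate, preservation, discovery.
#' @param epsilon Sampling-probability floor for bias weights.
#' @param maxent_regularization L1 penalty of the MaxEnt-style model.
#' @param seed Master integer seed; stage seeds are derived from it.
#' @return A `run_config` list.
#' @export
run_config <- function(pseudo_absence_ratio = 10, k_sd = 2,
                       cv_rounds = 100, cv_folds = 5, cell_cv_rounds = 1,
                       n_random_sets = 1000, weights = c(1, 1, 1),
                       epsilon = 0.01, maxent_regularization = 0.01,
                       seed = 1L) {
  stopifnot(pseudo_absence_ratio > 0, k_sd > 0, cv_rounds >= 1,
            cv_folds >= 2, n_random_sets >= 1, length(weights) == 3)
  structure(as.list(environment()), class = "run_config")
}

dedupe_occurrences <- function(df) {
  df[!duplicated(df[c("cell", "slice_age")]), , drop = FALSE]
}

#' Run the full fossil-potential pipeline
#'
#' Executes the whole chain for one focal taxon: age-quality filtering,
#' Gaussian time-matching of climates, envelope-constrained pseudo-absence
#' sampling, the three-model climate ensemble with cross-validated TSS
#' weights projected over the taxon's lifetime, the preservation and
#' bias-corrected discovery models, rank-rescaled combination, and (when
#' cells with only unreliably dated fossils exist) the independent KS /
#' TSS / probability-ratio validation.
#'
#' @param records Fossil-record `data.frame` (all taxa; see
#'   [read_fossil_csv()]).
#' @param grid A [grid_spec()].
#' @param stack A [climate_stack()].
#' @param layers Named list of predictor [raster_layer()]s: `rock_cover`,
#'   `lake_cover`, `cave_presence` (preservation; optional as a block),
#'   `slope`, `bare_soil` and either `rain_intensity` or `annual_precip` +
#'   `rain_days` (discovery), and the four accessibility layers of
#'   [select_bias_model()].
#' @param taxon Focal taxon name.
#' @param config A [run_config()].
#' @param output_dir Optional directory; when given, surfaces, model
#'   summaries, the validation report and a run log are written there.
#' @return A `pipeline_result` list with the fitted models, the four
#'   surfaces, thresholds, validation report and a log of seeds used.
#' @export
run_pipeline <- function(records, grid, stack, layers, taxon,
                         config = run_config(), output_dir = NULL) {
  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  note("pipeline start: taxon=%s seed=%d", taxon, config$seed)

  # --- fossil filtering and climate matching -------------------------------
  res <- stage("fossil_records", {
    focal <- extract_records(records, taxon)
    if (!nrow(focal)) stop("no records for taxon ", taxon)
    parts <- filter_reliable(focal)
    list(focal = focal, parts = parts)
  })
  train_clim <- stage("paleoclimate", {
    dedupe_occurrences(match_climate(res$parts$training, grid, stack,
                                     config$k_sd))
  })
  note("training presences: %d records -> %d (cell, slice) occurrences",
       nrow(res$parts$training), nrow(train_clim))

  # --- pseudo-absences from other-taxon fossil sites -----------------------
  dataset <- stage("pseudo_absences", {
    others <- records[records$taxon != taxon, , drop = FALSE]
    if (!nrow(others))
      stop("no fossil sites of other taxa to draw pseudo-absences from")
    cand <- dedupe_occurrences(match_climate(others, grid, stack, config$k_sd))
    cand <- cand[!(cand$cell %in% train_clim$cell), , drop = FALSE]
    pa <- sample_pseudo_absences(train_clim, cand,
                                 ratio = config$pseudo_absence_ratio,
                                 seed = config$seed + 11L)
    note("pseudo-absences: %d sampled from %d candidates", nrow(pa), nrow(cand))
    occurrence_dataset(taxon, train_clim, pa)
  })

  # --- climate-envelope ensemble -------------------------------------------
  fits <- stage("climate_envelope", {
    fit_envelope_ensemble(dataset, folds = config$cv_folds,
                          rounds = config$cv_rounds,
                          seed = config$seed + 20L)
  })
  for (m in names(fits))
    note("envelope %s: median TSS %.3f, median AUC %.3f", m,
         stats::median(fits[[m]]$skill$tss), stats::median(fits[[m]]$skill$auc))
  climate_surface <- stage("projection", {
    youngest <- min(train_clim$slice_age)
    keep <- which(stack$ages >= youngest)
    surfs <- lapply(stack$slices[keep], function(s) project_ensemble(fits, s))
    note("projected %d slices (>= %g ka)", length(keep), youngest)
    multi_temporal_average(surfs, youngest)
  })

  # --- preservation ---------------------------------------------------------
  val_cells <- validation_cells(res$focal, grid)
  all_cells <- stage("presence_cells", {
    setdiff(presence_cells(records, grid), val_cells)
  })
  note("all-taxa presence cells (validation cells excluded): %d", length(all_cells))
  have_pres <- all(c("rock_cover", "lake_cover", "cave_presence") %in% names(layers))
  pres_model <- NULL; preservation_surface <- NULL
  if (have_pres) {
    pres_model <- stage("preservation", {
      fit_preservation(all_cells, grid, layers$rock_cover, layers$lake_cover,
                       layers$cave_presence, folds = config$cv_folds,
                       rounds = config$cell_cv_rounds,
                       seed = config$seed + 31L)
    })
    preservation_surface <- predict_preservation(pres_model, layers$rock_cover,
                                                 layers$lake_cover,
                                                 layers$cave_presence)
  } else {
    note("preservation layers missing; combining climate and discovery only")
  }

  # --- discovery ------------------------------------------------------------
  disc <- stage("discovery", {
    rain_int <- layers$rain_intensity %||%
      rain_intensity(layers$annual_precip, layers$rain_days)
    bias <- select_bias_model(all_cells, grid, layers[ACCESS_VARS])
    note("bias model: %s (BIC %.1f)",
         if (length(bias$included_predictors))
           paste(bias$included_predictors, collapse = "+") else "(intercept)",
         bias$bic)
    samp <- predict_bias(bias, grid, layers[ACCESS_VARS])
    model <- fit_discovery(all_cells, grid, layers$slope, rain_int,
                           layers$bare_soil, sampling_prob = samp,
                           epsilon = config$epsilon,
                           folds = config$cv_folds,
                           rounds = config$cell_cv_rounds,
                           seed = config$seed + 41L)
    list(bias = bias, model = model,
         surface = predict_discovery(model, layers$slope, rain_int,
                                     layers$bare_soil))
  })

  # --- combination ----------------------------------------------------------
  combined <- stage("combiner", {
    combine_potential(climate_surface, preservation_surface, disc$surface,
                      weights = config$weights)
  })

  # --- thresholds and independent validation --------------------------------
  thresholds <- stage("thresholds", {
    land <- land_cells(grid)
    thr <- c(climate = tss_threshold(
      climate_surface$values[unique(dataset$presences$cell)],
      climate_surface$values[unique(dataset$pseudo_absences$cell)]))
    non_fossil <- setdiff(land, all_cells)
    if (!is.null(preservation_surface))
      thr["preservation"] <- tss_threshold(
        preservation_surface$values[all_cells],
        preservation_surface$values[non_fossil])
    thr["discovery"] <- tss_threshold(disc$surface$values[all_cells],
                                      disc$surface$values[non_fossil])
    thr
  })
  report <- NULL
  if (length(val_cells) >= 2 && !is.null(preservation_surface)) {
    report <- stage("validation", {
      validation_report(
        list(climate = climate_surface, preservation = preservation_surface,
             discovery = disc$surface, combined = combined),
        val_cells, thresholds, n_sets = config$n_random_sets,
        seed = config$seed + 51L)
    })
  } else {
    note("independent validation skipped (%d validation cells)", length(val_cells))
  }

  out <- structure(
    list(taxon = taxon, config = config, dataset = dataset,
         envelope_fits = fits, preservation_model = pres_model,
         bias_model = disc$bias, discovery_model = disc$model,
         surfaces = list(climate = climate_surface,
                         preservation = preservation_surface,
                         discovery = disc$surface, combined = combined),
         thresholds = thresholds, validation_cells = val_cells,
         report = report, log = log),
    class = "pipeline_result")
  if (!is.null(output_dir)) write_pipeline_outputs(out, output_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result for", x$taxon, "\n")
  cat("  envelope weights:",
      paste(sprintf("%s=%.2f", names(x$envelope_fits),
                    vapply(x$envelope_fits, function(f) f$tss_weight,
                           numeric(1))), collapse = ", "), "\n")
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

surface_as_layer <- function(surface, name) {
  raster_layer(surface$grid, surface$values, name = name)
}

#' Write the pipeline output bundle to disk
#'
#' Surfaces as CSV layers with sidecars, model coefficients and skill as
#' JSON, the bias-model ranking as CSV, the validation report as JSON, and
#' a plain-text run log recording the seeds.
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(result$surfaces)) {
    s <- result$surfaces[[nm]]
    if (is.null(s)) next
    write_layer(surface_as_layer(s, nm), file.path(dir, paste0(nm, ".csv")))
  }
  env_json <- lapply(result$envelope_fits, function(f) list(
    method = f$method, tss_weight = f$tss_weight,
    training_ranges = as.data.frame(f$training_ranges),
    median_tss = stats::median(f$skill$tss),
    median_auc = stats::median(f$skill$auc)))
  models <- list(
    envelope = env_json,
    preservation = if (!is.null(result$preservation_model))
      result$preservation_model[c("coefficients", "coefficients_raw")],
    discovery = result$discovery_model[c("coefficients", "coefficients_raw",
                                         "epsilon", "weighted")],
    bias = result$bias_model[c("included_predictors", "coefficients", "bic")],
    thresholds = as.list(result$thresholds))
  jsonlite::write_json(models, file.path(dir, "models.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  utils::write.csv(result$bias_model$ranking,
                   file.path(dir, "bias_model_ranking.csv"), row.names = FALSE)
  if (!is.null(result$report)) {
    rep <- result$report
    rep$ks <- lapply(rep$ks, function(x) x[c("median", "q1", "q3")])
    rep$tss <- lapply(rep$tss, function(x) x[c("median", "q1", "q3")])
    jsonlite::write_json(unclass(rep), file.path(dir, "validation_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  writeLines(result$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
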