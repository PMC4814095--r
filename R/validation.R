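#' Two-sample Kolmogorov-Smirnov statistic
#'
#' `D` is the supremum over x of the absolute difference between the two
#' empirical cumulative distribution functions, evaluated at every sample
#' point. Used here as a 0-1 separation measure between suitabilities at
#' fossil sites and at random cells: 1 means every value in one sample
#' exceeds every value in the other.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return D in `[0, 1]`.
#' @export
ks_statistic <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b))
    stop("both samples must be non-empty")
  x <- sort(unique(c(sample_a, sample_b)))
  Fa <- vapply(x, function(v) mean(sample_a <= v), numeric(1))
  Fb <- vapply(x, function(v) mean(sample_b <= v), numeric(1))
  max(abs(Fa - Fb))
}

summary_quartiles <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  c(q1 = q[1], median = q[2], q3 = q[3])
}

draw_random_cells <- function(grid, n_per_set, n_sets, seed,
                              exclude = integer(0)) {
  pool <- setdiff(land_cells(grid), exclude)
  if (n_per_set > length(pool))
    stop("more cells requested per random set than available land cells")
  withr_seed(seed, lapply(seq_len(n_sets),
                          function(i) sample(pool, n_per_set)))
}

#' KS separation of a surface at validation cells versus random cells
#'
#' For each of `n_sets` draws of `length(validation_cells)` random land
#' cells (without replacement within a set), computes the KS statistic
#' between the surface's values at the validation cells and at the random
#' cells. A median near 1 means independent fossil sites sit in the
#' highest-suitability cells.
#'
#' @param surface A `suitability_surface`.
#' @param validation_cells Cell indices of independent fossil sites.
#' @param n_sets Number of random sets (default 1000).
#' @param seed Integer RNG seed.
#' @param exclude_validation Exclude the validation cells from the random
#'   pool (default `TRUE`; random cells may still include other fossil
#'   cells, matching presence-background semantics).
#' @return List with `median`, `q1`, `q3`, and the full `draws` vector.
#' @export
ks_vs_random <- function(surface, validation_cells, n_sets = 1000, seed = 1L,
                         exclude_validation = TRUE) {
  if (n_sets < 1) stop("n_sets must be at least 1")
  v_at <- surface$values[validation_cells]
  sets <- draw_random_cells(surface$grid, length(validation_cells), n_sets,
                            seed,
                            if (exclude_validation) validation_cells else integer(0))
  d <- vapply(sets, function(cells) ks_statistic(v_at, surface$values[cells]),
              numeric(1))
  c(as.list(summary_quartiles(d)), list(draws = d))
}

#' TSS of a surface against random pseudo-absence sets
#'
#' Treats the validation cells as independent presences and, for each of
#' `n_sets` draws of `ratio` times as many random land cells as
#' pseudo-absences, computes the TSS at the TSS-maximising threshold.
#'
#' @inheritParams ks_vs_random
#' @param ratio Pseudo-absences per validation presence (default 10).
#' @return List with `median`, `q1`, `q3`, and the full `draws` vector.
#' @export
tss_vs_random <- function(surface, validation_cells, ratio = 10,
                          n_sets = 1000, seed = 1L,
                          exclude_validation = TRUE) {
  if (n_sets < 1) stop("n_sets must be at least 1")
  if (ratio <= 0) stop("ratio must be positive")
  v_at <- surface$values[validation_cells]
  n_abs <- round(ratio * length(validation_cells))
  sets <- draw_random_cells(surface$grid, n_abs, n_sets, seed,
                            if (exclude_validation) validation_cells else integer(0))
  t <- vapply(sets, function(cells) {
    sa <- surface$values[cells]
    thr <- tss_threshold(v_at, sa)
    compute_tss(sum(v_at >= thr), sum(v_at < thr),
                sum(sa < thr), sum(sa >= thr))
  }, numeric(1))
  c(as.list(summary_quartiles(t)), list(draws = t))
}

#' Probability ratio of finding fossil cells inside a predicted area
#'
#' The probability that a fossil cell lies in the suitable area, divided by
#' the probability of hitting a fossil cell by surveying the whole
#' landmass: `[|fossil in area| / |area|] / [|fossil| / |land|]`. A value
#' of 1 means the predicted area is no better than chance; above 1 it
#' concentrates fossil cells.
#'
#' @param binary_area Logical per-cell vector (`TRUE` = suitable).
#' @param fossil_cells Cell indices of (independent) fossil sites.
#' @param land_cells Cell indices of all land cells.
#' @return The ratio (>= 0).
#' @export
probability_ratio <- function(binary_area, fossil_cells, land_cells) {
  if (!all(fossil_cells %in% land_cells))
    stop("fossil cells must be a subset of land cells")
  area <- intersect(which(binary_area), land_cells)
  if (!length(area)) stop("the predicted suitable area is empty")
  p_in_area <- sum(fossil_cells %in% area) / length(area)
  p_by_chance <- length(fossil_cells) / length(land_cells)
  p_in_area / p_by_chance
}

#' Independent validation report for the three surfaces and their combination
#'
#' Runs the continuous (KS) and binary (TSS, probability-ratio) validations
#' against cells holding only unreliably dated fossils.
#'
#' @param surfaces Named list of rank-rescaled surfaces, including
#'   `climate`, `preservation`, `discovery`, `combined`.
#' @param validation_cells Independent fossil cells.
#' @param thresholds Named numeric vector of TSS-maximising thresholds for
#'   `climate`, `preservation`, `discovery` (on the rank scale).
#' @param n_sets Random sets per statistic (default 1000).
#' @param seed Integer RNG seed.
#' @return A `validation_report` list: per-surface KS and TSS quartiles,
#'   and the three probability ratios (climate area, preservation-discovery
#'   overlap, all-three overlap). A ratio whose suitable area is empty is
#'   reported as `NA` with a message.
#' @export
validation_report <- function(surfaces, validation_cells, thresholds,
                              n_sets = 1000, seed = 1L) {
  grid <- surfaces[[1]]$grid
  land <- land_cells(grid)
  # the same random sets are used for every surface, so per-surface
  # statistics are directly comparable (paired, common random numbers)
  ks <- lapply(surfaces, function(s)
    ks_vs_random(s, validation_cells, n_sets, seed + 1L))
  tss <- lapply(surfaces, function(s)
    tss_vs_random(s, validation_cells, 10, n_sets, seed + 2L))
  bin <- list(
    climate = binarize_surface(surfaces$climate, thresholds[["climate"]]),
    preservation = binarize_surface(surfaces$preservation,
                                    thresholds[["preservation"]]),
    discovery = binarize_surface(surfaces$discovery, thresholds[["discovery"]]))
  # an empty overlap leaves that ratio undefined rather than aborting
  safe_ratio <- function(area) {
    tryCatch(probability_ratio(area, validation_cells, land),
             error = function(e) {
               message("probability ratio undefined: ", conditionMessage(e))
               NA_real_
             })
  }
  pr <- list(
    climate = safe_ratio(bin$climate),
    pres_disc = safe_ratio(overlap_area(bin[c("preservation", "discovery")])),
    all = safe_ratio(overlap_area(bin)))
  structure(list(ks = ks, tss = tss, prob_ratio = pr,
                 n_random_sets = n_sets, seed = seed,
                 n_validation_cells = length(validation_cells)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Independent validation (", x$n_validation_cells, " cells, ",
      x$n_random_sets, " random sets)\n", sep = "")
  for (nm in names(x$ks))
    cat(sprintf("  %-12s KS %.2f (%.2f-%.2f)  TSS %.2f (%.2f-%.2f)\n", nm,
                x$ks[[nm]]$median, x$ks[[nm]]$q1, x$ks[[nm]]$q3,
                x$tss[[nm]]$median, x$tss[[nm]]$q1, x$tss[[nm]]$q3))
  cat(sprintf("  probability ratios: climate %.2f, preservation+discovery %.2f, all %.2f\n",
              x$prob_ratio$climate, x$prob_ratio$pres_disc, x$prob_ratio$all))
  invisible(x)
}
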