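#' Rank-rescale a suitability surface onto the unit interval
#'
#' Because the models are fit to presence-background data, raw outputs are
#' read as relative rankings rather than probabilities. Land-cell values are
#' replaced by `(rank - 1) / (n - 1)` with average ranks for ties, mapping
#' the lowest cell to 0 and the highest to 1 while preserving order; a
#' constant surface maps to 0.5 everywhere. Idempotent.
#'
#' @param surface A `suitability_surface`.
#' @return The rank-rescaled surface.
#' @export
rank_rescale <- function(surface) {
  grid <- surface$grid
  idx <- which(grid$land_mask & !is.na(surface$values))
  if (length(idx) < 2) stop("rank rescaling needs at least 2 valued land cells")
  r <- rank(surface$values[idx], ties.method = "average")
  vals <- rep(NA_real_, n_cells(grid))
  vals[idx] <- (r - 1) / (length(idx) - 1)
  new_surface(grid, vals, surface$extrapolation, surface$slice_age)
}

#' Combine the three suitability rankings into a fossil-potential map
#'
#' The final fossil potential of a cell is the (by default equally) weighted
#' mean of its climate, preservation and discovery rank scores.
#' Extrapolation flags are propagated as the union of the components' flags
#' but do not alter values.
#'
#' @param climate,preservation,discovery Rank-rescaled
#'   `suitability_surface`s on one grid. A `NULL` component is dropped with
#'   a warning and the remaining weights renormalised.
#' @param weights Three non-negative weights, not all zero (default equal).
#' @return An object of class `combined_potential`: a `suitability_surface`
#'   with the components and weights attached.
#' @export
combine_potential <- function(climate, preservation, discovery,
                              weights = c(1, 1, 1)) {
  comps <- list(climate = climate, preservation = preservation,
                discovery = discovery)
  stopifnot(length(weights) == 3, all(weights >= 0))
  missing_comp <- vapply(comps, is.null, logical(1))
  if (any(missing_comp)) {
    warning("component(s) missing from the combination: ",
            paste(names(comps)[missing_comp], collapse = ", "),
            "; weights renormalised over the rest")
    comps <- comps[!missing_comp]
    weights <- weights[!missing_comp]
  }
  if (sum(weights) == 0) stop("weights must not all be zero")
  grids <- lapply(comps, function(s) s$grid)
  g <- grids[[1]]
  for (h in grids[-1])
    if (!identical(h[c("origin_lon", "origin_lat", "cell_size", "n_rows", "n_cols")],
                   g[c("origin_lon", "origin_lat", "cell_size", "n_rows", "n_cols")]))
      stop("component surfaces are not aligned to one grid")
  V <- vapply(comps, function(s) s$values, numeric(n_cells(g)))
  w <- weights / sum(weights)
  vals <- as.numeric(as.matrix(V) %*% w)
  extrap <- Reduce(`|`, lapply(comps, function(s) s$extrapolation))
  out <- new_surface(g, vals, extrap, "combined")
  out$components <- comps
  out$weights <- weights
  class(out) <- c("combined_potential", class(out))
  out
}

#' TSS-maximising binarisation threshold
#'
#' Sweeps every distinct observed score and the midpoints between
#' consecutive distinct scores (plus one candidate above the maximum, the
#' all-unsuitable rule) and returns the threshold maximising the TSS of the
#' rule `score >= threshold`. Ties are broken toward the lowest such
#' threshold, i.e. the larger suitable area — for fossil hunting, missing a
#' presence is costlier than surveying extra cells.
#'
#' @param scores_presence,scores_absence Numeric score vectors.
#' @return The selected threshold.
#' @export
tss_threshold <- function(scores_presence, scores_absence) {
  if (!length(scores_presence) || !length(scores_absence))
    stop("both score lists must be non-empty")
  s <- sort(unique(c(scores_presence, scores_absence)))
  cand <- sort(unique(c(s, (s[-1] + s[-length(s)]) / 2, max(s) + 1)))
  tss <- vapply(cand, function(thr) {
    compute_tss(sum(scores_presence >= thr), sum(scores_presence < thr),
                sum(scores_absence < thr), sum(scores_absence >= thr))
  }, numeric(1))
  cand[which.max(tss)]  # which.max takes the first (lowest) maximiser
}

#' Binarise a surface at a threshold
#'
#' @param surface A `suitability_surface`.
#' @param threshold Cells with `value >= threshold` are suitable.
#' @return Logical per-cell vector (`NA` off-land / nodata).
#' @export
binarize_surface <- function(surface, threshold) {
  out <- surface$values >= threshold
  out[!surface$grid$land_mask] <- NA
  out
}

#' Cellwise overlap (conjunction) of binary suitability maps
#'
#' @param binaries Non-empty list of logical per-cell vectors of one length.
#' @return Logical vector: `TRUE` where every input is `TRUE`.
#' @export
overlap_area <- function(binaries) {
  if (!length(binaries)) stop("no binary surfaces supplied")
  lens <- lengths(binaries)
  if (length(unique(lens)) != 1) stop("binary surfaces differ in length")
  Reduce(`&`, binaries)
}
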