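#' Build a palaeoclimate time slice
#'
#' A slice pairs mean annual temperature (degrees C) and total annual
#' precipitation (mm) layers reconstructed for one past age.
#'
#' @param age_ka Age of the reconstruction in ka before present.
#' @param temperature,precipitation [raster_layer()]s on one shared grid.
#' @return An object of class `climate_slice`.
#' @export
climate_slice <- function(age_ka, temperature, precipitation) {
  stop_unless_aligned(temperature, precipitation)
  stopifnot(is.finite(age_ka), age_ka >= 0)
  structure(list(age_ka = age_ka, temperature = temperature,
                 precipitation = precipitation),
            class = "climate_slice")
}

#' Build an age-ordered palaeoclimate stack
#'
#' @param slices List of [climate_slice()]s; reordered by increasing age.
#'   Ages must be distinct and the list non-empty.
#' @return An object of class `climate_stack`.
#' @export
climate_stack <- function(slices) {
  if (length(slices) == 0) stop("climate stack must contain at least one slice")
  ages <- vapply(slices, function(s) s$age_ka, numeric(1))
  if (anyDuplicated(ages)) stop("slice ages must be distinct")
  slices <- slices[order(ages)]
  structure(list(slices = slices, ages = sort(ages)), class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf("climate_stack: %d slices, %g-%g ka\n",
              length(x$slices), min(x$ages), max(x$ages)))
  invisible(x)
}

#' Read a climate stack from a YAML manifest
#'
#' The manifest lists one entry per slice: `age_ka`, `temperature_path`,
#' `precipitation_path`, each path a CSV layer readable by [read_layer()].
#' Relative paths resolve against the manifest's directory.
#'
#' @param path Manifest YAML path.
#' @param grid Target [grid_spec()].
#' @return A [climate_stack()].
#' @export
read_stack_manifest <- function(path, grid) {
  man <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  slices <- lapply(man, function(e) {
    climate_slice(e$age_ka,
                  read_layer(resolve(e$temperature_path), grid),
                  read_layer(resolve(e$precipitation_path), grid))
  })
  climate_stack(slices)
}

#' Write a climate stack and its manifest
#'
#' @param stack A [climate_stack()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- lapply(stack$slices, function(s) {
    tp <- sprintf("tas_%gka.csv", s$age_ka)
    pp <- sprintf("pr_%gka.csv", s$age_ka)
    write_layer(s$temperature, file.path(dir, tp))
    write_layer(s$precipitation, file.path(dir, pp))
    list(age_ka = s$age_ka, temperature_path = tp, precipitation_path = pp)
  })
  mp <- file.path(dir, "stack.yml")
  yaml::write_yaml(man, mp)
  invisible(mp)
}

#' Select the time slices matching a fossil's age window
#'
#' Returns every slice within `k_sd` age standard deviations of the mean
#' fossil age (ties at the window edge included), always including the
#' single nearest slice so the result is never empty; a zero age SD or an
#' age beyond the stack therefore yields just the nearest slice.
#'
#' @param age_mean,age_sd Calibrated age mean and SD in ka.
#' @param stack A [climate_stack()].
#' @param k_sd Window half-width in SD units (default 2; the alternative
#'   1-SD window is the other published setting).
#' @return Integer indices into `stack$slices`.
#' @export
select_slices <- function(age_mean, age_sd, stack, k_sd = 2) {
  if (length(stack$slices) == 0) stop("empty climate stack")
  stopifnot(k_sd > 0, age_sd >= 0)
  d <- abs(stack$ages - age_mean)
  sel <- which(d <= k_sd * age_sd)
  nearest <- which.min(d)
  sort(unique(c(sel, nearest)))
}

#' Gaussian-weighted climate at a fossil's cell
#'
#' Averages temperature and precipitation over the slices selected by
#' [select_slices()], weighting each slice by a Gaussian kernel in age with
#' SD equal to the fossil's age SD, so slices closer in time to the mean
#' fossil age influence the average more. With `age_sd = 0` the weight
#' collapses onto the nearest slice. Slices with missing climate at the cell
#' are dropped before the weights are renormalised.
#'
#' @param age_mean,age_sd Fossil age mean and SD (ka).
#' @param cell Grid cell index of the fossil.
#' @param stack A [climate_stack()].
#' @param k_sd Slice-selection window in SD units (default 2).
#' @return Named numeric vector `c(temperature=, precipitation=)`.
#' @export
gaussian_weighted_climate <- function(age_mean, age_sd, cell, stack, k_sd = 2) {
  idx <- select_slices(age_mean, age_sd, stack, k_sd)
  ages <- stack$ages[idx]
  if (age_sd > 0) {
    w <- exp(-(ages - age_mean)^2 / (2 * age_sd^2))
  } else {
    w <- as.numeric(ages == ages[which.min(abs(ages - age_mean))])
  }
  tv <- vapply(stack$slices[idx], function(s) s$temperature$values[cell], numeric(1))
  pv <- vapply(stack$slices[idx], function(s) s$precipitation$values[cell], numeric(1))
  ok <- !is.na(tv) & !is.na(pv)
  if (!any(ok)) stop("no climate data at cell ", cell, " in any selected slice")
  w <- w[ok] / sum(w[ok])
  c(temperature = sum(w * tv[ok]), precipitation = sum(w * pv[ok]))
}

#' Time-matched climate for a table of fossil records
#'
#' @param records Fossil record `data.frame`.
#' @param grid A [grid_spec()].
#' @param stack A [climate_stack()].
#' @param k_sd Slice-selection window in SD units.
#' @return `data.frame` with columns `cell`, `slice_age` (nearest slice age),
#'   `temperature`, `precipitation`; records outside the grid are dropped
#'   with a warning (via [presence_cells()] semantics).
#' @export
match_climate <- function(records, grid, stack, k_sd = 2) {
  cells <- locate_cell(records$lon, records$lat, grid)
  keep <- which(!is.na(cells))
  res <- lapply(keep, function(i) {
    cl <- gaussian_weighted_climate(records$age_mean_ka[i], records$age_sd_ka[i],
                                    cells[i], stack, k_sd)
    nearest <- stack$ages[which.min(abs(stack$ages - records$age_mean_ka[i]))]
    data.frame(cell = cells[i], slice_age = nearest,
               temperature = cl[["temperature"]],
               precipitation = cl[["precipitation"]])
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}
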