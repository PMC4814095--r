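#' Configuration for a synthetic continent with known ground truth
#'
#' The generator forward-simulates every process the pipeline later tries
#' to recover: a smooth climate history with a glacial excursion, a focal
#' taxon with a bivariate Gaussian climate envelope, fossil deposition
#' conditioned on geological traps (rock, lakes, caves), exposure
#' conditioned on erosion proxies, and detection biased toward accessible
#' cells near synthetic cities. Background taxa deposited without a climate
#' envelope emulate the rest of a continental fossil database, supplying
#' the pseudo-absence pool and the all-taxa response of the preservation
#' and discovery models.
#'
#' @param n_rows,n_cols Grid dimensions (default 60 x 60 one-degree cells).
#' @param slice_ages Ages (ka) of the climate slices; the default is a
#'   tiered sequence denser toward the present (2 ka steps to 22 ka, 6 ka
#'   to 80 ka, 8 ka to 120 ka), mirroring how reconstructions resolve the
#'   recent past better.
#' @param temp_drift,precip_drift Amplitude of the glacial excursion
#'   (centred on 20 ka) in degrees C and mm; 0 freezes the climate.
#' @param envelope Named vector `t_opt, p_opt, t_sd, p_sd`: the focal
#'   taxon's climatic optimum and tolerance.
#' @param preservation_beta Intercept and logistic slopes for rock cover,
#'   lake cover, cave presence (raw scale, covers in `[0, 1]`).
#' @param exposure_beta Intercept and logistic slopes for z-scored slope,
#'   rain intensity, bare soil.
#' @param bias_beta Intercept and logistic slopes for z-scored population
#'   density, road density, distance to large cities, distance to medium
#'   cities (negative distance slopes: nearer is better sampled).
#' @param n_fossils Focal-taxon fossil records (default 150).
#' @param n_other_fossils Background-taxa records (default 300).
#' @param fraction_unreliable Share of focal records given unreliable age
#'   grades (B/C) and so held out for validation (default 0.25).
#' @param age_sd_range Range the per-record age SD is drawn from (ka).
#' @param age_noise_sd SD of the noise added to the slice age (ka).
#' @param land_fraction Share of cells kept as land (default 0.88).
#' @param seed Integer seed; the whole world is deterministic given it.
#' @return A `synthetic_world_config` list.
#' @export
synthetic_world_config <- function(
    n_rows = 60, n_cols = 60,
    slice_ages = c(seq(0, 22, 2), seq(26, 80, 6), seq(88, 120, 8)),
    temp_drift = 4, precip_drift = 250,
    envelope = c(t_opt = 22, p_opt = 800, t_sd = 3, p_sd = 250),
    preservation_beta = c(intercept = -1.5, rock_cover = 2,
                          lake_cover = 1.5, cave_presence = 1),
    exposure_beta = c(intercept = -1, slope = 1,
                      rain_intensity = 0.6, bare_soil = 0.8),
    bias_beta = c(intercept = -0.5, population_density = 1,
                  road_density = 0.5, dist_large_cities = -0.7,
                  dist_medium_cities = -0.3),
    n_fossils = 150, n_other_fossils = 300,
    fraction_unreliable = 0.25,
    age_sd_range = c(1, 4), age_noise_sd = 0.5,
    land_fraction = 0.88, seed = 42L) {
  stopifnot(n_rows >= 4, n_cols >= 4, length(slice_ages) >= 1,
            all(envelope[c("t_sd", "p_sd")] > 0),
            fraction_unreliable >= 0, fraction_unreliable <= 1,
            land_fraction > 0, land_fraction <= 1,
            age_sd_range[1] >= 0, diff(age_sd_range) >= 0)
  structure(as.list(environment()), class = "synthetic_world_config")
}

# smooth random field in [0, 1]: a sum of seeded Gaussian bumps, so values
# are spatially autocorrelated at the bump length scale
smooth_field <- function(n_rows, n_cols, n_bumps = 8, rel_width = c(0.1, 0.35)) {
  rc <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  f <- numeric(nrow(rc))
  ext <- max(n_rows, n_cols)
  for (i in seq_len(n_bumps)) {
    cx <- stats::runif(1, 1, n_cols); cy <- stats::runif(1, 1, n_rows)
    wdt <- stats::runif(1, rel_width[1], rel_width[2]) * ext
    amp <- stats::rnorm(1)
    f <- f + amp * exp(-((rc$col - cx)^2 + (rc$row - cy)^2) / (2 * wdt^2))
  }
  rng <- range(f)
  if (diff(rng) == 0) return(rep(0.5, length(f)))
  (f - rng[1]) / diff(rng)  # row-major (north-west first) ordering
}

zscore <- function(v) {
  s <- stats::sd(v, na.rm = TRUE)
  if (is.na(s) || s == 0) s <- 1
  (v - mean(v, na.rm = TRUE)) / s
}

glacial_kernel <- function(age) exp(-(age - 20)^2 / (2 * 15^2))

#' Generate a synthetic continent
#'
#' Builds the grid and land mask, the climate stack (smooth present-day
#' temperature/precipitation fields plus a glacial excursion and a small
#' drift-scaled per-slice anomaly), geological, erosion and accessibility
#' layers, and the true per-cell suitability surfaces implied by the
#' configuration. Deterministic given `config$seed`.
#'
#' @param config A [synthetic_world_config()].
#' @return A `synthetic_world` list: `grid`, `stack`, `layers` (named
#'   [raster_layer()]s), `truth` (occurrence averaged over slices,
#'   preservation, discovery, and their product), and per-cell process
#'   probabilities used by [simulate_fossil_records()].
#' @export
generate_world <- function(config) {
  cfg <- config
  withr_seed(cfg$seed, {
    nr <- cfg$n_rows; nc <- cfg$n_cols; n <- nr * nc
    mask_field <- smooth_field(nr, nc, n_bumps = 10)
    land <- mask_field >= stats::quantile(mask_field, 1 - cfg$land_fraction)
    grid <- grid_spec(110, -45, nr, nc, cell_size = 1, land_mask = land)
    cen <- cell_centroid(seq_len(n), grid)

    # present-day climate: latitudinal temperature gradient and a west-east
    # precipitation gradient, each warped by a smooth field
    t0 <- 28 - 0.35 * (max(cen[, "lat"]) - cen[, "lat"]) +
      6 * (smooth_field(nr, nc) - 0.5)
    p0 <- pmax(60, 250 + 900 * (cen[, "lon"] - min(cen[, "lon"])) /
                 max(1, diff(range(cen[, "lon"]))) +
                 500 * (smooth_field(nr, nc) - 0.5))

    mask_na <- function(v) { v[!land] <- NA_real_; v }
    slices <- lapply(cfg$slice_ages, function(a) {
      k <- glacial_kernel(a)
      anom_t <- 0.1 * cfg$temp_drift * (smooth_field(nr, nc) - 0.5)
      anom_p <- 0.1 * cfg$precip_drift * (smooth_field(nr, nc) - 0.5)
      climate_slice(a,
        raster_layer(grid, mask_na(t0 - cfg$temp_drift * k + anom_t),
                     name = sprintf("tas_%gka", a)),
        raster_layer(grid, mask_na(pmax(30, p0 - cfg$precip_drift * k + anom_p)),
                     name = sprintf("pr_%gka", a)))
    })
    stack <- climate_stack(slices)

    # geological traps: much finer spatial grain than climate (rock units,
    # lake basins and karst vary at ~100 km scales, not continental ones)
    rock <- smooth_field(nr, nc, n_bumps = 40, rel_width = c(0.04, 0.12))
    lake <- pmax(0, smooth_field(nr, nc, n_bumps = 35, rel_width = c(0.02, 0.07)) - 0.55) / 0.45
    cave_field <- smooth_field(nr, nc, n_bumps = 35, rel_width = c(0.02, 0.08))
    cave <- as.numeric(cave_field > stats::quantile(cave_field, 0.8))
    pb <- cfg$preservation_beta
    p_pres <- stats::plogis(pb[["intercept"]] + pb[["rock_cover"]] * rock +
                              pb[["lake_cover"]] * lake +
                              pb[["cave_presence"]] * cave)

    # erosion proxies, again at topographic rather than continental grain
    slope <- 18 * smooth_field(nr, nc, n_bumps = 35, rel_width = c(0.03, 0.10))
    rain_days <- pmax(10, 160 * smooth_field(nr, nc) *
                        (p0 / max(p0)) + 20)
    rain_int_v <- p0 / rain_days
    bare <- smooth_field(nr, nc, n_bumps = 30, rel_width = c(0.04, 0.12))
    eb <- cfg$exposure_beta
    zs <- zscore(mask_na(slope)); zr <- zscore(mask_na(rain_int_v))
    zb <- zscore(mask_na(bare))
    p_expo <- stats::plogis(eb[["intercept"]] + eb[["slope"]] * zs +
                              eb[["rain_intensity"]] * zr +
                              eb[["bare_soil"]] * zb)

    # accessibility: cities on land, density decaying with distance
    land_idx <- which(land)
    large <- sample(land_idx, 2)
    medium <- sample(land_idx, 6)
    dmin <- function(cities) {
      cc <- cell_centroid(cities, grid)
      apply(cen, 1, function(pt)
        min(sqrt((pt[1] - cc[, "lon"])^2 + (pt[2] - cc[, "lat"])^2)))
    }
    d_large <- dmin(large); d_medium <- dmin(medium)
    pop <- 3 * exp(-d_large^2 / (2 * 6^2)) + exp(-d_medium^2 / (2 * 4^2)) +
      0.2 * smooth_field(nr, nc)
    road <- 0.7 * pop / max(pop) + 0.3 * smooth_field(nr, nc)
    bb <- cfg$bias_beta
    p_samp <- stats::plogis(bb[["intercept"]] +
                              bb[["population_density"]] * zscore(mask_na(pop)) +
                              bb[["road_density"]] * zscore(mask_na(road)) +
                              bb[["dist_large_cities"]] * zscore(mask_na(d_large)) +
                              bb[["dist_medium_cities"]] * zscore(mask_na(d_medium)))

    # true occurrence probability per slice, and its lifetime average
    env <- cfg$envelope
    occ_slice <- vapply(stack$slices, function(s) {
      tv <- s$temperature$values; pv <- s$precipitation$values
      exp(-0.5 * ((tv - env[["t_opt"]]) / env[["t_sd"]])^2 -
            0.5 * ((pv - env[["p_opt"]]) / env[["p_sd"]])^2)
    }, numeric(n))
    occ_mean <- rowMeans(occ_slice)

    lay <- function(v, nm) raster_layer(grid, mask_na(v), name = nm)
    layers <- list(
      rock_cover = lay(rock, "rock_cover"),
      lake_cover = lay(lake, "lake_cover"),
      cave_presence = lay(cave, "cave_presence"),
      slope = lay(slope, "slope"),
      annual_precip = stack$slices[[1]]$precipitation,
      rain_days = lay(rain_days, "rain_days"),
      rain_intensity = lay(rain_int_v, "rain_intensity"),
      bare_soil = lay(bare, "bare_soil"),
      population_density = lay(pop, "population_density"),
      road_density = lay(road, "road_density"),
      dist_large_cities = lay(d_large, "dist_large_cities"),
      dist_medium_cities = lay(d_medium, "dist_medium_cities"))
    truth <- list(
      occurrence = lay(occ_mean, "true_occurrence"),
      preservation = lay(p_pres, "true_preservation"),
      discovery = lay(p_expo, "true_discovery"),
      product = lay(occ_mean * p_pres * p_expo, "true_product"))
    structure(list(config = cfg, grid = grid, stack = stack,
                   layers = layers, truth = truth,
                   process = list(occ_slice = occ_slice,
                                  preservation = mask_na(p_pres),
                                  exposure = mask_na(p_expo),
                                  sampling = mask_na(p_samp))),
              class = "synthetic_world")
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("synthetic_world: %dx%d grid (%d land cells), %d climate slices, seed %d\n",
              x$grid$n_rows, x$grid$n_cols, sum(x$grid$land_mask),
              length(x$stack$slices), x$config$seed))
  invisible(x)
}

#' Simulate a fossil-record table from a synthetic world
#'
#' Focal-taxon fossils land in (cell, slice) pairs with probability
#' proportional to occurrence x preservation x exposure x sampling;
#' background-taxa fossils omit the occurrence term. Ages are the slice age
#' plus Gaussian noise (so temporal cross-validation has well-defined
#' rounds), with a per-record age SD drawn from `age_sd_range`. A
#' `fraction_unreliable` share of focal records is graded B/C; the rest
#' (and all background records) are graded A*/A.
#'
#' @param world A `synthetic_world`.
#' @param taxon Focal taxon name (default `"Simulodon"`).
#' @return Fossil-record `data.frame` in [read_fossil_csv()] layout.
#' @export
simulate_fossil_records <- function(world, taxon = "Simulodon") {
  cfg <- world$config
  grid <- world$grid
  pr <- world$process
  n <- n_cells(grid)
  n_sl <- length(world$stack$slices)
  withr_seed(cfg$seed + 1L, {
    base <- pr$preservation * pr$exposure * pr$sampling
    focal_int <- as.numeric(pr$occ_slice * base)      # n x n_slices, col-major
    focal_int[is.na(focal_int)] <- 0
    if (sum(focal_int) <= 0) stop("total fossil deposition intensity is zero")
    draw_records <- function(intensity, n_rec, taxa, unreliable_frac) {
      pick <- sample.int(length(intensity), n_rec, replace = TRUE,
                         prob = intensity)
      cell <- (pick - 1L) %% n + 1L
      slice <- (pick - 1L) %/% n + 1L
      age0 <- world$stack$ages[slice]
      rc <- cell_rowcol(cell, grid)
      cs <- grid$cell_size
      north <- grid$origin_lat + grid$n_rows * cs
      lon <- grid$origin_lon + (rc[, "col"] - 1 + stats::runif(n_rec)) * cs
      lat <- north - (rc[, "row"] - stats::runif(n_rec)) * cs
      unrel <- stats::runif(n_rec) < unreliable_frac
      quality <- ifelse(unrel, sample(c("B", "C"), n_rec, replace = TRUE),
                        sample(c("A*", "A"), n_rec, replace = TRUE))
      data.frame(
        taxon = sample(taxa, n_rec, replace = TRUE),
        lon = lon, lat = lat,
        age_mean_ka = pmax(0.1, age0 + stats::rnorm(n_rec, 0, cfg$age_noise_sd)),
        age_sd_ka = stats::runif(n_rec, cfg$age_sd_range[1], cfg$age_sd_range[2]),
        quality = quality,
        site_id = NA_character_)
    }
    focal <- draw_records(focal_int, cfg$n_fossils, taxon,
                          cfg$fraction_unreliable)
    recs <- focal
    if (cfg$n_other_fossils > 0) {
      other_int <- as.numeric(matrix(base, n, n_sl))
      other_int[is.na(other_int)] <- 0
      other <- draw_records(other_int, cfg$n_other_fossils,
                            c("Crypticotherium", "Latebrornis"), 0.25)
      recs <- rbind(focal, other)
    }
    recs$site_id <- sprintf("S%04d", seq_len(nrow(recs)))
    recs
  })
}

#' Write a synthetic world and records to pipeline-ready files
#'
#' Emits exactly the formats the pipeline consumes: CSV layers with YAML
#' sidecars, a stack manifest, and the fossil CSV.
#'
#' @param world A `synthetic_world`.
#' @param records Fossil `data.frame` from [simulate_fossil_records()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_stack(world$stack, file.path(dir, "climate"))
  for (nm in names(world$layers))
    write_layer(world$layers[[nm]], file.path(dir, paste0(nm, ".csv")))
  utils::write.csv(records, file.path(dir, "fossils.csv"), row.names = FALSE)
  invisible(dir)
}
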