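# Shared fixtures: tiny grids, constant-gradient climate stacks, and a
# down-sized synthetic world for unit tests. Everything is built in code.

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

tiny_grid <- function(n_rows = 4, n_cols = 5, origin_lon = 0, origin_lat = 0,
                      cell_size = 1, land_mask = NULL) {
  grid_spec(origin_lon, origin_lat, n_rows, n_cols,
            cell_size = cell_size, land_mask = land_mask)
}

const_slice <- function(age, grid, temp, precip) {
  climate_slice(age,
                raster_layer(grid, rep(temp, grid$n_rows * grid$n_cols)),
                raster_layer(grid, rep(precip, grid$n_rows * grid$n_cols)))
}

# stack whose per-slice climates are simple known functions of age
linear_stack <- function(ages, grid, t0 = 20, p0 = 500,
                         t_per_ka = 0, p_per_ka = 0) {
  climate_stack(lapply(ages, function(a)
    const_slice(a, grid, t0 + t_per_ka * a, p0 + p_per_ka * a)))
}

clim_df <- function(temperature, precipitation, cell = seq_along(temperature),
                    slice_age = 10) {
  data.frame(cell = cell, slice_age = slice_age,
             temperature = temperature, precipitation = precipitation)
}

small_world_config <- function(seed, n_fossils = 80, n_other_fossils = 160, ...) {
  synthetic_world_config(n_rows = 30, n_cols = 30,
                         slice_ages = c(seq(0, 20, 4), seq(28, 60, 8)),
                         n_fossils = n_fossils,
                         n_other_fossils = n_other_fossils,
                         seed = seed, ...)
}

# independent oracles -------------------------------------------------------

auc_oracle <- function(sp, sa) {
  wins <- 0
  for (p in sp) for (a in sa)
    wins <- wins + (p > a) + 0.5 * (p == a)
  wins / (length(sp) * length(sa))
}

ks_oracle <- function(a, b) {
  d <- 0
  for (x in c(a, b))
    d <- max(d, abs(sum(a <= x) / length(a) - sum(b <= x) / length(b)))
  d
}

clim_matrix_test <- function(df)
  as.matrix(df[, c("temperature", "precipitation")])

bioclim_oracle <- function(pres, pts) {
  score_one <- function(x, v) {
    if (min(v) == max(v)) return(as.numeric(x == v[1]))
    if (x < min(v) || x > max(v)) return(0)
    p <- sum(v <= x) / length(v)
    2 * min(p, 1 - p)
  }
  apply(pts, 1, function(pt)
    min(score_one(pt[1], pres[, 1]), score_one(pt[2], pres[, 2])))
}

best_tss_oracle <- function(sp, sa) {
  cand <- sort(unique(c(sp, sa)))
  cand <- sort(unique(c(cand, cand - 1e-9, max(cand) + 1)))
  best <- -Inf
  for (thr in cand) {
    tss <- sum(sp >= thr) / length(sp) + sum(sa < thr) / length(sa) - 1
    best <- max(best, tss)
  }
  best
}

tss_at <- function(sp, sa, thr) {
  compute_tss(sum(sp >= thr), sum(sp < thr), sum(sa < thr), sum(sa >= thr))
}
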