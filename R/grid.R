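#' Define a regular geographic grid
#'
#' A `grid_spec` fixes the cell lattice every per-cell vector in the package
#' refers to: a regular lon/lat grid of `cell_size`-degree cells whose
#' south-west corner sits at (`origin_lon`, `origin_lat`). Cells are addressed
#' row-major from the north-west corner, so cell 1 is the top-left cell and
#' cell `n_rows * n_cols` the bottom-right one. A logical `land_mask` marks
#' which cells take part in analyses; sea cells are carried as `NA` in layers.
#'
#' @param origin_lon,origin_lat Longitude/latitude of the grid's south-west
#'   outer corner, in decimal degrees.
#' @param n_rows,n_cols Grid dimensions (cells).
#' @param cell_size Cell edge length in degrees (default 1).
#' @param land_mask Logical vector of length `n_rows * n_cols` in row-major
#'   (north-west first) order; `NULL` means all land.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(110, -45, n_rows = 35, n_cols = 45)
#' locate_cell(138.3, -29.7, g)
#' @export
grid_spec <- function(origin_lon, origin_lat, n_rows, n_cols,
                      cell_size = 1, land_mask = NULL) {
  stopifnot(is.finite(origin_lon), is.finite(origin_lat),
            cell_size > 0, n_rows >= 1, n_cols >= 1)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  n <- n_rows * n_cols
  if (is.null(land_mask)) land_mask <- rep(TRUE, n)
  if (length(land_mask) != n)
    stop("land_mask must have length n_rows * n_cols")
  structure(
    list(origin_lon = origin_lon, origin_lat = origin_lat,
         cell_size = cell_size, n_rows = n_rows, n_cols = n_cols,
         land_mask = as.logical(land_mask)),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g deg, SW corner (%g, %g), %d land cells\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_lon, x$origin_lat,
              sum(x$land_mask)))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

land_cells <- function(grid) which(grid$land_mask)

#' Row/column to cell index and back
#'
#' @param row,col 1-based row (from the north) and column (from the west).
#' @param grid A [grid_spec()].
#' @return `cell_index()` returns the row-major index; `cell_rowcol()` a
#'   two-column matrix of (row, col).
#' @export
cell_index <- function(row, col, grid) {
  stopifnot(all(row >= 1 & row <= grid$n_rows),
            all(col >= 1 & col <= grid$n_cols))
  (row - 1L) * grid$n_cols + col
}

#' @rdname cell_index
#' @param cell Row-major cell index.
#' @export
cell_rowcol <- function(cell, grid) {
  cell <- as.integer(cell)
  cbind(row = (cell - 1L) %/% grid$n_cols + 1L,
        col = (cell - 1L) %% grid$n_cols + 1L)
}

#' Cell centroid coordinates
#'
#' @inheritParams cell_rowcol
#' @return Two-column matrix of (lon, lat) centroids in degrees.
#' @export
cell_centroid <- function(cell, grid) {
  rc <- cell_rowcol(cell, grid)
  cs <- grid$cell_size
  north <- grid$origin_lat + grid$n_rows * cs
  cbind(lon = grid$origin_lon + (rc[, "col"] - 0.5) * cs,
        lat = north - (rc[, "row"] - 0.5) * cs)
}

#' Locate the grid cell containing a point
#'
#' Cell ownership is half-open on the west and south edges: a cell covers
#' `[west, west + cell_size) x [south, south + cell_size)`, so every point
#' maps to exactly one cell or to none (on or beyond the north/east outer
#' boundary). Vectorised over coordinates.
#'
#' @param lon,lat Coordinates in degrees.
#' @param grid A [grid_spec()].
#' @return Integer cell index (row-major from the north-west), `NA` for points
#'   outside the grid extent.
#' @export
locate_cell <- function(lon, lat, grid) {
  if (any(!is.finite(lon)) || any(!is.finite(lat)))
    stop("non-finite coordinates")
  cs <- grid$cell_size
  col <- floor((lon - grid$origin_lon) / cs) + 1
  row_from_s <- floor((lat - grid$origin_lat) / cs)  # 0-based from the south
  row <- grid$n_rows - row_from_s                    # 1-based from the north
  ok <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
  out <- rep(NA_integer_, length(col))
  out[ok] <- as.integer((row[ok] - 1) * grid$n_cols + col[ok])
  out
}

#' Per-cell raster layer on a grid
#'
#' Thin container pairing a numeric per-cell vector with its [grid_spec()].
#' `NA` values mark nodata cells and are excluded from all statistics.
#'
#' @param grid A [grid_spec()].
#' @param values Numeric vector of length `n_rows * n_cols`, row-major from
#'   the north-west corner, or a `n_rows x n_cols` matrix.
#' @param name Optional layer name used in messages and sidecar metadata.
#' @return An object of class `raster_layer`.
#' @export
raster_layer <- function(grid, values, name = "layer") {
  if (is.matrix(values)) {
    stopifnot(nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
    values <- as.numeric(t(values))
  }
  if (length(values) != n_cells(grid))
    stop("values length does not match grid")
  structure(list(grid = grid, values = as.numeric(values), name = name),
            class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  v <- x$values[x$grid$land_mask & !is.na(x$values)]
  cat(sprintf("raster_layer '%s' on %dx%d grid; land range [%g, %g]\n",
              x$name, x$grid$n_rows, x$grid$n_cols,
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

layer_matrix <- function(layer) {
  matrix(layer$values, layer$grid$n_rows, layer$grid$n_cols, byrow = TRUE)
}

stop_unless_aligned <- function(...) {
  layers <- list(...)
  g <- layers[[1]]$grid
  for (l in layers[-1]) {
    h <- l$grid
    if (h$n_rows != g$n_rows || h$n_cols != g$n_cols ||
        h$cell_size != g$cell_size ||
        h$origin_lon != g$origin_lon || h$origin_lat != g$origin_lat)
      stop("raster layers are not aligned to one grid")
  }
  invisible(g)
}

grid_to_list <- function(grid) {
  list(origin_lon = grid$origin_lon, origin_lat = grid$origin_lat,
       cell_size = grid$cell_size, n_rows = grid$n_rows,
       n_cols = grid$n_cols,
       land_mask = paste(as.integer(grid$land_mask), collapse = ""))
}

grid_from_list <- function(x) {
  mask <- NULL
  if (!is.null(x$land_mask))
    mask <- as.integer(strsplit(x$land_mask, "")[[1]]) == 1L
  grid_spec(x$origin_lon, x$origin_lat, x$n_rows, x$n_cols,
            cell_size = x$cell_size, land_mask = mask)
}

sidecar_path <- function(path) paste0(path, ".yml")

#' Write a raster layer to disk
#'
#' The native format is a CSV table with columns `row`, `col`, `value`
#' (nodata cells omitted) plus a YAML sidecar `<path>.yml` carrying the grid
#' spec, so a layer file is self-describing. Values are written at full
#' double precision and round-trip bitwise.
#'
#' @param layer A [raster_layer()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_layer <- function(layer, path) {
  grid <- layer$grid
  keep <- which(!is.na(layer$values))
  rc <- cell_rowcol(keep, grid)
  df <- data.frame(row = rc[, "row"], col = rc[, "col"],
                   value = sprintf("%.17g", layer$values[keep]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  yaml::write_yaml(c(grid_to_list(grid), list(name = layer$name)),
                   sidecar_path(path))
  invisible(path)
}

#' Read a raster layer, aligning it to a target grid
#'
#' Reads the CSV (row, col, value) dialect written by [write_layer()]; the
#' YAML sidecar supplies the source grid. If the source grid matches `grid`
#' the values are taken as-is; if it is an integer refinement of `grid`
#' (finer cells nested inside the target cells, same extent) it is
#' aggregated: by mean of non-missing subcells for continuous layers, or by
#' presence-any for binary layers.
#'
#' @param path CSV path (sidecar `<path>.yml` must exist).
#' @param grid Target [grid_spec()].
#' @param aggregate `"mean"` (continuous) or `"any"` (binary presence).
#' @return A [raster_layer()] on `grid`.
#' @export
read_layer <- function(path, grid, aggregate = c("mean", "any")) {
  aggregate <- match.arg(aggregate)
  if (!file.exists(path)) stop("unreadable file: ", path)
  if (!file.exists(sidecar_path(path)))
    stop("missing grid sidecar: ", sidecar_path(path))
  meta <- yaml::read_yaml(sidecar_path(path))
  src <- grid_from_list(meta)
  if (abs(src$origin_lon) > 360 || abs(src$origin_lat) > 90)
    stop("source CRS is not geographic (origin out of lon/lat range)")
  df <- utils::read.csv(path)
  vals <- rep(NA_real_, n_cells(src))
  vals[cell_index(df$row, df$col, src)] <- df$value

  same <- src$cell_size == grid$cell_size &&
    src$origin_lon == grid$origin_lon && src$origin_lat == grid$origin_lat &&
    src$n_rows == grid$n_rows && src$n_cols == grid$n_cols
  if (same)
    return(raster_layer(grid, vals, name = meta$name %||% "layer"))

  # extent overlap check
  src_e <- c(src$origin_lon, src$origin_lon + src$n_cols * src$cell_size,
             src$origin_lat, src$origin_lat + src$n_rows * src$cell_size)
  tgt_e <- c(grid$origin_lon, grid$origin_lon + grid$n_cols * grid$cell_size,
             grid$origin_lat, grid$origin_lat + grid$n_rows * grid$cell_size)
  if (src_e[2] <= tgt_e[1] || src_e[1] >= tgt_e[2] ||
      src_e[4] <= tgt_e[3] || src_e[3] >= tgt_e[4])
    stop("source extent is disjoint from the target grid")

  ratio <- grid$cell_size / src$cell_size
  if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1)
    stop("source grid is neither identical to nor a refinement of the target")
  # aggregate finer cells into the target cell containing their centroid
  src_cells <- seq_len(n_cells(src))
  cen <- cell_centroid(src_cells, src)
  tgt <- locate_cell(cen[, "lon"], cen[, "lat"], grid)
  keep <- !is.na(tgt) & !is.na(vals)
  out <- rep(NA_real_, n_cells(grid))
  if (any(keep)) {
    if (aggregate == "mean") {
      agg <- tapply(vals[keep], tgt[keep], mean)
    } else {
      agg <- tapply(vals[keep], tgt[keep], function(v) as.numeric(any(v != 0)))
    }
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  raster_layer(grid, out, name = meta$name %||% "layer")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
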