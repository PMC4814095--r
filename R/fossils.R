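#' Read a fossil-record table
#'
#' Expects a UTF-8 CSV with header columns `taxon, lon, lat, age_mean_ka,
#' age_sd_ka, quality, site_id`. Ages are calibrated thousands of years
#' before present; `quality` is the four-level age-reliability grade
#' (`A*`, `A`, `B`, `C`, in decreasing reliability).
#'
#' @param path CSV file path.
#' @return A `data.frame` of fossil records with validated columns.
#' @export
read_fossil_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("taxon", "lon", "lat", "age_mean_ka", "age_sd_ka", "quality", "site_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("fossil CSV missing columns: ", paste(miss, collapse = ", "))
  validate_fossil_records(df)
  df
}

QUALITY_LEVELS <- c("A*", "A", "B", "C")
RELIABLE_LEVELS <- c("A*", "A")

validate_fossil_records <- function(records) {
  bad <- which(!(records$quality %in% QUALITY_LEVELS))
  if (length(bad))
    stop("unknown age-quality code '", records$quality[bad[1]],
         "' in record ", bad[1],
         " (site ", records$site_id[bad[1]], ")")
  if (any(records$age_mean_ka <= 0)) stop("age_mean_ka must be positive")
  if (any(records$age_sd_ka < 0)) stop("age_sd_ka must be non-negative")
  invisible(records)
}

#' Split fossil records into reliably and unreliably dated sets
#'
#' Records graded `A*` or `A` have reliable calibrated ages and are used to
#' train the climate-envelope models; the remainder (`B`, `C`) are held out
#' as independent validation data. Input order is preserved in both outputs
#' and the two sets partition the input.
#'
#' @param records Fossil record `data.frame` (see [read_fossil_csv()]).
#' @return List with elements `training` and `validation`.
#' @export
filter_reliable <- function(records) {
  validate_fossil_records(records)
  reliable <- records$quality %in% RELIABLE_LEVELS
  list(training = records[reliable, , drop = FALSE],
       validation = records[!reliable, , drop = FALSE])
}

#' Grid cells containing at least one fossil record
#'
#' Collapses records to unique presence cells: the response in all three
#' suitability models is fossil presence/absence at the cell level, never
#' density, to avoid bias from spatially aggregated prospecting. Records
#' falling outside the grid are dropped with a warning.
#'
#' @param records Fossil record `data.frame`.
#' @param grid A [grid_spec()].
#' @return Sorted integer vector of unique cell indices.
#' @export
presence_cells <- function(records, grid) {
  if (nrow(records) == 0) return(integer(0))
  cells <- locate_cell(records$lon, records$lat, grid)
  out <- which(is.na(cells))
  if (length(out))
    warning(length(out), " record(s) outside the grid extent excluded (sites: ",
            paste(utils::head(records$site_id[out], 5), collapse = ", "), ")")
  sort(unique(cells[!is.na(cells)]))
}

#' Validation cells: cells holding only unreliably dated fossils
#'
#' Cells that contain at least one reliably dated record contribute to
#' training and are excluded here, keeping the validation set spatially
#' independent of the training presences.
#'
#' @param records Fossil record `data.frame` for one taxon.
#' @param grid A [grid_spec()].
#' @return Sorted integer vector of cell indices.
#' @export
validation_cells <- function(records, grid) {
  parts <- filter_reliable(records)
  train_cells <- presence_cells(parts$training, grid)
  val_cells <- presence_cells(parts$validation, grid)
  setdiff(val_cells, train_cells)
}

#' Extract records for one taxon or for all taxa
#'
#' Taxon-specific extraction feeds the climate-envelope model; the all-taxa
#' mode (any taxon, any age quality) feeds the preservation and discovery
#' models, where the mere presence of any fossil shows that fossils can be
#' preserved and found in a cell.
#'
#' @param records Fossil record `data.frame`.
#' @param taxon Taxon name, or `NULL` for all records.
#' @return Filtered `data.frame`.
#' @export
extract_records <- function(records, taxon = NULL) {
  if (is.null(taxon)) return(records)
  records[records$taxon == taxon, , drop = FALSE]
}
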