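#' Write a grid as long-format CSV
#'
#' Rasters are exchanged as plain-text tables with columns `lon,lat,value`,
#' one row per cell, missing cells written with an empty value field. This
#' keeps every artifact human-readable and diffable.
#'
#' @param grid A [lat_lon_grid()].
#' @param path Output file path.
#' @export
write_grid_csv <- function(grid, path) {
  df <- data.frame(
    lon = rep(grid$lon, each = length(grid$lat)),
    lat = rep(grid$lat, times = length(grid$lon)),
    value = as.vector(grid$values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a grid from long-format CSV
#'
#' @param path File written by [write_grid_csv()].
#' @return A [lat_lon_grid()].
#' @export
read_grid_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("lon", "lat", "value") %in% names(df)))
  lats <- sort(unique(df$lat))
  lons <- sort(unique(df$lon))
  g <- lat_lon_grid(c(lats[2] - lats[1], lons[2] - lons[1]))
  cells <- point_to_cell(g, df$lon, df$lat)
  g$values[cells] <- df$value
  g
}

#' Read an occurrence table from CSV
#'
#' Expected headers: `lon,lat,reef_type,age_min,age_max,source` (extra
#' columns are ignored; missing age columns are treated as modern records).
#'
#' @param path CSV file path.
#' @return An [occurrence_set()].
#' @export
read_occurrences_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("lon", "lat") %in% names(df)))
  occurrence_set(
    lon = df$lon, lat = df$lat,
    reef_type = if ("reef_type" %in% names(df)) df$reef_type else "true_reef",
    age_min = if ("age_min" %in% names(df)) df$age_min else NA_real_,
    age_max = if ("age_max" %in% names(df)) df$age_max else NA_real_,
    source = if ("source" %in% names(df)) df$source else "csv")
}

#' Write an occurrence table to CSV
#' @param occ An [occurrence_set()].
#' @param path Output file path.
#' @export
write_occurrences_csv <- function(occ, path) {
  utils::write.csv(
    occ[, c("lon", "lat", "reef_type", "age_min", "age_max", "source")],
    path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
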