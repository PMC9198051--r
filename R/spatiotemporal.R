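EARTH_RADIUS_KM <- 6371

#' Cell areas on the sphere
#'
#' Exact spherical cell areas `A(phi) = R^2 dlambda (sin(phi_top) -
#' sin(phi_bot))` with `R = 6371` km; independent of longitude, summing to
#' `4 pi R^2` over the globe.
#'
#' @param grid A [lat_lon_grid()] template.
#' @return A [lat_lon_grid()] of cell areas in km^2.
#' @export
cell_area_grid <- function(grid) {
  rlat <- res_lat(grid); rlon <- res_lon(grid)
  phi_bot <- (grid$lat - rlat / 2) * pi / 180
  phi_top <- (grid$lat + rlat / 2) * pi / 180
  a_lat <- EARTH_RADIUS_KM^2 * (rlon * pi / 180) * (sin(phi_top) - sin(phi_bot))
  lat_lon_grid(grid$resolution,
               matrix(a_lat, length(grid$lat), length(grid$lon)))
}

#' Area-weighted hemispheric centroid latitude of suitable habitat
#'
#' Mean latitude of suitable cell centers in one hemisphere, weighted by
#' spherical cell area so that low-latitude (larger) cells count more.
#'
#' @param binary A `binary_map`.
#' @param hemisphere `"N"` or `"S"` (cells assigned by center-latitude sign).
#' @param areas Optional [cell_area_grid()] (computed if missing).
#' @return Centroid latitude in degrees (signed); `NA` if the hemisphere has
#'   no suitable cell.
#' @export
weighted_centroid <- function(binary, hemisphere = c("N", "S"), areas = NULL) {
  hemisphere <- match.arg(hemisphere)
  if (is.null(areas)) areas <- cell_area_grid(binary)
  v <- binary$values
  v[is.na(v)] <- FALSE
  suit <- which(v, arr.ind = TRUE)
  if (nrow(suit) == 0) return(NA_real_)
  lat <- binary$lat[suit[, 1]]
  keep <- if (hemisphere == "N") lat > 0 else lat < 0
  if (!any(keep)) return(NA_real_)
  w <- areas$values[suit[keep, , drop = FALSE]]
  sum(w * lat[keep]) / sum(w)
}

# Most poleward suitable cell-center latitude in one hemisphere (positive
# magnitude in degrees), NA if empty.
poleward_extent <- function(values, lat_centers, hemisphere) {
  values[is.na(values)] <- FALSE
  suit <- which(values, arr.ind = TRUE)
  if (nrow(suit) == 0) return(NA_real_)
  lat <- lat_centers[suit[, 1]]
  lat <- if (hemisphere == "N") lat[lat > 0] else -lat[lat < 0]
  if (!length(lat)) return(NA_real_)
  max(lat)
}

#' Reef zone: most poleward latitude of suitable habitat
#'
#' The point estimate is the most poleward suitable cell-center latitude of
#' the median-map binary prediction; the uncertainty interval is the 2.5 and
#' 97.5 percentiles of the per-replicate poleward extremes, each replicate
#' thresholded at the same value.
#'
#' @param sm A `suitability_map` (with replicate stack).
#' @param threshold Threshold value applied to the median and each replicate.
#' @param hemisphere `"N"` or `"S"`.
#' @return List with `estimate`, `lo`, `hi` (degrees poleward, positive
#'   magnitudes; `NA` if the hemisphere is empty in the median map).
#' @export
reef_zone <- function(sm, threshold, hemisphere = c("N", "S")) {
  hemisphere <- match.arg(hemisphere)
  med_bin <- sm$median$values >= threshold
  est <- poleward_extent(med_bin, sm$median$lat, hemisphere)
  if (is.na(est)) return(list(estimate = NA_real_, lo = NA_real_, hi = NA_real_))
  per_rep <- vapply(seq_len(ncol(sm$reps)), function(r) {
    v <- matrix(FALSE, length(sm$median$lat), length(sm$median$lon))
    v[cbind(sm$cells$row, sm$cells$col)] <- sm$reps[, r] >= threshold
    pe <- poleward_extent(v, sm$median$lat, hemisphere)
    if (is.na(pe)) 0 else pe
  }, numeric(1))
  q <- stats::quantile(per_rep, c(0.025, 0.975), names = FALSE)
  list(estimate = est, lo = q[1], hi = q[2])
}

#' Suitable habitat area, global and in latitudinal bins
#'
#' Sums spherical cell areas over suitable cells, globally and within
#' latitude bins (default 20-degree bins spanning -90..90, aligned so the
#' tropics/subtropics split at 10 and 30 degrees). Bin areas sum to the
#' global area by construction.
#'
#' @param binary A `binary_map`.
#' @param areas Optional [cell_area_grid()].
#' @param bin_edges Ascending edges partitioning `[-90, 90]`.
#' @return List with `global` (km^2) and `binned`, a data frame of
#'   `lat_lo`, `lat_hi`, `area`.
#' @export
habitat_area <- function(binary, areas = NULL,
                         bin_edges = seq(-90, 90, by = 20)) {
  stopifnot(bin_edges[1] == -90, bin_edges[length(bin_edges)] == 90,
            all(diff(bin_edges) > 0))
  if (is.null(areas)) areas <- cell_area_grid(binary)
  v <- binary$values
  v[is.na(v)] <- FALSE
  suit <- which(v, arr.ind = TRUE)
  nb <- length(bin_edges) - 1
  if (nrow(suit) == 0) {
    binned <- data.frame(lat_lo = bin_edges[-length(bin_edges)],
                         lat_hi = bin_edges[-1], area = 0)
    return(list(global = 0, binned = binned))
  }
  lat <- binary$lat[suit[, 1]]
  a <- areas$values[suit]
  bin <- findInterval(lat, bin_edges, rightmost.closed = TRUE)
  area_bin <- vapply(seq_len(nb), function(b) sum(a[bin == b]), numeric(1))
  list(global = sum(a),
       binned = data.frame(lat_lo = bin_edges[-length(bin_edges)],
                           lat_hi = bin_edges[-1], area = area_bin))
}

#' OLS regression of fossil site counts on suitable habitat area
#'
#' @param area Per-stage global suitable area.
#' @param n_sites Per-stage fossil site counts.
#' @return List with `slope`, `intercept`, `r_squared`, `p_value` (two-sided
#'   p of the slope).
#' @export
area_vs_sites_regression <- function(area, n_sites) {
  ok <- is.finite(area) & is.finite(n_sites)
  if (sum(ok) < 3) stop("need at least 3 stages with defined values")
  if (stats::var(area[ok]) == 0) stop("zero variance in habitat area")
  fit <- stats::lm(n_sites[ok] ~ area[ok])
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2, 4]))
}

#' Stage-level spatiotemporal metric summary
#'
#' @param sm A `suitability_map` for the stage.
#' @param threshold Binary threshold value.
#' @param n_fossil_sites Fossil site count for the stage (default `NA`).
#' @return One-row data frame with centroids, reef zones with quantiles,
#'   global area and the 30-50 degree N bin area (10^6 km^2).
#' @export
stage_metrics <- function(sm, threshold, n_fossil_sites = NA_integer_) {
  bin <- binary_map(sm$median, threshold, stage_id = sm$stage_id)
  areas <- cell_area_grid(bin)
  rz_n <- reef_zone(sm, threshold, "N")
  rz_s <- reef_zone(sm, threshold, "S")
  ha <- habitat_area(bin, areas)
  b3050 <- ha$binned$area[ha$binned$lat_lo == 30]
  data.frame(stage = sm$stage_id,
             centroid_n = weighted_centroid(bin, "N", areas),
             centroid_s = weighted_centroid(bin, "S", areas),
             rz_n = rz_n$estimate, rz_n_lo = rz_n$lo, rz_n_hi = rz_n$hi,
             rz_s = rz_s$estimate, rz_s_lo = rz_s$lo, rz_s_hi = rz_s$hi,
             area_global_1e6km2 = ha$global / 1e6,
             area_30_50N_1e6km2 = if (length(b3050)) b3050 / 1e6 else NA_real_,
             n_fossil_sites = n_fossil_sites)
}
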