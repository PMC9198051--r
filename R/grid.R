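#' Regular global latitude-longitude grid
#'
#' The universal spatial carrier of the package: a regular global raster at a
#' resolution that divides 180 evenly, with cell centers at half-resolution
#' offsets (at 1 degree: latitudes -89.5..89.5, longitudes -179.5..179.5).
#' Longitude is periodic; no cell straddles the equator or the dateline.
#' Missing values are encoded as `NA` in the value matrix.
#'
#' @param resolution Cell size in degrees: a scalar, or a length-2 vector
#'   `c(lat, lon)` for anisotropic grids (e.g. a 2.5 x 3.75 degree climate
#'   model grid). The latitude spacing must divide 180 evenly and the
#'   longitude spacing 360.
#' @param values Optional numeric (or logical) matrix of dimension
#'   `(180/res_lat) x (360/res_lon)`, rows ordered south to north.
#' @return An object of class `lat_lon_grid` with fields `resolution`,
#'   `lat` (ascending cell-center latitudes), `lon` (cell-center longitudes)
#'   and `values`.
#' @export
lat_lon_grid <- function(resolution, values = NULL) {
  if (!is.numeric(resolution) || !length(resolution) %in% 1:2 ||
      any(resolution <= 0))
    stop("resolution must be a positive scalar or length-2 c(lat, lon)")
  rlat <- resolution[1]
  rlon <- resolution[length(resolution)]
  nlat <- 180 / rlat
  nlon <- 360 / rlon
  if (abs(nlat - round(nlat)) > 1e-9 || abs(nlon - round(nlon)) > 1e-9)
    stop("resolution (", rlat, ", ", rlon,
         ") does not divide (180, 360) evenly")
  nlat <- as.integer(round(nlat))
  nlon <- as.integer(round(nlon))
  if (is.null(values)) {
    values <- matrix(NA_real_, nlat, nlon)
  } else {
    values <- as.matrix(values)
    if (!all(dim(values) == c(nlat, nlon)))
      stop("values must be a ", nlat, " x ", nlon, " matrix at (",
           rlat, ", ", rlon, ") degree resolution, got ",
           paste(dim(values), collapse = " x "))
  }
  structure(
    list(resolution = if (rlat == rlon) rlat else c(rlat, rlon),
         lat = -90 + rlat * (seq_len(nlat) - 0.5),
         lon = -180 + rlon * (seq_len(nlon) - 0.5),
         values = values),
    class = "lat_lon_grid")
}

res_lat <- function(g) g$resolution[1]
res_lon <- function(g) g$resolution[length(g$resolution)]

#' @export
print.lat_lon_grid <- function(x, ...) {
  cat(sprintf("<lat_lon_grid %g x %g deg, %d x %d cells, %d defined>\n",
              res_lat(x), res_lon(x), length(x$lat), length(x$lon),
              sum(!is.na(x$values))))
  invisible(x)
}

is_grid <- function(x) inherits(x, "lat_lon_grid")

stop_if_not_conformable <- function(a, b, what = "grids") {
  if (length(a$lat) != length(b$lat) || length(a$lon) != length(b$lon))
    stop(what, " are not on the same grid (resolutions (",
         paste(a$resolution, collapse = ", "), ") and (",
         paste(b$resolution, collapse = ", "), "))")
  invisible(TRUE)
}

#' Assign points to grid cells
#'
#' Cells are half-open: cell `[i, j]` covers latitudes `[lat_lo, lat_lo + res)`
#' and longitudes `[lon_lo, lon_lo + res)`, so a point exactly on a boundary
#' belongs to the cell north/east of it. Longitude wraps; latitude 90 is
#' clamped to the northernmost row.
#'
#' @param grid A [lat_lon_grid()].
#' @param lon,lat Point coordinates in degrees.
#' @return A two-column integer matrix of (row, col) indices.
#' @export
point_to_cell <- function(grid, lon, lat) {
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  row <- floor((lat + 90) / res_lat(grid)) + 1
  row <- pmin(pmax(row, 1), nlat)
  col <- (floor((lon + 180) / res_lon(grid)) %% nlon) + 1
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Cell-center coordinates for cell indices
#' @param grid A [lat_lon_grid()].
#' @param cells Data frame or matrix with `row` and `col` columns.
#' @return Data frame with `lon` and `lat` cell-center coordinates.
#' @export
cell_centers <- function(grid, cells) {
  cells <- as.data.frame(cells)
  data.frame(lon = grid$lon[cells$col], lat = grid$lat[cells$row])
}

#' Extract grid values at cells
#' @param grid A [lat_lon_grid()].
#' @param cells Data frame or matrix with `row` and `col` columns.
#' @return Numeric vector of cell values.
#' @export
grid_values_at <- function(grid, cells) {
  cells <- as.data.frame(cells)
  grid$values[cbind(cells$row, cells$col)]
}

#' Bathymetry grid
#'
#' Substrate depth in metres below sea level, positive down; land is encoded
#' as depth <= 0. Depth must be finite everywhere.
#'
#' @param grid A [lat_lon_grid()] of finite depths.
#' @return Object of classes `bathymetry` and `lat_lon_grid`.
#' @export
bathymetry <- function(grid) {
  stopifnot(is_grid(grid))
  if (any(!is.finite(grid$values)))
    stop("bathymetry depth must be finite everywhere")
  class(grid) <- c("bathymetry", "lat_lon_grid")
  grid
}

#' Aggregate bathymetry to a coarser grid, preserving minimum depth
#'
#' Each coarse cell takes the minimum (shallowest) depth among its marine
#' (depth > 0) constituent fine cells, so oceanic islands and shallow banks
#' survive aggregation. A block with no marine fine cell is land, and takes
#' the block maximum (its least-elevated land value).
#'
#' @param bathy A [bathymetry()] at fine resolution.
#' @param target_resolution Coarse resolution; must be an integer multiple of
#'   the source resolution.
#' @return A [bathymetry()] at `target_resolution`.
#' @export
aggregate_min_depth <- function(bathy, target_resolution) {
  stopifnot(is_grid(bathy))
  f <- target_resolution / bathy$resolution
  if (abs(f - round(f)) > 1e-9 || f < 1)
    stop("target resolution ", target_resolution,
         " is not an integer multiple of source resolution ",
         bathy$resolution)
  f <- as.integer(round(f))
  M <- bathy$values
  marine <- ifelse(M > 0, M, Inf)
  nl <- nrow(M) / f; nn <- ncol(M) / f
  min_marine <- matrix(Inf, nl, nn)
  max_all <- matrix(-Inf, nl, nn)
  for (a in seq_len(f)) {
    ri <- seq(a, nrow(M), by = f)
    for (b in seq_len(f)) {
      ci <- seq(b, ncol(M), by = f)
      min_marine <- pmin(min_marine, marine[ri, ci, drop = FALSE])
      max_all <- pmax(max_all, M[ri, ci, drop = FALSE])
    }
  }
  out <- ifelse(is.finite(min_marine), min_marine, max_all)
  bathymetry(lat_lon_grid(target_resolution, out))
}

# Two-point interpolation weight matrix along one axis.
# Non-periodic axes clamp beyond the outermost source centers
# (nearest-row extrapolation); periodic axes wrap.
interp_weight_matrix <- function(src, tgt, periodic = FALSE) {
  n <- length(src)
  W <- matrix(0, length(tgt), n)
  if (periodic) {
    step <- src[2] - src[1]
    u <- (tgt - src[1]) / step
    i0 <- floor(u)
    fr <- u - i0
    j1 <- (as.integer(i0) %% n) + 1L
    j2 <- (as.integer(i0 + 1) %% n) + 1L
    for (k in seq_along(tgt)) {
      W[k, j1[k]] <- W[k, j1[k]] + (1 - fr[k])
      W[k, j2[k]] <- W[k, j2[k]] + fr[k]
    }
  } else {
    for (k in seq_along(tgt)) {
      y <- tgt[k]
      if (y <= src[1]) {
        W[k, 1] <- 1
      } else if (y >= src[n]) {
        W[k, n] <- 1
      } else {
        i <- findInterval(y, src)
        w <- (y - src[i]) / (src[i + 1] - src[i])
        W[k, i] <- 1 - w
        W[k, i + 1] <- w
      }
    }
  }
  W
}

#' Bilinearly regrid a layer onto a finer grid
#'
#' Each target cell-center value is the bilinear interpolation of the four
#' surrounding coarse cell centers, with longitudinal wraparound. Poleward of
#' the outermost coarse rows the nearest coarse row is used (no polar values
#' are invented). Missing coarse values propagate as `NA` to any target cell
#' whose interpolation stencil touches them.
#'
#' @param layer Coarse [lat_lon_grid()].
#' @param target A [lat_lon_grid()] template supplying the target axes.
#' @return A [lat_lon_grid()] on the target axes.
#' @export
bilinear_regrid <- function(layer, target) {
  stopifnot(is_grid(layer), is_grid(target))
  if (all(is.na(layer$values))) stop("cannot regrid an empty layer")
  Wlat <- interp_weight_matrix(layer$lat, target$lat, periodic = FALSE)
  Wlon <- interp_weight_matrix(layer$lon, target$lon, periodic = TRUE)
  na_src <- is.na(layer$values)
  V0 <- layer$values
  V0[na_src] <- 0
  out <- Wlat %*% V0 %*% t(Wlon)
  # a stencil touching NA yields NA rather than a partially-weighted value
  if (any(na_src)) {
    touched <- (Wlat > 0) %*% na_src %*% t(Wlon > 0)
    out[touched > 0] <- NA_real_
  }
  lat_lon_grid(target$resolution, out)
}

#' Build the shallow-water mask
#'
#' Marine cells shallower than 200 m, approximating the photic zone where
#' reef growth is possible. The depth bound is strict on both sides:
#' `0 < depth < depth_max`.
#'
#' @param bathy A [bathymetry()] on the working grid.
#' @param depth_max Depth cutoff in metres (default 200).
#' @return A logical-valued [lat_lon_grid()] with class `shallow_mask`.
#' @export
build_shallow_mask <- function(bathy, depth_max = 200) {
  stopifnot(is_grid(bathy))
  g <- lat_lon_grid(bathy$resolution, bathy$values > 0 & bathy$values < depth_max)
  class(g) <- c("shallow_mask", "lat_lon_grid")
  g
}

#' Count of mask cells
#' @param mask A `shallow_mask` grid.
#' @return Integer number of shallow cells.
#' @export
mask_size <- function(mask) sum(mask$values, na.rm = TRUE)

#' Cell indices of a mask
#' @param mask A `shallow_mask` grid.
#' @return Data frame of `row`, `col` for all mask cells.
#' @export
mask_cells <- function(mask) {
  idx <- which(mask$values)
  ai <- arrayInd(idx, dim(mask$values))
  data.frame(row = ai[, 1], col = ai[, 2])
}

# Sum and count of defined queen-move neighbours, longitude wrapped,
# no latitude wrap.
neighbour_sums <- function(V) {
  n <- nrow(V); m <- ncol(V)
  D <- !is.na(V)
  V0 <- ifelse(D, V, 0)
  S <- matrix(0, n, m)
  C <- matrix(0L, n, m)
  for (di in -1:1) {
    rows_dst <- seq_len(n)
    rows_src <- rows_dst + di
    ok <- rows_src >= 1 & rows_src <= n
    for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      cols_src <- ((seq_len(m) - 1 + dj) %% m) + 1
      S[rows_dst[ok], ] <- S[rows_dst[ok], ] + V0[rows_src[ok], cols_src]
      C[rows_dst[ok], ] <- C[rows_dst[ok], ] + D[rows_src[ok], cols_src]
    }
  }
  list(sum = S, count = C)
}

#' Fill missing layer values over the shallow mask by focal means
#'
#' Every mask cell missing a value receives the mean of its defined 3 x 3
#' neighbours (longitude-wrapped). By default passes repeat until every mask
#' cell is defined; already-defined values are never overwritten. If a pass
#' fills nothing while mask cells remain missing, an error lists them.
#'
#' @param layer A [lat_lon_grid()] sharing the mask's axes.
#' @param mask A `shallow_mask` grid.
#' @param single_pass If `TRUE`, perform one pass only (no closure guarantee).
#' @return The filled [lat_lon_grid()].
#' @export
focal_fill <- function(layer, mask, single_pass = FALSE) {
  stopifnot(is_grid(layer), is_grid(mask))
  stop_if_not_conformable(layer, mask, "layer and mask")
  V <- layer$values
  target <- mask$values & is.na(V)
  while (any(target)) {
    nb <- neighbour_sums(V)
    fillable <- target & nb$count > 0
    if (!any(fillable)) {
      if (single_pass) break
      bad <- which(target, arr.ind = TRUE)
      stop("focal_fill: ", nrow(bad), " mask cell(s) have no defined ",
           "neighbours after stabilization: ",
           paste(sprintf("(%d,%d)", bad[, 1], bad[, 2])[seq_len(min(10, nrow(bad)))],
                 collapse = " "))
    }
    V[fillable] <- nb$sum[fillable] / nb$count[fillable]
    target <- mask$values & is.na(V)
    if (single_pass) break
  }
  out <- lat_lon_grid(layer$resolution, V)
  class(out) <- class(layer)
  out
}

#' Occurrence table constructor
#'
#' Point records for modern or fossil reefs. Fossil records carry an age
#' interval in Ma; modern records leave the ages `NA`.
#'
#' @param lon,lat Coordinates in degrees (`-90 <= lat <= 90`).
#' @param reef_type Character reef-type token (e.g. `"true_reef"`,
#'   `"non_reef_coral_community"`).
#' @param is_true_reef Logical flag; defaults to `reef_type == "true_reef"`.
#' @param age_min,age_max Age interval bounds in Ma (`age_min <= age_max`).
#' @param source Data-source token.
#' @return A data frame of class `occurrence_set`.
#' @export
occurrence_set <- function(lon, lat, reef_type = "true_reef",
                           is_true_reef = NULL,
                           age_min = NA_real_, age_max = NA_real_,
                           source = "synthetic") {
  n <- length(lon)
  if (any(lat < -90 | lat > 90, na.rm = TRUE))
    stop("latitude out of range [-90, 90]")
  bad_age <- !is.na(age_min) & !is.na(age_max) & age_min > age_max
  if (any(bad_age)) stop("age_min > age_max for ", sum(bad_age), " record(s)")
  reef_type <- rep_len(as.character(reef_type), n)
  if (is.null(is_true_reef)) is_true_reef <- reef_type == "true_reef"
  out <- data.frame(lon = lon, lat = lat, reef_type = reef_type,
                    is_true_reef = rep_len(is_true_reef, n),
                    age_min = rep_len(age_min, n),
                    age_max = rep_len(age_max, n),
                    source = rep_len(as.character(source), n))
  class(out) <- c("occurrence_set", "data.frame")
  out
}

#' Filter occurrences and subsample them to grid cells
#'
#' Records that are not true reefs, fall on land, or lie at or beyond the
#' photic depth cutoff (i.e. outside the shallow mask) are dropped; survivors
#' are floor-assigned to half-open grid cells and duplicate cells collapse to
#' one presence with the provenance count retained.
#'
#' @param occ An [occurrence_set()].
#' @param mask A `shallow_mask` grid defining the working cells.
#' @return Data frame of class `presence_cells` with columns `row`, `col`,
#'   `count`, carrying the grid resolution as an attribute.
#' @export
subsample_to_cells <- function(occ, mask) {
  stopifnot(inherits(occ, "occurrence_set") || is.data.frame(occ))
  keep <- if ("is_true_reef" %in% names(occ)) occ$is_true_reef else rep(TRUE, nrow(occ))
  occ <- occ[keep & is.finite(occ$lon) & is.finite(occ$lat), , drop = FALSE]
  cells <- point_to_cell(mask, occ$lon, occ$lat)
  inside <- mask$values[cells]
  cells <- cells[inside, , drop = FALSE]
  if (nrow(cells) == 0) {
    warning("subsample_to_cells: no occurrences survive filtering")
    out <- data.frame(row = integer(0), col = integer(0), count = integer(0))
  } else {
    key <- paste(cells[, 1], cells[, 2])
    tab <- table(key)
    first <- !duplicated(key)
    out <- data.frame(row = cells[first, 1], col = cells[first, 2])
    out$count <- as.integer(tab[paste(out$row, out$col)])
    out <- out[order(out$row, out$col), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "resolution") <- mask$resolution
  class(out) <- c("presence_cells", "data.frame")
  out
}

#' Queen-move dilation of a logical grid
#'
#' Marks each cell TRUE if it or any of its 8 neighbours (longitude-wrapped,
#' no latitude wrap) is TRUE. Used for one-cell search buffers around fossil
#' localities.
#'
#' @param grid Logical-valued [lat_lon_grid()].
#' @return Logical-valued [lat_lon_grid()] of the dilation.
#' @export
queen_dilate <- function(grid) {
  V <- grid$values
  V[is.na(V)] <- FALSE
  nb <- neighbour_sums(ifelse(V, 1, 0))
  out <- lat_lon_grid(grid$resolution, V | nb$sum > 0)
  class(out) <- class(grid)
  out
}
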