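#' Configuration for a synthetic world
#'
#' Defines a seeded sequence of geological stages — bathymetry, climate, a
#' "truth" reef species, modern presences and fossil localities — with the
#' statistical structure the pipeline assumes: continental shelves whose
#' area responds to sea level, zonally graded sea surface temperature with
#' stage-level warm/cool offsets, a truth species limited by minimum SST
#' (~18 degrees C) and minimum insolation, and hemispherically biased fossil
#' sampling with age-interval uncertainty.
#'
#' Stage 1 is the calibration ("modern") stage; stages 2..n_stages are the
#' hindcast targets, ordered old to young in the stage table.
#'
#' @param seed Integer master seed; every random product derives a named
#'   substream from it, so adding stages never perturbs earlier stages.
#' @param n_stages Number of stages (>= 1).
#' @param continents List of continent specs, each a list with `lon`, `lat`
#'   (center, degrees), `half_lon`, `half_lat` (half-widths, degrees),
#'   `drift_lon`, `drift_lat` (degrees of center drift per stage index).
#' @param sea_level_offset Per-stage sea-level offset in metres (negative =
#'   sea-level fall, shallower water); recycled to `n_stages`.
#' @param stage_sst_offset Per-stage global SST offset g_t in degrees C
#'   (positive = warmer stage); recycled to `n_stages`.
#' @param t_eq Equatorial mean-maximum SST (degrees C).
#' @param delta_t Pole-to-equator SST range (degrees C, > 0).
#' @param seasonal_range Equatorial gap between sst_max and sst_min (degrees C).
#' @param seasonal_asym Extra poleward seasonal amplitude s (degrees C).
#' @param noise_sd Spatial SST anomaly s.d. sigma (degrees C): white noise
#'   smoothed over 5 cells and rescaled to sigma, giving warm-pool/gyre-like
#'   patches. The seasonal-minimum layer co-varies with the maximum layer;
#'   its independent component has s.d. `noise_sd / 4`.
#' @param ins_noise_sd Cloud-like anomaly s.d. (W m^-2) applied to both
#'   insolation layers (same smoothing; stationary across stages).
#' @param theta_sst Truth species minimum-SST limit (degrees C; default 18).
#' @param theta_sst_width Logistic width of the SST response (degrees C).
#' @param theta_ins Truth species minimum-insolation limit (W m^-2).
#' @param theta_ins_width Logistic width of the insolation response (W m^-2).
#' @param n_modern_presences Modern presence cells drawn from the truth.
#' @param fossils_per_stage Expected fossil localities per hindcast stage.
#' @param hemisphere_bias rho in [0, 1]: Southern-Hemisphere localities are
#'   retained with probability rho (1 = unbiased, 0 = Northern only).
#' @param age_jitter Uniform widening (Myr) applied to each side of a fossil
#'   record's stage interval.
#' @param cold_outlier_frac Fraction of fossil localities deliberately placed
#'   on shallow cells below the SST limit (false-negative emulation).
#' @param stage_duration Stage length in Myr for the synthetic stage table.
#' @param ramp_width Width (degrees) of the continental-shelf depth ramp
#'   from coastline to 200 m.
#' @param slope_width Width (degrees) of the continental slope from 200 m to
#'   the abyssal depth.
#' @param ocean_depth Abyssal depth (m).
#' @param land_height Maximum land elevation magnitude (m).
#' @param bathy_resolution Native bathymetry resolution (degrees).
#' @param climate_resolution Native climate resolution, `c(lat, lon)` degrees.
#' @return A list of class `world_config`.
#' @export
world_config <- function(seed = 1,
                         n_stages = 5,
                         continents = list(
                           list(lon = 30, lat = 18, half_lon = 55, half_lat = 32,
                                drift_lon = 0, drift_lat = 0),
                           list(lon = -120, lat = -12, half_lon = 35, half_lat = 28,
                                drift_lon = 3, drift_lat = 2),
                           list(lon = 150, lat = -40, half_lon = 30, half_lat = 20,
                                drift_lon = -2, drift_lat = 3)),
                         sea_level_offset = 0,
                         stage_sst_offset = c(0, 4, 2, 0, -4),
                         t_eq = 29, delta_t = 28,
                         seasonal_range = 4, seasonal_asym = 6,
                         noise_sd = 2,
                         ins_noise_sd = 15,
                         theta_sst = 18, theta_sst_width = 0.5,
                         theta_ins = 120, theta_ins_width = 15,
                         n_modern_presences = 500,
                         fossils_per_stage = 40,
                         hemisphere_bias = 0.5,
                         age_jitter = 2,
                         cold_outlier_frac = 0,
                         stage_duration = 10,
                         ramp_width = 6, slope_width = 2,
                         ocean_depth = 4000, land_height = 500,
                         bathy_resolution = 0.5,
                         climate_resolution = c(2.5, 3.75)) {
  stopifnot(n_stages >= 1, delta_t > 0,
            hemisphere_bias >= 0, hemisphere_bias <= 1,
            cold_outlier_frac >= 0, cold_outlier_frac < 1)
  cfg <- list(seed = as.integer(seed), n_stages = as.integer(n_stages),
              continents = continents,
              sea_level_offset = rep_len(sea_level_offset, n_stages),
              stage_sst_offset = rep_len(stage_sst_offset, n_stages),
              t_eq = t_eq, delta_t = delta_t,
              seasonal_range = seasonal_range, seasonal_asym = seasonal_asym,
              noise_sd = noise_sd, ins_noise_sd = ins_noise_sd,
              theta_sst = theta_sst, theta_sst_width = theta_sst_width,
              theta_ins = theta_ins, theta_ins_width = theta_ins_width,
              n_modern_presences = as.integer(n_modern_presences),
              fossils_per_stage = fossils_per_stage,
              hemisphere_bias = hemisphere_bias,
              age_jitter = age_jitter,
              cold_outlier_frac = cold_outlier_frac,
              stage_duration = stage_duration,
              ramp_width = ramp_width, slope_width = slope_width,
              ocean_depth = ocean_depth, land_height = land_height,
              bathy_resolution = bathy_resolution,
              climate_resolution = climate_resolution)
  class(cfg) <- "world_config"
  cfg
}

#' Synthetic stage table
#'
#' Stage i spans `[i * d, (i - 1) * d]` Ma with duration `d`, so stage 1 is
#' the youngest (the calibration stage) and stage `n_stages` the oldest.
#'
#' @param config A [world_config()].
#' @return Data frame with `stage_id`, `t_old`, `t_young` (Ma), young to old.
#' @export
stage_table <- function(config) {
  i <- seq_len(config$n_stages)
  data.frame(stage_id = paste0("stage", i),
             t_old = i * config$stage_duration,
             t_young = (i - 1) * config$stage_duration)
}

# Wrapped longitudinal offset in (-180, 180].
lon_diff <- function(lon, center) ((lon - center + 180) %% 360) - 180

#' Generate stage bathymetry
#'
#' Continents are smooth rectangular plateaus (depth <= 0) surrounded by a
#' linear shelf ramp reaching 200 m over `ramp_width` degrees, then a steep
#' slope to the abyssal depth. The whole depth field is shifted by the
#' stage's sea-level offset (a fall turns outer-shelf into shelf and inner
#' shelf into land). Deterministic given `(seed, stage_index)`.
#'
#' @param config A [world_config()].
#' @param stage_index Stage number in `1..n_stages`.
#' @return A [bathymetry()] at the native bathymetry resolution.
#' @export
make_bathymetry <- function(config, stage_index) {
  stopifnot(stage_index >= 1, stage_index <= config$n_stages)
  g <- lat_lon_grid(config$bathy_resolution)
  lon <- matrix(g$lon, length(g$lat), length(g$lon), byrow = TRUE)
  lat <- matrix(g$lat, length(g$lat), length(g$lon))
  # signed distance (degrees) outside the nearest continent edge;
  # negative values are inside (scaled by relative depth into the plateau)
  edge <- matrix(Inf, nrow(lon), ncol(lon))
  for (ct in config$continents) {
    clon <- ct$lon + ct$drift_lon * (stage_index - 1)
    clat <- ct$lat + ct$drift_lat * (stage_index - 1)
    dlon <- abs(lon_diff(lon, clon)) - ct$half_lon
    dlat <- abs(lat - clat) - ct$half_lat
    d <- pmax(dlon, dlat)   # Chebyshev-style rectangle distance
    edge <- pmin(edge, d)
  }
  depth <- ifelse(
    edge <= 0,
    # plateau: elevation grows with distance inside the coastline
    pmax(-config$land_height, edge / 10 * config$land_height),
    ifelse(edge <= config$ramp_width,
           200 * edge / config$ramp_width,
           pmin(config$ocean_depth,
                200 + (config$ocean_depth - 200) *
                  (edge - config$ramp_width) / config$slope_width)))
  depth <- depth + config$sea_level_offset[stage_index]
  # keep land strictly land and the abyss finite after the offset
  bathymetry(lat_lon_grid(config$bathy_resolution, depth))
}

# 5-cell boxcar smoothing (longitude wrapped, latitude clamped) of a
# white-noise field; gives the spatially correlated climate noise.
smooth5 <- function(M) {
  n <- nrow(M); m <- ncol(M)
  S <- matrix(0, n, m); C <- matrix(0, n, m)
  for (di in -2:2) {
    rows_src <- seq_len(n) + di
    ok <- rows_src >= 1 & rows_src <= n
    for (dj in -2:2) {
      cols_src <- ((seq_len(m) - 1 + dj) %% m) + 1
      S[ok, ] <- S[ok, ] + M[rows_src[ok], cols_src]
      C[ok, ] <- C[ok, ] + 1
    }
  }
  S / C
}

#' Generate stage climate at the native climate-model resolution
#'
#' Mean-maximum SST follows a zonal profile
#' `T_eq + g_t - delta_t * sin^2(lat)` plus smoothed Gaussian noise;
#' mean-minimum SST sits `seasonal_range + seasonal_asym * |sin(lat)|`
#' below it. Insolation layers are smooth decreasing functions of |lat|.
#' Layer-pair ordering (`max >= min`) is enforced by construction and a
#' final clip. If a bathymetry is supplied, cells whose center falls on
#' land are set missing in all four layers, as in an ocean model.
#'
#' @param config A [world_config()].
#' @param stage_index Stage number in `1..n_stages`.
#' @param bathy Optional [bathymetry()] used to mask land cells.
#' @return A [climate_stack()] at the native climate resolution.
#' @export
make_climate <- function(config, stage_index, bathy = NULL) {
  stopifnot(stage_index >= 1, stage_index <= config$n_stages)
  g <- lat_lon_grid(config$climate_resolution)
  nlat <- length(g$lat); nlon <- length(g$lon)
  sphi <- sin(g$lat * pi / 180)
  gt <- config$stage_sst_offset[stage_index]
  prof_max <- config$t_eq + gt - config$delta_t * sphi^2
  prof_gap <- config$seasonal_range + config$seasonal_asym * abs(sphi)
  # anomaly fields are stationary across stages (geography-locked warm
  # pools, gyres and climatological cloudiness); stage differences enter
  # through g_t and the drifting continents. White noise is smoothed over
  # 5 cells and rescaled so sigma keeps its meaning as the cell-level
  # anomaly scale.
  noise <- function(tag, sd) {
    if (sd == 0) return(matrix(0, nlat, nlon))
    with_seed(derive_seed(config$seed, "climate", tag), {
      sm <- smooth5(matrix(stats::rnorm(nlat * nlon), nlat, nlon))
      sm / stats::sd(sm) * sd
    })
  }
  sst_max <- matrix(prof_max, nlat, nlon) + noise("sst_max", config$noise_sd)
  # the seasonal minimum shares the maximum layer's anomalies (a warm pool
  # is warm year-round); only a small independent component is added
  sst_min <- sst_max - matrix(prof_gap, nlat, nlon) +
    noise("sst_min", config$noise_sd / 4)
  sst_min <- pmin(sst_min, sst_max)
  # mean-max/min insolation are nearly flat through the tropics (the
  # seasonal sun tracks latitude) and fall off steeply poleward: sin^4
  # shape, plus cloud-like stationary anomalies
  ins_max <- matrix(420 - 180 * sphi^4, nlat, nlon) +
    noise("ins_max", config$ins_noise_sd)
  ins_min <- matrix(pmax(0, 280 - 260 * sphi^4), nlat, nlon) +
    noise("ins_min", config$ins_noise_sd)
  ins_min <- pmin(ins_min, ins_max)
  if (!is.null(bathy)) {
    centers <- expand.grid(row = seq_len(nlat), col = seq_len(nlon))
    pts <- cell_centers(g, centers)
    dep <- grid_values_at(bathy, point_to_cell(bathy, pts$lon, pts$lat))
    land <- matrix(dep <= 0, nlat, nlon)
    sst_max[land] <- NA; sst_min[land] <- NA
    ins_max[land] <- NA; ins_min[land] <- NA
  }
  mk <- function(v) lat_lon_grid(config$climate_resolution, v)
  climate_stack(paste0("stage", stage_index),
                mk(sst_max), mk(sst_min), mk(ins_max), mk(ins_min))
}

#' Truth suitability and modern presence sample
#'
#' The truth species responds to only two of the four predictors: suitability
#' is the product of logistic responses in minimum SST (midpoint
#' `theta_sst`, width `theta_sst_width`) and minimum insolation (midpoint
#' `theta_ins`, width `theta_ins_width`), on shallow-mask cells and zero
#' elsewhere. Presence cells are drawn without replacement with probability
#' proportional to truth.
#'
#' @param config A [world_config()].
#' @param stage_index Stage number.
#' @param mask `shallow_mask` on the working grid.
#' @param climate [climate_stack()] regridded to the mask grid.
#' @param n_presences Number of presence cells to draw (default: config's
#'   `n_modern_presences`; 0 gives an empty set).
#' @return List with `truth` (a [lat_lon_grid()] in `[0, 1]`) and
#'   `presences` (a `presence_cells` data frame).
#' @export
make_truth_and_presences <- function(config, stage_index, mask, climate,
                                     n_presences = config$n_modern_presences) {
  stop_if_not_conformable(mask, climate$sst_min, "mask and climate")
  truth_v <- matrix(0, length(mask$lat), length(mask$lon))
  cells <- mask_cells(mask)
  if (nrow(cells)) {
    sstmin <- grid_values_at(climate$sst_min, cells)
    insmin <- grid_values_at(climate$ins_min, cells)
    t_cell <- stats::plogis((sstmin - config$theta_sst) / config$theta_sst_width) *
      stats::plogis((insmin - config$theta_ins) / config$theta_ins_width)
    truth_v[cbind(cells$row, cells$col)] <- t_cell
  }
  truth <- lat_lon_grid(res_lat(mask), truth_v)
  if (n_presences == 0) {
    pres <- data.frame(row = integer(0), col = integer(0), count = integer(0))
  } else {
    pos <- which(truth_v[cbind(cells$row, cells$col)] > 0)
    if (length(pos) < n_presences)
      stop("only ", length(pos), " positive-truth cells available for ",
           n_presences, " requested presences")
    pick <- with_seed(derive_seed(config$seed, "presences", stage_index),
                      sample(pos, n_presences, replace = FALSE,
                             prob = truth_v[cbind(cells$row, cells$col)][pos]))
    pres <- data.frame(row = cells$row[pick], col = cells$col[pick],
                       count = 1L)
    pres <- pres[order(pres$row, pres$col), ]
    rownames(pres) <- NULL
  }
  attr(pres, "resolution") <- mask$resolution
  class(pres) <- c("presence_cells", "data.frame")
  list(truth = truth, presences = pres)
}

#' Sample fossil localities from past truth suitability
#'
#' Per hindcast stage, localities are drawn (with replacement across draws,
#' then deduplicated at record level is NOT applied — localities are point
#' records) proportional to truth suitability; Southern-Hemisphere draws are
#' thinned by the hemispheric bias `rho`; each record's stage interval is
#' widened by seeded uniform jitter on each side so the >50% age-binning
#' rule is exercised; an optional fraction of cold outliers is placed on
#' shallow cells below the SST limit.
#'
#' @param config A [world_config()].
#' @param stages List of per-stage lists, each with `stage_index`, `truth`
#'   (a [lat_lon_grid()]), `mask` (`shallow_mask`) and `climate` (working
#'   grid [climate_stack()]), for the stages fossils should be drawn from.
#' @return An [occurrence_set()] of fossil localities.
#' @export
make_fossils <- function(config, stages) {
  st <- stage_table(config)
  recs <- list()
  for (s in stages) {
    i <- s$stage_index
    seed_i <- derive_seed(config$seed, "fossils", i)
    draw_stage <- function() {
      cells <- mask_cells(s$mask)
      tv <- grid_values_at(s$truth, cells)
      pos <- which(tv > 0)
      n_draw <- stats::rpois(1, config$fossils_per_stage)
      if (n_draw == 0 || length(pos) == 0) return(NULL)
      pick <- sample(pos, n_draw, replace = TRUE, prob = tv[pos])
      lat_pick <- s$mask$lat[cells$row[pick]]
      keep <- lat_pick >= 0 | stats::runif(n_draw) < config$hemisphere_bias
      pick <- pick[keep]
      n_cold <- round(config$cold_outlier_frac * length(pick) /
                        max(1e-9, 1 - config$cold_outlier_frac))
      cold_rows <- integer(0); cold_cols <- integer(0)
      if (n_cold > 0) {
        sstmin <- grid_values_at(s$climate$sst_min, cells)
        cold <- which(sstmin < config$theta_sst)
        if (length(cold)) {
          ci <- sample(cold, min(n_cold, length(cold)), replace = TRUE)
          cold_rows <- cells$row[ci]; cold_cols <- cells$col[ci]
        }
      }
      rows <- c(cells$row[pick], cold_rows)
      cols <- c(cells$col[pick], cold_cols)
      if (!length(rows)) return(NULL)
      ctr <- cell_centers(s$mask, data.frame(row = rows, col = cols))
      n <- nrow(ctr)
      j1 <- stats::runif(n, 0, config$age_jitter)
      j2 <- stats::runif(n, 0, config$age_jitter)
      data.frame(lon = ctr$lon, lat = ctr$lat,
                 age_min = pmax(0, st$t_young[i] - j1),
                 age_max = st$t_old[i] + j2,
                 stage_true = st$stage_id[i])
    }
    rec <- with_seed(seed_i, draw_stage())
    if (!is.null(rec)) recs[[length(recs) + 1]] <- rec
  }
  if (!length(recs))
    return(occurrence_set(numeric(0), numeric(0)))
  all <- do.call(rbind, recs)
  out <- occurrence_set(all$lon, all$lat, reef_type = "true_reef",
                        age_min = all$age_min, age_max = all$age_max,
                        source = "synthetic_fossil")
  out$stage_true <- all$stage_true
  out
}

#' Generate a complete synthetic stage on the working grid
#'
#' Convenience wrapper: native bathymetry, minimum-depth aggregation to the
#' working resolution, shallow-water mask, native climate masked to ocean,
#' bilinear regrid plus focal gap fill, and the truth suitability layer.
#'
#' @param config A [world_config()].
#' @param stage_index Stage number.
#' @param working_resolution Working grid resolution in degrees (default 1).
#' @return List with `stage_index`, `stage_id`, `bathy_native`, `bathy`,
#'   `mask`, `climate` (working grid), `truth`.
#' @export
make_stage <- function(config, stage_index, working_resolution = 1) {
  bn <- make_bathymetry(config, stage_index)
  bw <- aggregate_min_depth(bn, working_resolution)
  mask <- build_shallow_mask(bw)
  clim <- regrid_climate(make_climate(config, stage_index, bathy = bn), mask)
  tp <- make_truth_and_presences(config, stage_index, mask, clim,
                                 n_presences = 0)
  list(stage_index = stage_index, stage_id = paste0("stage", stage_index),
       bathy_native = bn, bathy = bw, mask = mask, climate = clim,
       truth = tp$truth)
}
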