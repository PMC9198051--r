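#' Bin fossil occurrences into stages by the majority-overlap rule
#'
#' A record with age interval `[age_min, age_max]` is assigned to the stage
#' covering strictly more than 50% of that interval; point-aged records
#' (`age_min == age_max`) go to the containing stage. Records meeting no
#' stage's majority rule, or with malformed intervals, are excluded with a
#' reason. Survivors are subsampled to working-grid cells per stage.
#'
#' @param occ An [occurrence_set()] of fossil records (palaeocoordinates).
#' @param stages Data frame with `stage_id`, `t_old`, `t_young` (Ma),
#'   non-overlapping.
#' @param mask_by_stage Named list of `shallow_mask` grids keyed by stage id
#'   (used for cell assignment; fossil cells are kept whether or not they
#'   fall inside the mask, since off-mask fossils are what validation
#'   measures).
#' @return Named list (by stage id) with elements `cells` (data frame
#'   `row`, `col`, `count`), `n_records`; plus attribute `excluded`, a data
#'   frame of dropped records with reasons.
#' @export
bin_fossils <- function(occ, stages, mask_by_stage) {
  stopifnot(all(stages$t_old > stages$t_young))
  excluded <- data.frame(index = integer(0), reason = character(0))
  assign_to <- rep(NA_character_, nrow(occ))
  for (k in seq_len(nrow(occ))) {
    a_min <- occ$age_min[k]; a_max <- occ$age_max[k]
    if (is.na(a_min) || is.na(a_max) || a_min > a_max) {
      excluded <- rbind(excluded,
                        data.frame(index = k, reason = "malformed interval"))
      next
    }
    if (a_max == a_min) {
      hit <- which(stages$t_young <= a_min & a_min <= stages$t_old)
      if (length(hit)) assign_to[k] <- stages$stage_id[hit[1]]
      else excluded <- rbind(excluded,
                             data.frame(index = k, reason = "outside stage table"))
      next
    }
    ov <- pmax(0, pmin(a_max, stages$t_old) - pmax(a_min, stages$t_young))
    frac <- ov / (a_max - a_min)
    best <- which.max(frac)
    if (frac[best] > 0.5) assign_to[k] <- stages$stage_id[best]
    else excluded <- rbind(excluded,
                           data.frame(index = k, reason = "no stage covers >50%"))
  }
  out <- list()
  for (sid in stages$stage_id) {
    idx <- which(assign_to == sid)
    if (!length(idx)) {
      out[[sid]] <- list(cells = data.frame(row = integer(0), col = integer(0),
                                            count = integer(0)),
                         n_records = 0L)
      next
    }
    mask <- mask_by_stage[[sid]]
    cells <- point_to_cell(mask, occ$lon[idx], occ$lat[idx])
    key <- paste(cells[, 1], cells[, 2])
    tab <- table(key)
    first <- !duplicated(key)
    cdf <- data.frame(row = cells[first, 1], col = cells[first, 2])
    cdf$count <- as.integer(tab[paste(cdf$row, cdf$col)])
    cdf <- cdf[order(cdf$row, cdf$col), ]
    rownames(cdf) <- NULL
    out[[sid]] <- list(cells = cdf, n_records = length(idx))
  }
  attr(out, "excluded") <- excluded
  out
}

#' Predictive success of a binary hindcast at fossil cells
#'
#' The percentage of fossil cells that are predicted suitable; with
#' `buffer = 1`, a fossil counts if its own cell or any of its 8 queen-move
#' neighbours (longitude-wrapped, no latitude wrap) is suitable, absorbing
#' one cell of palaeocoordinate uncertainty.
#'
#' @param fossil_cells Data frame of `row`, `col` on the binary map's grid.
#' @param binary A `binary_map`.
#' @param buffer 0 (exact cell) or 1 (one-cell queen buffer).
#' @return Percentage in `[0, 100]`; `NA` with a warning if no fossil cells.
#' @export
predictive_success <- function(fossil_cells, binary, buffer = 0) {
  if (nrow(fossil_cells) == 0) {
    warning("predictive_success: no fossil cells; undefined")
    return(NA_real_)
  }
  g <- if (buffer >= 1) queen_dilate(binary) else binary
  v <- grid_values_at(g, fossil_cells)
  v[is.na(v)] <- FALSE
  100 * mean(v)
}

#' Random-point null model for predictive success
#'
#' Draws `n_sets` sets of `n_points` cells from the shallow mask (uniform
#' over cells by default, or area-weighted by the cosine of latitude) and
#' scores each set against the binary map exactly as fossils are scored
#' (no buffer).
#'
#' @param mask `shallow_mask` defining the sampling frame.
#' @param binary `binary_map` for the same stage.
#' @param n_points Points per set (the stage's fossil count).
#' @param n_sets Number of random sets (default 1000).
#' @param seed Integer seed.
#' @param area_weighted If `TRUE`, cells are drawn with probability
#'   proportional to their area (cos latitude).
#' @return List with `pct` (length `n_sets`), `mean`, `lo`, `hi` (2.5 and
#'   97.5 percentiles).
#' @export
random_null <- function(mask, binary, n_points, n_sets = 1000, seed = 1,
                        area_weighted = FALSE) {
  stopifnot(n_points >= 1, n_sets >= 1)
  cells <- mask_cells(mask)
  if (nrow(cells) == 0) stop("mask is empty")
  suit <- grid_values_at(binary, cells)
  suit[is.na(suit)] <- FALSE
  prob <- if (area_weighted) cos(mask$lat[cells$row] * pi / 180) else NULL
  pct <- with_seed(derive_seed(seed, "null"), {
    vapply(seq_len(n_sets), function(s) {
      idx <- sample.int(nrow(cells), n_points, replace = TRUE, prob = prob)
      100 * mean(suit[idx])
    }, numeric(1))
  })
  list(pct = pct, mean = mean(pct),
       lo = unname(stats::quantile(pct, 0.025)),
       hi = unname(stats::quantile(pct, 0.975)))
}

#' Validate one stage's hindcast against its fossil record
#'
#' Computes buffer-0 and buffer-1 predictive success, the random-point null
#' distribution, a one-sample one-sided signed-rank test of the null
#' percentages against the observed buffer-0 success (alternative: null
#' less), and a two-sample one-sided rank-sum test of continuous median
#' suitability at fossil cells against random mask cells (alternative:
#' fossil greater).
#'
#' @param fossil_cells Data frame of fossil `row`, `col` for the stage.
#' @param binary `binary_map` of the stage hindcast.
#' @param median_suitability Continuous median suitability [lat_lon_grid()].
#' @param mask `shallow_mask` of the stage.
#' @param n_sets Random sets for the null model (default 1000).
#' @param n_random_values Random cells for the two-sample test (default 1000).
#' @param seed Integer seed.
#' @param area_weighted Passed to [random_null()].
#' @return One-row data frame: `stage`, `n_fossils`, `pct`, `pct_buffer`,
#'   `null_mean`, `null_lo`, `null_hi`, `p1`, `p2`.
#' @export
validate_stage <- function(fossil_cells, binary, median_suitability, mask,
                           n_sets = 1000, n_random_values = 1000, seed = 1,
                           area_weighted = FALSE) {
  sid <- attr(binary, "stage_id")
  if (is.null(sid)) sid <- NA_character_
  n_f <- nrow(fossil_cells)
  if (n_f == 0) {
    return(data.frame(stage = sid, n_fossils = 0L, pct = NA_real_,
                      pct_buffer = NA_real_, null_mean = NA_real_,
                      null_lo = NA_real_, null_hi = NA_real_,
                      p1 = NA_real_, p2 = NA_real_))
  }
  pct <- predictive_success(fossil_cells, binary, buffer = 0)
  pct_b <- predictive_success(fossil_cells, binary, buffer = 1)
  null <- random_null(mask, binary, n_points = n_f, n_sets = n_sets,
                      seed = seed, area_weighted = area_weighted)
  p1 <- tryCatch(
    wilcoxon_one_sample(null$pct, pct, alternative = "less")$p_value,
    error = function(e) NA_real_)
  fs <- grid_values_at(median_suitability, fossil_cells)
  fs[is.na(fs)] <- 0
  cells <- mask_cells(mask)
  rnd <- with_seed(derive_seed(seed, "twosample"),
                   sample.int(nrow(cells), n_random_values, replace = TRUE))
  rs <- grid_values_at(median_suitability, cells[rnd, , drop = FALSE])
  p2 <- wilcoxon_two_sample(fs, rs, alternative = "greater")$p_value
  data.frame(stage = sid, n_fossils = n_f, pct = pct, pct_buffer = pct_b,
             null_mean = null$mean, null_lo = null$lo, null_hi = null$hi,
             p1 = p1, p2 = p2)
}
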