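#' Area under the ROC curve (rank form)
#'
#' The probability that a randomly chosen presence outscores a randomly
#' chosen background cell, with ties counted one half: the Mann-Whitney
#' statistic divided by the number of presence-background pairs. Identical
#' for any monotone transform of the scores.
#'
#' @param presence_scores,background_scores Non-empty numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(presence_scores, background_scores) {
  m <- length(presence_scores); n <- length(background_scores)
  if (m == 0 || n == 0) stop("both score sets must be non-empty")
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Continuous Boyce index
#'
#' Overlapping windows slide across the score range; each window's
#' predicted-to-expected ratio P/E is the fraction of presences falling
#' inside divided by the fraction of background cells inside. The index is
#' the Spearman rank correlation between P/E and the window midpoint over
#' windows containing background, so +1 means presence density rises
#' monotonically with predicted suitability and values near 0 mean the
#' prediction gradient carries no information about presences.
#'
#' @param presence_scores,background_scores Scores in `[0, 1]`.
#' @param n_windows Number of overlapping windows (default 101; >= 3).
#' @param window_width Window width; default one tenth of the observed
#'   score range.
#' @return Boyce index in `[-1, 1]`.
#' @export
boyce_index <- function(presence_scores, background_scores,
                        n_windows = 101, window_width = NULL) {
  stopifnot(n_windows >= 3)
  lo <- min(background_scores, presence_scores)
  hi <- max(background_scores, presence_scores)
  if (hi <= lo) stop("degenerate score range")
  if (is.null(window_width)) window_width <- (hi - lo) / 10
  starts <- seq(lo, hi - window_width, length.out = n_windows)
  mids <- starts + window_width / 2
  pe <- vapply(starts, function(s) {
    inb <- mean(background_scores >= s & background_scores <= s + window_width)
    if (inb == 0) return(NA_real_)
    inp <- mean(presence_scores >= s & presence_scores <= s + window_width)
    inp / inb
  }, numeric(1))
  ok <- !is.na(pe)
  if (!any(ok)) stop("no window contains background scores")
  stats::cor(mids[ok], pe[ok], method = "spearman")
}

#' Binary suitability map
#'
#' @param suitability A [lat_lon_grid()] of continuous suitability (defined
#'   on mask cells).
#' @param threshold Threshold value in `[0, 1]`.
#' @param kind Threshold kind token (`"ltp"` or `"maxsss"`).
#' @param stage_id Stage identifier.
#' @return Logical-valued [lat_lon_grid()] of class `binary_map` (TRUE where
#'   suitability >= threshold), with `threshold` and `kind` attributes.
#' @export
binary_map <- function(suitability, threshold, kind = "ltp", stage_id = NULL) {
  g <- lat_lon_grid(suitability$resolution, suitability$values >= threshold)
  g$values[is.na(suitability$values)] <- NA
  attr(g, "threshold") <- threshold
  attr(g, "kind") <- kind
  attr(g, "stage_id") <- stage_id
  class(g) <- c("binary_map", "lat_lon_grid")
  g
}

#' Least-training-presence threshold
#'
#' The minimum suitability over training presence cells: the most inclusive
#' threshold that still classifies every training presence as suitable.
#'
#' @param suitability A [lat_lon_grid()] of suitability (typically the
#'   replicate median).
#' @param presences `presence_cells` of training presences.
#' @return List with `threshold` and the `binary_map`.
#' @export
threshold_ltp <- function(suitability, presences) {
  s <- grid_values_at(suitability, presences)
  if (any(is.na(s))) stop("a training presence has no defined suitability")
  thr <- min(s)
  list(threshold = thr,
       binary = binary_map(suitability, thr, kind = "ltp"))
}

#' MaxSSS threshold
#'
#' Scans all distinct observed scores as candidate thresholds and picks the
#' one maximising sensitivity (over presences, score >= t) plus specificity
#' (over background, score < t). Ties are broken toward the lowest such
#' threshold, giving the most inclusive map.
#'
#' @param suitability A [lat_lon_grid()] of suitability.
#' @param presences `presence_cells` with defined suitability.
#' @param background Data frame of background cells (`row`, `col`).
#' @return List with `threshold`, `sss` (max sensitivity + specificity) and
#'   the `binary_map`.
#' @export
threshold_maxsss <- function(suitability, presences, background) {
  ps <- grid_values_at(suitability, presences)
  bs <- grid_values_at(suitability, background)
  if (!length(ps) || !length(bs)) stop("empty presence or background scores")
  cand <- sort(unique(c(ps, bs)))
  sss <- vapply(cand, function(t) mean(ps >= t) + mean(bs < t), numeric(1))
  best <- cand[which.max(sss)]   # which.max returns the first (lowest) maximiser
  list(threshold = best, sss = max(sss),
       binary = binary_map(suitability, best, kind = "maxsss"))
}

# MESS similarity of values v to a reference vector (Elith-style):
# inside the range, twice the smaller tail percentage; outside, the negative
# linear extrapolation in units of percent of the reference range.
mess_similarity <- function(v, ref) {
  rmin <- min(ref); rmax <- max(ref); rng <- rmax - rmin
  if (rng <= 0) stop("constant reference variable")
  sr <- sort(ref)
  f <- 100 * findInterval(v, sr, left.open = TRUE) / length(ref)  # % strictly below
  ifelse(v < rmin, 100 * (v - rmin) / rng,
         ifelse(v > rmax, 100 * (rmax - v) / rng,
                ifelse(f < 50, 2 * f, 2 * (100 - f))))
}

#' Multivariate environmental similarity surface
#'
#' Per mask cell and climate variable, similarity to the calibration
#' reference distribution; the cell value is the minimum across variables
#' and the most dissimilar variable is recorded. Negative values flag novel
#' conditions outside the calibration range (model extrapolation).
#'
#' @param reference Named list of reference value vectors, one per climate
#'   layer (typically background values from the calibration stage).
#' @param climate [climate_stack()] of the projection stage on the mask grid.
#' @param mask `shallow_mask` of the projection stage.
#' @return List of class `mess_map`: `similarity` (a [lat_lon_grid()]) and
#'   `worst_variable` (a [lat_lon_grid()] of variable indices into
#'   `names(reference)`), plus `variables`.
#' @export
mess <- function(reference, climate, mask) {
  vars <- climate_layer_names()
  stopifnot(all(vars %in% names(reference)))
  for (nm in vars) {
    if (!length(reference[[nm]])) stop("empty reference for ", nm)
    if (max(reference[[nm]]) - min(reference[[nm]]) <= 0)
      stop("constant reference variable: ", nm)
  }
  cells <- mask_cells(mask)
  S <- vapply(vars, function(nm) {
    mess_similarity(grid_values_at(climate[[nm]], cells), reference[[nm]])
  }, numeric(nrow(cells)))
  if (is.null(dim(S))) S <- matrix(S, nrow = nrow(cells))
  smin <- apply(S, 1, min)
  worst <- apply(S, 1, which.min)
  sim <- lat_lon_grid(mask$resolution)
  sim$values[cbind(cells$row, cells$col)] <- smin
  wv <- lat_lon_grid(mask$resolution)
  wv$values[cbind(cells$row, cells$col)] <- worst
  structure(list(similarity = sim, worst_variable = wv, variables = vars),
            class = "mess_map")
}

#' Per-replicate evaluation of a calibrated suitability map
#'
#' Computes AUC and the continuous Boyce index for each bootstrap replicate,
#' scoring the replicate's held-out presences against the shared background.
#'
#' @param sm A [bootstrap_suitability()] result.
#' @param n_windows,window_width Passed to [boyce_index()].
#' @return Data frame with one row per replicate: `replicate`, `auc`, `boyce`.
#' @export
evaluate_replicates <- function(sm, n_windows = 101, window_width = NULL) {
  rows <- lapply(seq_along(sm$eval), function(r) {
    ev <- sm$eval[[r]]
    data.frame(replicate = r,
               auc = auc(ev$test, ev$background),
               boyce = boyce_index(ev$test, ev$background,
                                   n_windows = n_windows,
                                   window_width = window_width))
  })
  do.call(rbind, rows)
}
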