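# Numerically stable log-sum-exp.
logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Sample background cells from the shallow mask
#'
#' Cells are drawn uniformly at random from mask cells; if more cells are
#' requested than the mask holds, sampling switches to with-replacement and
#' a message is logged.
#'
#' @param mask A `shallow_mask` grid.
#' @param n Number of background cells (> 0).
#' @param seed Integer seed.
#' @param replace Force with/without replacement; `NULL` (default) uses
#'   without replacement unless `n` exceeds the mask size.
#' @return Data frame of `row`, `col` background cells.
#' @export
sample_background <- function(mask, n, seed = 1, replace = NULL) {
  if (n <= 0) stop("n must be positive")
  cells <- mask_cells(mask)
  if (nrow(cells) == 0) stop("mask is empty")
  if (is.null(replace)) replace <- n > nrow(cells)
  if (n > nrow(cells) && !replace)
    stop("requested ", n, " cells without replacement from a ",
         nrow(cells), "-cell mask")
  if (replace && n > nrow(cells))
    message("sample_background: n = ", n, " exceeds mask size ",
            nrow(cells), "; sampling with replacement")
  idx <- with_seed(seed, sample.int(nrow(cells), n, replace = replace))
  cells[idx, , drop = FALSE]
}

# Raw predictor matrix -> 8-column feature matrix (4 linear + 4 quadratic).
raw_to_features <- function(X) {
  F <- cbind(X, X^2)
  colnames(F) <- c(paste0(colnames(X), "_lin"), paste0(colnames(X), "_quad"))
  F
}

# Feature scaling constants from the background; quadratic features are
# scaled by the background min/max of the squared variable, matching the
# convention of scaling every feature to [0, 1] over the background.
feature_spec <- function(B_features) {
  fmin <- apply(B_features, 2, min)
  fmax <- apply(B_features, 2, max)
  list(fmin = fmin, fmax = fmax, names = colnames(B_features))
}

# Rescale features with the training constants; deliberately NOT clamped to
# [0, 1], so hindcasts extrapolate beyond the calibration range.
scale_features <- function(F, spec) {
  sweep(sweep(F, 2, spec$fmin), 2, pmax(spec$fmax - spec$fmin, .Machine$double.eps), "/")
}

maxent_objective <- function(lambda, pbar, B, beta_j) {
  -sum(pbar * lambda) + logsumexp(B %*% lambda) + sum(beta_j * abs(lambda))
}

#' Fit a presence-background maximum entropy model
#'
#' Minimises the L1-regularised maxent objective
#' `-(1/m) sum_presence lambda.f(x) + log Z(lambda) + sum_j beta_j |lambda_j|`
#' where `Z` sums `exp(lambda.f)` over the background, features are the four
#' climate layers plus their squares rescaled to `[0, 1]` using background
#' minima and maxima, and `beta_j = beta * s_j / sqrt(m)` with `s_j` the
#' presence-sample standard deviation of feature j. The objective is convex;
#' it is minimised by cyclic coordinate descent with per-coordinate Newton
#' steps, soft thresholding and backtracking, to a stated objective
#' tolerance. Features constant over the background are dropped with a
#' warning. Deterministic given its inputs.
#'
#' @param P_raw Presence predictor matrix (rows = presence cells, one column
#'   per climate variable).
#' @param B_raw Background predictor matrix (same columns).
#' @param features `"lq"` (linear + quadratic, default) or `"l"` (linear only).
#' @param beta Global regularisation multiplier (default 1; 0 disables).
#' @param tol Convergence tolerance on the objective change (default 1e-7).
#' @param max_iter Maximum number of coordinate-descent sweeps (default 5000).
#' @param lambda0 Optional starting weights (full feature length).
#' @return An object of class `maxent_model` with fields `weights`, `log_z`,
#'   `entropy`, `spec` (scaling constants), `beta_j`, `features`, `meta`
#'   (n presences, n background, iterations, final objective, convergence).
#' @export
fit_maxent <- function(P_raw, B_raw, features = c("lq", "l"), beta = 1,
                       tol = 1e-7, max_iter = 5000, lambda0 = NULL) {
  features <- match.arg(features)
  P_raw <- as.matrix(P_raw); B_raw <- as.matrix(B_raw)
  if (nrow(P_raw) < 2) stop("need at least 2 presence cells")
  if (any(!is.finite(P_raw)) || any(!is.finite(B_raw))) {
    bad <- which(!is.finite(rbind(P_raw, B_raw)), arr.ind = TRUE)[1, ]
    stop("non-finite predictor value in column '",
         colnames(P_raw)[bad[2]], "' (row ", bad[1], ")")
  }
  if (is.null(colnames(P_raw)))
    colnames(P_raw) <- colnames(B_raw) <- paste0("v", seq_len(ncol(P_raw)))
  PF <- if (features == "lq") raw_to_features(P_raw) else P_raw
  BF <- if (features == "lq") raw_to_features(B_raw) else B_raw
  spec <- feature_spec(BF)
  degenerate <- spec$fmax - spec$fmin <= .Machine$double.eps
  if (any(degenerate))
    warning("dropping degenerate feature(s) constant over background: ",
            paste(spec$names[degenerate], collapse = ", "))
  keep <- which(!degenerate)
  P <- scale_features(PF, spec)[, keep, drop = FALSE]
  B <- scale_features(BF, spec)[, keep, drop = FALSE]
  m <- nrow(P); nb <- nrow(B); k <- length(keep)
  pbar <- colMeans(P)
  s_j <- apply(P, 2, stats::sd)
  beta_j <- beta * s_j / sqrt(m)
  lambda <- if (is.null(lambda0)) rep(0, k) else lambda0[keep]

  eta <- as.vector(B %*% lambda)
  obj <- -sum(pbar * lambda) + logsumexp(eta) + sum(beta_j * abs(lambda))
  iters <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    iters <- it
    obj_prev <- obj
    for (j in seq_len(k)) {
      lz <- logsumexp(eta)
      w <- exp(eta - lz)
      bj <- B[, j]
      ew <- sum(w * bj)
      g <- -pbar[j] + ew
      h <- max(sum(w * bj^2) - ew^2, 1e-10)
      target <- lambda[j] - g / h
      new_l <- sign(target) * max(0, abs(target) - beta_j[j] / h)
      delta <- new_l - lambda[j]
      if (delta == 0) next
      # backtrack on the exact 1-D objective to guarantee descent
      ok <- FALSE
      for (bt in 1:30) {
        cand <- lambda[j] + delta
        eta_c <- eta + delta * bj
        obj_c <- -(sum(pbar * lambda) - pbar[j] * lambda[j] + pbar[j] * cand) +
          logsumexp(eta_c) +
          sum(beta_j * abs(lambda)) - beta_j[j] * abs(lambda[j]) +
          beta_j[j] * abs(cand)
        if (obj_c <= obj + 1e-15) { ok <- TRUE; break }
        delta <- delta / 2
      }
      if (ok) {
        lambda[j] <- lambda[j] + delta
        eta <- eta + delta * bj
        obj <- obj_c
      }
    }
    if (abs(obj_prev - obj) < tol) { converged <- TRUE; break }
  }
  lz <- logsumexp(eta)
  w <- exp(eta - lz)
  H <- -sum(w * log(pmax(w, 1e-300)))
  full_lambda <- rep(0, ncol(BF))
  names(full_lambda) <- spec$names
  full_lambda[keep] <- lambda
  structure(
    list(weights = full_lambda, log_z = lz, entropy = H,
         spec = spec, keep = keep,
         beta_j = stats::setNames(replace(rep(0, ncol(BF)), keep, beta_j),
                                  spec$names),
         features = features, variables = colnames(P_raw),
         meta = list(n_presences = m, n_background = nb,
                     iterations = iters, objective = obj,
                     converged = converged, beta = beta, tol = tol)),
    class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model: %d presences, %d background, H = %.3f, %s>\n",
              x$meta$n_presences, x$meta$n_background, x$entropy,
              if (x$meta$converged) paste0("converged in ", x$meta$iterations,
                                           " sweeps")
              else "not converged"))
  print(round(x$weights, 4))
  invisible(x)
}

# Raw log-probability log q(x) = lambda.f(x) - log Z for a matrix of raw
# predictors; training rescale, no clamping.
maxent_log_raw <- function(model, X_raw) {
  F <- if (model$features == "lq") raw_to_features(as.matrix(X_raw))
       else as.matrix(X_raw)
  Fs <- scale_features(F, model$spec)[, model$keep, drop = FALSE]
  as.vector(Fs %*% model$weights[model$keep]) - model$log_z
}

#' Logistic suitability prediction on a mask
#'
#' Per cell, raw output `q = exp(lambda.f(x) - log Z)` is transformed to the
#' logistic scale `exp(H) q / (1 + exp(H) q)` using the entropy `H` of the
#' fitted distribution (implicit prevalence 0.5); a cell whose raw output
#' equals `exp(-H)` maps to 0.5. Features use the training rescale without
#' clamping, so extrapolated hindcast conditions are honoured.
#'
#' @param model A [fit_maxent()] model.
#' @param climate [climate_stack()] on the mask grid.
#' @param mask `shallow_mask` grid.
#' @return A [lat_lon_grid()] of logistic suitability in `[0, 1]`, defined
#'   exactly on mask cells.
#' @export
predict_logistic <- function(model, climate, mask) {
  cells <- mask_cells(mask)
  out <- lat_lon_grid(mask$resolution)
  if (nrow(cells) == 0) return(out)
  X <- climate_values_at(climate, cells)
  lr <- maxent_log_raw(model, X)
  out$values[cbind(cells$row, cells$col)] <- stats::plogis(model$entropy + lr)
  out
}

#' Bootstrap-replicated suitability modelling
#'
#' Repeats a random train/test split of the presence cells (85/15 by
#' default), fits a maxent model on each training set against one shared
#' background sample, and predicts logistic suitability over the mask. The
#' returned map carries the replicate stack, the cell-wise median layer, the
#' fitted models, and each replicate's held-out presence scores and the
#' background scores needed for evaluation.
#'
#' @param presences `presence_cells` on the mask grid.
#' @param mask `shallow_mask` grid.
#' @param climate [climate_stack()] on the mask grid.
#' @param n_background Background sample size (default 10000).
#' @param n_reps Number of bootstrap replicates (default 100).
#' @param train_frac Fraction of presences used for training (default 0.85).
#' @param seed Integer seed.
#' @param beta,tol,max_iter,features Passed to [fit_maxent()].
#' @param resample If `TRUE`, presences are resampled with replacement
#'   before each split (classic bootstrap); default is a plain random split.
#' @return An object of class `suitability_map`: `stage_id`, `median` (a
#'   [lat_lon_grid()]), `reps` (cells x reps matrix), `cells`, `models`,
#'   `background`, `eval` (per-replicate test/background scores),
#'   `threshold_inputs`.
#' @export
bootstrap_suitability <- function(presences, mask, climate,
                                  n_background = 10000, n_reps = 100,
                                  train_frac = 0.85, seed = 1,
                                  beta = 1, tol = 1e-7, max_iter = 5000,
                                  features = "lq", resample = FALSE) {
  stopifnot(n_reps >= 1, train_frac > 0, train_frac < 1)
  bg <- sample_background(mask, n_background,
                          seed = derive_seed(seed, "background"))
  cells <- mask_cells(mask)
  B_raw <- climate_values_at(climate, bg)
  X_all <- climate_values_at(climate, cells)
  P_raw_all <- climate_values_at(climate, presences)
  m <- nrow(presences)
  reps <- matrix(NA_real_, nrow(cells), n_reps)
  models <- vector("list", n_reps)
  eval_scores <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    split <- with_seed(derive_seed(seed, "split", r), {
      pool <- if (resample) sample.int(m, m, replace = TRUE) else seq_len(m)
      shuffled <- sample(pool)
      n_train <- floor(train_frac * m)
      list(train = shuffled[seq_len(max(1, n_train))],
           test = shuffled[-seq_len(max(1, n_train))])
    })
    if (length(split$train) < 2)
      stop("fewer than 2 training presences in replicate ", r)
    model <- fit_maxent(P_raw_all[split$train, , drop = FALSE], B_raw,
                        features = features, beta = beta, tol = tol,
                        max_iter = max_iter)
    pred <- stats::plogis(model$entropy + maxent_log_raw(model, X_all))
    reps[, r] <- pred
    models[[r]] <- model
    test_idx <- match(paste(presences$row[split$test], presences$col[split$test]),
                      paste(cells$row, cells$col))
    bg_idx <- match(paste(bg$row, bg$col), paste(cells$row, cells$col))
    eval_scores[[r]] <- list(test = pred[test_idx], background = pred[bg_idx],
                             train = pred[match(paste(presences$row[split$train],
                                                      presences$col[split$train]),
                                               paste(cells$row, cells$col))])
  }
  med <- apply(reps, 1, stats::median)
  med_grid <- lat_lon_grid(mask$resolution)
  med_grid$values[cbind(cells$row, cells$col)] <- med
  structure(
    list(stage_id = climate$stage_id, median = med_grid, reps = reps,
         cells = cells, mask = mask, models = models, background = bg,
         eval = eval_scores, presences = presences,
         meta = list(n_reps = n_reps, train_frac = train_frac, seed = seed)),
    class = "suitability_map")
}

#' Hindcast a replicated model onto a past stage
#'
#' Applies every replicate model to the past stage's climate and mask, with
#' no refitting and the training feature rescale, then recomputes the
#' cell-wise median.
#'
#' @param sm A [bootstrap_suitability()] result (carries the models).
#' @param past_climate [climate_stack()] on the past working grid.
#' @param past_mask `shallow_mask` for the past stage.
#' @return A `suitability_map` for the past stage (no evaluation scores).
#' @export
hindcast <- function(sm, past_climate, past_mask) {
  cells <- mask_cells(past_mask)
  n_reps <- length(sm$models)
  if (nrow(cells) == 0) {
    warning("hindcast: past stage has no shallow cells; empty map")
    med_grid <- lat_lon_grid(past_mask$resolution)
    return(structure(list(stage_id = past_climate$stage_id, median = med_grid,
                          reps = matrix(NA_real_, 0, n_reps), cells = cells,
                          mask = past_mask, models = sm$models,
                          meta = sm$meta),
                     class = "suitability_map"))
  }
  X <- climate_values_at(past_climate, cells)
  reps <- vapply(sm$models, function(model) {
    stats::plogis(model$entropy + maxent_log_raw(model, X))
  }, numeric(nrow(cells)))
  if (is.null(dim(reps))) reps <- matrix(reps, nrow = nrow(cells))
  med <- apply(reps, 1, stats::median)
  med_grid <- lat_lon_grid(past_mask$resolution)
  med_grid$values[cbind(cells$row, cells$col)] <- med
  structure(
    list(stage_id = past_climate$stage_id, median = med_grid, reps = reps,
         cells = cells, mask = past_mask, models = sm$models, meta = sm$meta),
    class = "suitability_map")
}

#' Serialise a maxent model to JSON
#' @param model A `maxent_model`.
#' @param path Output file path.
#' @export
save_maxent_json <- function(model, path) {
  obj <- list(weights = as.list(model$weights), log_z = model$log_z,
              entropy = model$entropy,
              scaling = list(fmin = as.list(model$spec$fmin),
                             fmax = as.list(model$spec$fmax)),
              beta_j = as.list(model$beta_j), features = model$features,
              variables = model$variables, meta = model$meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
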