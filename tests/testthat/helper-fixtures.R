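# Shared fixtures, built once per test run and memoised. The "study" world
# is the full-size 1-degree, 5-stage synthetic world used by the
# calibration-scale checks; unit tests use small hand-built grids instead.

.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

study_world <- function() get_fixture("study_world", function() {
  wc <- world_config(seed = 1)
  stages <- lapply(seq_len(wc$n_stages), function(i) make_stage(wc, i))
  tp <- make_truth_and_presences(wc, 1, stages[[1]]$mask, stages[[1]]$climate)
  list(config = wc, stages = stages, truth = tp$truth,
       presences = tp$presences)
})

# 20-replicate calibrated model on the study world (the heavier fixture,
# shared by the hindcast-validation and recovery checks)
study_model <- function() get_fixture("study_model", function() {
  w <- study_world()
  sm <- suppressMessages(bootstrap_suitability(
    w$presences, w$stages[[1]]$mask, w$stages[[1]]$climate,
    n_background = 10000, n_reps = 20, seed = 1))
  ltp <- threshold_ltp(sm$median, w$presences)
  list(sm = sm, ltp = ltp$threshold)
})

# small square bathymetry grid at a given resolution with constant depth,
# optionally patched by a function of (lat, lon)
flat_bathymetry <- function(resolution, depth) {
  g <- lat_lon_grid(resolution)
  g$values[] <- depth
  bathymetry(g)
}

# climate stack with constant layers on a grid template
constant_climate <- function(grid, sst_max = 28, sst_min = 24,
                             ins_max = 400, ins_min = 250,
                             stage_id = "test") {
  mk <- function(v) {
    g <- lat_lon_grid(grid$resolution)
    g$values[] <- v
    g
  }
  climate_stack(stage_id, mk(sst_max), mk(sst_min), mk(ins_max), mk(ins_min))
}

# brute-force pairwise AUC (enumeration oracle)
auc_brute <- function(pres, bg) {
  wins <- 0
  for (p in pres) for (b in bg)
    wins <- wins + (p > b) + 0.5 * (p == b)
  wins / (length(pres) * length(bg))
}

# exhaustive signed-rank p-value by enumerating all 2^n sign patterns
signed_rank_p_enum <- function(x, mu, alternative = "less") {
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  count <- 0
  for (bits in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(bits))[seq_len(n)]
    W <- sum(r[signs == 1])
    if (alternative == "less") count <- count + (W <= W_obs)
    else count <- count + (W >= W_obs)
  }
  count / 2^n
}

# maxent objective evaluated exactly as fit_maxent defines it, for use with
# a generic optimiser as an independent oracle
maxent_obj_fun <- function(P, B, beta_j) {
  pbar <- colMeans(P)
  function(lambda) {
    eta <- as.vector(B %*% lambda)
    me <- max(eta)
    -sum(pbar * lambda) + me + log(sum(exp(eta - me))) +
      sum(beta_j * abs(lambda))
  }
}
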