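make_instance <- function(seed, n_bg = 8, n_pres = 4, n_var = 2) {
  set.seed(seed)
  B <- matrix(rnorm(n_bg * n_var, 20, 4), n_bg, n_var,
              dimnames = list(NULL, paste0("v", seq_len(n_var))))
  P <- B[sample(n_bg, n_pres, replace = TRUE), , drop = FALSE] +
    matrix(rnorm(n_pres * n_var, 0, 0.3), n_pres, n_var)
  list(P = P, B = B)
}

test_that("background sampling stays inside the mask and is seeded", {
  b <- flat_bathymetry(1, 4000)
  b$values[80:100, 100:140] <- 50
  mask <- build_shallow_mask(b)
  bg1 <- sample_background(mask, 500, seed = 42)
  bg2 <- sample_background(mask, 500, seed = 42)
  expect_identical(bg1, bg2)
  expect_true(all(mask$values[cbind(bg1$row, bg1$col)]))
  # requesting exactly the mask without replacement returns the mask
  n <- mask_size(mask)
  bg_all <- sample_background(mask, n, seed = 1, replace = FALSE)
  expect_equal(nrow(unique(bg_all)), n)
  expect_error(sample_background(mask, 0), "positive")
  expect_message(sample_background(mask, n + 10, seed = 1), "replacement")
})

test_that("fitted objective matches a generic-optimiser minimum on tiny instances", {
  for (seed in 1:5) {
    inst <- make_instance(seed)
    fit <- fit_maxent(inst$P, inst$B, features = "l", beta = 0.5,
                      tol = 1e-12, max_iter = 20000)
    spec <- paleoreef:::feature_spec(inst$B)
    Ps <- paleoreef:::scale_features(inst$P, spec)
    Bs <- paleoreef:::scale_features(inst$B, spec)
    beta_j <- 0.5 * apply(Ps, 2, sd) / sqrt(nrow(Ps))
    f <- maxent_obj_fun(Ps, Bs, beta_j)
    best <- Inf
    for (r in 1:6) {
      set.seed(100 * seed + r)
      o <- suppressWarnings(
        optim(rnorm(ncol(Ps), 0, 2), f, method = "Nelder-Mead",
              control = list(maxit = 5000, reltol = 1e-14)))
      best <- min(best, o$value)
    }
    expect_lt(fit$meta$objective, best + 1e-4)
  }
})

test_that("moment matching holds at beta = 0 (KKT at the optimum)", {
  for (seed in 1:10) {
    inst <- make_instance(seed, n_bg = 30, n_pres = 8)
    fit <- fit_maxent(inst$P, inst$B, features = "l", beta = 0,
                      tol = 1e-14, max_iter = 50000)
    spec <- paleoreef:::feature_spec(inst$B)
    Bs <- paleoreef:::scale_features(inst$B, spec)
    Ps <- paleoreef:::scale_features(inst$P, spec)
    w <- exp(as.vector(Bs %*% fit$weights) - fit$log_z)
    expect_lt(max(abs(colSums(w * Bs) - colMeans(Ps))), 1e-5)
  }
})

test_that("raw background probabilities sum to one and entropy is non-negative", {
  inst <- make_instance(7, n_bg = 50, n_pres = 10)
  fit <- fit_maxent(inst$P, inst$B, beta = 1)
  spec <- fit$spec
  Bs <- paleoreef:::scale_features(paleoreef:::raw_to_features(inst$B),
                                   spec)[, fit$keep, drop = FALSE]
  w <- exp(as.vector(Bs %*% fit$weights[fit$keep]) - fit$log_z)
  expect_lt(abs(sum(w) - 1), 1e-10)
  expect_gte(fit$entropy, 0)
})

test_that("the objective is convex: random restarts agree", {
  inst <- make_instance(13, n_bg = 40, n_pres = 10)
  objs <- sapply(1:5, function(r) {
    set.seed(r)
    fit_maxent(inst$P, inst$B, beta = 0.3, tol = 1e-12, max_iter = 50000,
               lambda0 = rnorm(2 * ncol(inst$P), 0, 3))$meta$objective
  })
  expect_lt(diff(range(objs)), 1e-6)
})

test_that("no signal means shrinkage: presence = background gives near-zero weights", {
  set.seed(21)
  B <- matrix(rnorm(60, 20, 4), 30, 2, dimnames = list(NULL, c("a", "b")))
  fit <- fit_maxent(B, B, beta = 1, features = "l")
  expect_lt(max(abs(fit$weights)), 0.05)
  # raw distribution is near-uniform over background
  spec <- fit$spec
  Bs <- paleoreef:::scale_features(B, spec)[, fit$keep, drop = FALSE]
  w <- exp(as.vector(Bs %*% fit$weights[fit$keep]) - fit$log_z)
  expect_lt(max(abs(w - 1 / 30)), 1e-3)
})

test_that("degenerate and non-finite predictors are handled explicitly", {
  set.seed(3)
  B <- cbind(v1 = rnorm(20, 10), v2 = 5)   # constant second variable
  P <- B[1:4, ]
  expect_warning(fit_maxent(P, B, features = "l"), "degenerate")
  B2 <- cbind(v1 = rnorm(20, 10)); B2[3] <- NA
  expect_error(fit_maxent(B2[1:3, , drop = FALSE], B2, features = "l"),
               "non-finite")
  expect_error(fit_maxent(B2[1, , drop = FALSE], B2, features = "l"),
               "at least 2")
})

test_that("logistic output is a rank-preserving transform centred at exp(-H)", {
  # a cell whose raw output equals exp(-entropy) maps to exactly 0.5
  inst <- make_instance(17, n_bg = 40, n_pres = 10)
  fit <- fit_maxent(inst$P, inst$B, beta = 1)
  lr <- paleoreef:::maxent_log_raw(fit, inst$B)
  logistic <- stats::plogis(fit$entropy + lr)
  expect_equal(stats::plogis(fit$entropy + (-fit$entropy)), 0.5)
  # rank preservation: AUC identical between raw and logistic scores
  lp <- paleoreef:::maxent_log_raw(fit, inst$P)
  expect_equal(auc(stats::plogis(fit$entropy + lp), logistic),
               auc(lp, lr))
})

test_that("prediction on identical background climate is constant", {
  mask <- build_shallow_mask(flat_bathymetry(1, 100))
  cl <- constant_climate(mask)
  set.seed(5)
  # fit on a variable instance, then predict on the constant stage
  inst <- make_instance(19, n_bg = 30, n_pres = 8, n_var = 4)
  colnames(inst$P) <- colnames(inst$B) <- climate_layer_names()
  fit <- fit_maxent(inst$P, inst$B, beta = 1)
  pred <- predict_logistic(fit, cl, mask)
  expect_equal(length(unique(as.vector(pred$values))), 1)
  expect_true(all(pred$values >= 0 & pred$values <= 1))
})

test_that("a cell far below the training SST range extrapolates to ~0 suitability", {
  w <- study_world()
  m <- study_model()
  model <- m$sm$models[[1]]
  cold <- cbind(sst_max = 2, sst_min = -2, ins_max = 350, ins_min = 250)
  p_cold <- stats::plogis(model$entropy +
                            paleoreef:::maxent_log_raw(model, cold))
  expect_lt(p_cold, 0.01)
})

test_that("bootstrap replication is seeded, split correctly, and median-stacked", {
  b <- flat_bathymetry(1, 4000)
  b$values[85:95, 170:200] <- 50
  mask <- build_shallow_mask(b)
  wc <- world_config(seed = 2, n_stages = 1)
  cl <- make_climate(wc, 1)
  clw <- regrid_climate(cl, mask)
  tp <- make_truth_and_presences(wc, 1, mask, clw, n_presences = 40)
  sm1 <- bootstrap_suitability(tp$presences, mask, clw, n_background = 300,
                               n_reps = 1, seed = 5)
  expect_equal(sm1$median$values[cbind(sm1$cells$row, sm1$cells$col)],
               sm1$reps[, 1])
  sm_a <- bootstrap_suitability(tp$presences, mask, clw, n_background = 300,
                                n_reps = 3, seed = 9)
  sm_b <- bootstrap_suitability(tp$presences, mask, clw, n_background = 300,
                                n_reps = 3, seed = 9)
  expect_identical(sm_a$median, sm_b$median)
  # train/test split proportions
  expect_equal(length(sm_a$eval[[1]]$test), 40 - floor(0.85 * 40))
  expect_error(
    bootstrap_suitability(tp$presences[1:2, ], mask, clw,
                          n_background = 100, n_reps = 1, seed = 1,
                          train_frac = 0.5),
    "training presences")
})

test_that("hindcasting the calibration stage reproduces the calibration map", {
  w <- study_world()
  m <- study_model()
  h <- hindcast(m$sm, w$stages[[1]]$climate, w$stages[[1]]$mask)
  expect_equal(h$median$values, m$sm$median$values, tolerance = 1e-12)
  # a stage with no shallow cells yields an empty map with a warning
  empty_mask <- build_shallow_mask(flat_bathymetry(1, 4000))
  cl <- constant_climate(empty_mask)
  expect_warning(h0 <- hindcast(m$sm, cl, empty_mask), "no shallow")
  expect_true(all(is.na(h0$median$values)))
})

test_that("model JSON serialisation round-trips the weights", {
  inst <- make_instance(23, n_bg = 30, n_pres = 8)
  fit <- fit_maxent(inst$P, inst$B, beta = 1)
  path <- withr::local_tempfile(fileext = ".json")
  save_maxent_json(fit, path)
  back <- jsonlite::read_json(path)
  expect_equal(unlist(back$weights), fit$weights, tolerance = 1e-12)
  expect_equal(back$entropy, fit$entropy, tolerance = 1e-12)
})
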