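#' Full run configuration
#'
#' Bundles the synthetic-world configuration with the modelling, evaluation
#' and validation knobs. Defaults mirror the standard study settings: 10,000
#' background cells, 100 bootstrap replicates with an 85/15 train/test
#' split, at most 5000 optimiser sweeps, LTP and MaxSSS thresholds, 1000
#' random point sets, alpha 0.05.
#'
#' @param seed Top-level seed, fanned out into named substreams.
#' @param world A [world_config()] (its own seed is overridden by `seed`).
#' @param working_resolution Working grid resolution in degrees.
#' @param n_background,n_reps,train_frac,max_iter,beta,tol,features
#'   Passed to [bootstrap_suitability()].
#' @param n_sets,n_random_values Validation knobs (see [validate_stage()]).
#' @param alpha Significance level for the Wilcoxon tests.
#' @param area_weighted_null Use cos-latitude weights in the null model.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, world = world_config(seed = seed),
                       working_resolution = 1,
                       n_background = 10000, n_reps = 100, train_frac = 0.85,
                       max_iter = 5000, beta = 1, tol = 1e-7, features = "lq",
                       n_sets = 1000, n_random_values = 1000, alpha = 0.05,
                       area_weighted_null = FALSE) {
  world$seed <- as.integer(derive_seed(seed, "world"))
  cfg <- list(seed = as.integer(seed), world = world,
              working_resolution = working_resolution,
              n_background = n_background, n_reps = n_reps,
              train_frac = train_frac, max_iter = max_iter, beta = beta,
              tol = tol, features = features, n_sets = n_sets,
              n_random_values = n_random_values, alpha = alpha,
              area_weighted_null = area_weighted_null)
  class(cfg) <- "run_config"
  cfg
}

#' Small demonstration configuration
#'
#' A 3-stage world on a 2-degree working grid with reduced replicate,
#' background and null-set counts, sized so a full end-to-end run completes
#' in well under a minute. Used by the worked examples and the determinism
#' checks.
#'
#' @param seed Top-level seed.
#' @return A `run_config`.
#' @export
demo_config <- function(seed = 1) {
  run_config(
    seed = seed,
    world = world_config(seed = seed, n_stages = 3,
                         stage_sst_offset = c(0, 4, -4),
                         n_modern_presences = 150,
                         fossils_per_stage = 30),
    working_resolution = 2,
    n_background = 2000, n_reps = 3, max_iter = 2000, tol = 1e-6,
    n_sets = 200, n_random_values = 300)
}

#' Run the full pipeline on a synthetic world
#'
#' Generates every stage (bathymetry, shallow mask, climate on the working
#' grid), calibrates the bootstrap-replicated maxent model on stage 1's
#' presences, derives LTP and MaxSSS thresholds from the calibration stage,
#' hindcasts every stage, evaluates the calibration replicates (AUC, Boyce),
#' computes MESS novelty maps against the calibration background, validates
#' each hindcast against the synthetic fossil record with random-point null
#' models and one-sided Wilcoxon tests, and summarises spatiotemporal
#' metrics plus the site-count vs. area regression. Fully deterministic
#' given the configuration seed.
#'
#' @param config A [run_config()].
#' @param outdir Optional directory; when given, CSV tables (`validation_*`,
#'   `stage_metrics_*`, `evaluation`), the model JSON and the resolved
#'   configuration are written there.
#' @return A results bundle (list): `config`, `stages`, `calibration`
#'   (suitability map), `thresholds`, `evaluation`, `hindcasts`, `mess`,
#'   `fossils`, `binned`, `validation` (per threshold kind), `metrics` (per
#'   threshold kind), `regression`.
#' @export
run_all <- function(config, outdir = NULL) {
  wc <- config$world
  step <- function(...) message(format(Sys.time(), "%H:%M:%S "), ...)

  step("generating ", wc$n_stages, " synthetic stage(s)")
  stages <- lapply(seq_len(wc$n_stages), function(i) {
    tryCatch(make_stage(wc, i, config$working_resolution),
             error = function(e) stop("stage ", i, " generation failed: ",
                                      conditionMessage(e)))
  })

  step("calibrating on stage 1 (", mask_size(stages[[1]]$mask), " mask cells)")
  tp <- make_truth_and_presences(wc, 1, stages[[1]]$mask, stages[[1]]$climate)
  presences <- tp$presences
  calib <- bootstrap_suitability(
    presences, stages[[1]]$mask, stages[[1]]$climate,
    n_background = config$n_background, n_reps = config$n_reps,
    train_frac = config$train_frac, seed = derive_seed(config$seed, "hsm"),
    beta = config$beta, tol = config$tol, max_iter = config$max_iter,
    features = config$features)
  evaluation <- evaluate_replicates(calib)

  ltp <- threshold_ltp(calib$median, presences)
  maxsss <- threshold_maxsss(calib$median, presences, calib$background)
  thresholds <- list(ltp = ltp$threshold, maxsss = maxsss$threshold)
  ref <- as.data.frame(climate_values_at(stages[[1]]$climate, calib$background))

  step("hindcasting ", wc$n_stages, " stage(s)")
  hindcasts <- lapply(stages, function(s) hindcast(calib, s$climate, s$mask))
  mess_maps <- lapply(stages, function(s)
    mess(as.list(ref), s$climate, s$mask))

  step("sampling and binning fossils")
  fossil_stages <- stages[seq_len(wc$n_stages)[-1]]
  fossils <- make_fossils(wc, fossil_stages)
  st <- stage_table(wc)
  masks <- stats::setNames(lapply(stages, `[[`, "mask"), st$stage_id)
  binned <- bin_fossils(fossils, st, masks)

  step("validating hindcasts")
  validation <- list()
  metrics <- list()
  for (kind in c("ltp", "maxsss")) {
    thr <- thresholds[[kind]]
    vrows <- list(); mrows <- list()
    for (i in seq_len(wc$n_stages)) {
      sid <- st$stage_id[i]
      bin <- binary_map(hindcasts[[i]]$median, thr, kind = kind,
                        stage_id = sid)
      fc <- binned[[sid]]$cells
      vrows[[i]] <- validate_stage(
        fc, bin, hindcasts[[i]]$median, stages[[i]]$mask,
        n_sets = config$n_sets, n_random_values = config$n_random_values,
        seed = derive_seed(config$seed, "null", kind, i),
        area_weighted = config$area_weighted_null)
      mrows[[i]] <- stage_metrics(hindcasts[[i]], thr,
                                  n_fossil_sites = nrow(fc))
    }
    validation[[kind]] <- do.call(rbind, vrows)
    metrics[[kind]] <- do.call(rbind, mrows)
  }

  regression <- lapply(metrics, function(mm) {
    past <- seq_len(nrow(mm))[-1]   # fossils exist only for hindcast stages
    if (length(past) >= 3)
      area_vs_sites_regression(mm$area_global_1e6km2[past],
                               mm$n_fossil_sites[past])
    else NULL
  })

  bundle <- list(config = config, stages = stages, calibration = calib,
                 presences = presences, truth_modern = tp$truth,
                 thresholds = thresholds, evaluation = evaluation,
                 hindcasts = hindcasts, mess = mess_maps, fossils = fossils,
                 binned = binned, validation = validation, metrics = metrics,
                 regression = regression)
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

#' Write the tabular outputs of a results bundle
#'
#' @param bundle A [run_all()] result.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
  wr(bundle$evaluation, "evaluation.csv")
  for (kind in names(bundle$validation)) {
    wr(bundle$validation[[kind]], paste0("validation_", kind, ".csv"))
    wr(bundle$metrics[[kind]], paste0("stage_metrics_", kind, ".csv"))
  }
  wr(data.frame(kind = names(bundle$thresholds),
                threshold = unlist(bundle$thresholds)), "thresholds.csv")
  write_occurrences_csv(bundle$fossils, file.path(outdir, "fossils.csv"))
  save_maxent_json(bundle$calibration$models[[1]],
                   file.path(outdir, "model_rep1.json"))
  cfg <- bundle$config
  cfg$world$continents <- lapply(cfg$world$continents, as.list)
  jsonlite::write_json(cfg, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(outdir)
}
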