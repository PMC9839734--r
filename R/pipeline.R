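#' Pipeline configuration profiles
#'
#' `"study"` mirrors the full experimental protocol: 24 horses split 16-4-4,
#' walk at 1.7 and 1.8 m/s, trot at 3.3, 4.0, 4.5 and 5.0 m/s, 20 s of
#' locomotion per trial, bilayer BiLSTM with 200 hidden units, 10 repeats.
#' `"scaled"` is a reduced profile for desk-scale runs: 6 horses split 4-1-1,
#' 64 hidden units, 1 repeat, same speeds, gaits, dropout, learning rate,
#' batch size and epoch budget; every deviation from the study profile is
#' listed in the run manifest.
#'
#' @param profile `"study"` or `"scaled"`.
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir output directory for reports and tables.
#' @param cache_dir directory for cached stage outputs (content-hash keyed).
#' @param ... overrides for any config field.
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(profile = c("scaled", "study"), seed = 1L,
                            out_dir = "results/pipeline",
                            cache_dir = NULL, ...) {
  profile <- match.arg(profile)
  base <- list(
    profile = profile, seed = as.integer(seed), out_dir = out_dir,
    cache_dir = cache_dir,
    n_horses = 24L, counts = c(16L, 4L, 4L),
    speeds = list(walk = c(1.7, 1.8), trot = c(3.3, 4.0, 4.5, 5.0)),
    duration = 30, standstill = 10,
    sensor = list(),
    node_sets = c("All", "UB", "Limbs", "Sac", "Wth"),
    events_source = "detector", target_strides = NULL,
    hidden_units = 200L, dropout_p = 0.40,
    learning_rate = 0.002, batch_size = 64L, max_epochs = 40L,
    n_repeats = 10L,
    deviations = character(0))
  if (profile == "scaled") {
    base$n_horses <- 6L; base$counts <- c(4L, 1L, 1L)
    base$hidden_units <- 64L; base$n_repeats <- 1L
    base$duration <- 35; base$target_strides <- 260L
    base$deviations <- c("n_horses 24 -> 6", "split 16-4-4 -> 4-1-1",
                         "hidden_units 200 -> 64", "repeats 10 -> 1",
                         "locomotion 20 s -> 25 s per trial",
                         "strides thinned to <= 260 per gait")
  }
  over <- list(...)
  for (k in names(over)) base[[k]] <- over[[k]]
  assert_that(sum(base$counts) == base$n_horses,
              "split counts (%d) must sum to the horse count (%d)",
              sum(base$counts), base$n_horses)
  structure(base, class = "run_config")
}

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

cache_get_or <- function(cache_dir, key, fn) {
  if (is.null(cache_dir)) return(fn())
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(cache_dir, paste0(key, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  val <- fn()
  saveRDS(val, path)
  val
}

#' Simulate and process the trials of one gait
#'
#' @param config a [pipeline_config()].
#' @param gait `"walk"` or `"trot"`.
#' @return list of processed `trial_recording`s (one per horse x speed).
#' @export
simulate_gait_trials <- function(config, gait) {
  horses <- sample_horses(config$n_horses, seed = config$seed)
  sensor <- do.call(sensor_model, config$sensor)
  trials <- list()
  for (hi in seq_along(horses)) {
    for (si in seq_along(config$speeds[[gait]])) {
      sp <- config$speeds[[gait]][si]
      h <- horses[[hi]]
      # per-trial seed so repeated trials of one horse differ
      h$rng_seed <- (h$rng_seed + 7919L * si +
                       if (gait == "trot") 104729L else 0L) %% .Machine$integer.max
      trial <- simulate_trial(h, gait_params(gait, sp), sensor,
                              duration = config$duration,
                              standstill = config$standstill)
      trials[[length(trials) + 1]] <- process_trial(trial)
    }
  }
  trials
}

#' Run the full simulate - calibrate - segment - build - train - evaluate
#' pipeline
#'
#' Executes every stage for each configured gait and node set, training one
#' curve and one peak predictor per combination, and writes metric tables,
#' the node-set comparison report and a run manifest (config hash, seeds,
#' deviations from the study profile) into `out_dir`. Stage outputs are
#' cached under `cache_dir` keyed by the hash of the config fields they
#' depend on, so partial re-runs resume.
#'
#' @param config a [pipeline_config()].
#' @param gaits gaits to run.
#' @return list of class `pipeline_result`: per gait the fitted node sets and
#'   the `node_set_report`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         gaits = names(config$speeds)) {
  assert_that(sum(config$counts) == config$n_horses,
              "split counts must sum to the horse count")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  sim_cfg <- config[c("n_horses", "seed", "speeds", "duration", "standstill",
                      "sensor")]
  results <- list()
  for (gait in gaits) {
    trials <- cache_get_or(config$cache_dir,
                           paste0("trials_", gait, "_",
                                  config_hash(c(sim_cfg, gait))),
                           function() simulate_gait_trials(config, gait))
    fits <- list()
    for (ns_name in config$node_sets) {
      ns <- node_set(ns_name)
      samples <- thin_samples(build_samples(trials, ns,
                                            events_source = config$events_source),
                              config$target_strides)
      bundle <- finalize_bundle(split_by_horse(samples, config$counts,
                                               seed = config$seed + 17L))
      tc <- training_config(config$learning_rate, config$batch_size,
                            config$max_epochs, seed = config$seed + 29L)
      key_base <- config_hash(list(sim_cfg, gait, ns_name,
                                   config$hidden_units, config$dropout_p, tc,
                                   config$counts, config$events_source))
      fit_curve <- cache_get_or(config$cache_dir,
                                paste0("curve_", key_base), function() {
        train_predictor(NULL, bundle, tc,
                        model_config(hidden_units = config$hidden_units,
                                     dropout_p = config$dropout_p,
                                     head = "curve"))
      })
      fit_peak <- cache_get_or(config$cache_dir,
                               paste0("peak_", key_base), function() {
        train_predictor(NULL, bundle, tc,
                        model_config(hidden_units = config$hidden_units,
                                     dropout_p = config$dropout_p,
                                     head = "peak"))
      })
      fits[[ns_name]] <- list(curve = fit_curve, peak = fit_peak,
                              test = bundle$test, bundle_horses = bundle$horses)
    }
    report <- compare_node_sets(fits)
    write_num_csv(report$medians,
                  file.path(config$out_dir, paste0(gait, "_curve_medians.csv")))
    write_num_csv(report$peaks,
                  file.path(config$out_dir, paste0(gait, "_peak_agreement.csv")))
    write_num_csv(report$si,
                  file.path(config$out_dir, paste0(gait, "_si_agreement.csv")))
    results[[gait]] <- list(fits = fits, report = report)
  }
  manifest <- list(config_hash = config_hash(unclass(config)),
                   seed = config$seed, profile = config$profile,
                   deviations = config$deviations,
                   package_version = as.character(utils::packageVersion("equigrf")),
                   gaits = gaits, timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  structure(results, class = "pipeline_result")
}
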