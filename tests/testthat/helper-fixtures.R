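# Shared fixtures, memoised for the whole test session: simulation and
# training are the expensive stages, so every test file draws on the same
# cached objects.

.fix <- new.env(parent = emptyenv())

fix_memo <- function(key, fn) {
  if (!exists(key, envir = .fix)) assign(key, fn(), envir = .fix)
  get(key, envir = .fix)
}

fix_trial <- function(gait = "walk", seed = 42L, duration = 22, ...) {
  key <- paste("trial", gait, seed, duration, sep = "_")
  fix_memo(key, function() {
    simulate_trial(horse_spec("H1", rng_seed = seed), gait_params(gait),
                   sensor_model(), duration = duration, ...)
  })
}

fix_processed <- function(gait = "walk", seed = 42L, duration = 22) {
  key <- paste("proc", gait, seed, duration, sep = "_")
  fix_memo(key, function() process_trial(fix_trial(gait, seed, duration)))
}

# the scaled headline experiment: 6 horses 4-1-1, All node set, hidden 64,
# <= 40 epochs, <= 260 strides per gait
headline_run <- function(gait) {
  fix_memo(paste0("headline_", gait), function() {
    cfg <- pipeline_config("scaled", seed = 1)
    trials <- simulate_gait_trials(cfg, gait)
    samples <- thin_samples(build_samples(trials, node_set("All")),
                            cfg$target_strides)
    bundle <- finalize_bundle(split_by_horse(samples, cfg$counts,
                                             seed = cfg$seed + 17L))
    fit <- train_predictor(NULL, bundle,
                           training_config(seed = cfg$seed + 29L),
                           model_config(hidden_units = cfg$hidden_units,
                                        head = "curve"))
    list(trials = trials, bundle = bundle, fit = fit,
         ev = evaluate_curve_predictions(fit, bundle$test))
  })
}

# reduced node-set comparison: 4 node sets x 3 paired repeats on the walk
# trials of the headline run (hidden 32, 12 epochs, 120 strides)
ordering_run <- function() {
  fix_memo("ordering", function() {
    trials <- headline_run("walk")$trials
    out <- list()
    for (ns in c("All", "UB", "Limbs", "Sac")) {
      samples <- thin_samples(build_samples(trials, node_set(ns)), 120)
      ex <- repeat_experiment(samples, c(4, 1, 1),
                              model_config(hidden_units = 32, head = "curve"),
                              training_config(max_epochs = 12, seed = 100L),
                              n_repeats = 3, seeds = c(101L, 202L, 303L))
      out[[ns]] <- vapply(ex$repeats, `[[`, numeric(1), "median_rmse")
    }
    out
  })
}

# synthetic task whose curve target is a fixed linear map of the inputs
make_linear_samples <- function(n = 24, C = 6, Tn = 60, seed = 5L) {
  withr::with_seed(seed, {
    W <- matrix(stats::rnorm(4 * C, 0, 0.6), 4, C)
    lapply(seq_len(n), function(i) {
      tgrid <- seq(0, 1, length.out = Tn)
      X <- t(vapply(seq_len(C), function(j) {
        stats::rnorm(1, 0, 1) * sin(2 * pi * tgrid + stats::runif(1, 0, 2 * pi)) +
          stats::rnorm(1, 0, 0.3)
      }, numeric(Tn)))
      structure(list(input = X, curve = W %*% X,
                     peak = apply(W %*% X, 1, max),
                     peak_time = rep(0.5, 4), single_peak = rep(TRUE, 4),
                     stance_frac = cbind(rep(0, 4), rep(1, 4)),
                     meta = list(horse_id = sprintf("H%02d", (i %% 6) + 1),
                                 gait = "trot", speed = 1,
                                 start = i, end = i + 1)),
                class = "stride_sample")
    })
  })
}
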