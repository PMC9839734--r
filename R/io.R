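# Plain-text serialization: trials as a directory of CSV files with a JSON
# sidecar; numeric values written with %.17g so round-trips are bit-exact.

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

write_num_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write / read a trial recording as a directory of CSV files
#'
#' Layout: `meta.json` (horse, gait and sensor specifications, calibration
#' truth), one `node_<name>.csv` per IMU node (timestamps, low-g and high-g
#' acceleration, gyroscope), `grfz.csv` (force-plate stream on its own
#' clock), `omc.csv` (angular-velocity magnitude surrogate), `events.csv`
#' (limb, type, time_s) and `truth_grfz.csv`.
#'
#' @param trial a `trial_recording`.
#' @param dir output directory (created).
#' @return `dir`, invisibly (writer); a `trial_recording` (reader). Truth
#'   node-level signal channels are not serialized; everything else
#'   round-trips exactly.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gp <- unclass(trial$gait_params)
  gp$footfall_phases <- as.list(gp$footfall_phases)  # keep names in JSON
  meta <- list(horse = unclass(trial$horse),
               gait_params = gp,
               sensor = unclass(trial$sensor),
               standstill = trial$standstill, duration = trial$duration,
               truth = trial$truth[c("gyro_bias", "accel_scale",
                                     "clock_offset", "amps", "stride_starts",
                                     "periods", "t_lead", "balance_window",
                                     "front_share")])
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  for (node in grf_nodes()) {
    nd <- trial$nodes[[node]]
    df <- data.frame(t = trial$t_imu, nd$acc_low, nd$acc_high, nd$gyro)
    names(df) <- c("t", paste0("low_", c("x", "y", "z")),
                   paste0("high_", c("x", "y", "z")),
                   paste0("gyr_", c("x", "y", "z")))
    write_num_csv(df, file.path(dir, sprintf("node_%s.csv", node)))
  }
  gr <- data.frame(t = trial$grfz$t, trial$grfz$force)
  names(gr) <- c("t", grf_limbs())
  write_num_csv(gr, file.path(dir, "grfz.csv"))
  write_num_csv(data.frame(t = trial$omc$t, ang_mag = trial$omc$ang_mag),
                file.path(dir, "omc.csv"))
  ev <- do.call(rbind, lapply(grf_limbs(), function(limb) {
    rbind(data.frame(limb = limb, type = "on", time_s = trial$events[[limb]]$on),
          data.frame(limb = limb, type = "off", time_s = trial$events[[limb]]$off))
  }))
  write_num_csv(ev, file.path(dir, "events.csv"))
  tg <- data.frame(t = trial$truth$t_grf, trial$truth$grfz)
  names(tg) <- c("t", grf_limbs())
  write_num_csv(tg, file.path(dir, "truth_grfz.csv"))
  invisible(dir)
}

#' @rdname write_trial
#' @export
read_trial <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  nodes <- list()
  for (node in grf_nodes()) {
    df <- utils::read.csv(file.path(dir, sprintf("node_%s.csv", node)))
    ax <- c("acc_x", "acc_y", "acc_z"); gx <- c("gyr_x", "gyr_y", "gyr_z")
    nodes[[node]] <- list(
      acc_low = `dimnames<-`(as.matrix(df[2:4]), list(NULL, ax)),
      acc_high = `dimnames<-`(as.matrix(df[5:7]), list(NULL, ax)),
      gyro = `dimnames<-`(as.matrix(df[8:10]), list(NULL, gx)))
    t_imu <- df$t
  }
  gr <- utils::read.csv(file.path(dir, "grfz.csv"))
  omc <- utils::read.csv(file.path(dir, "omc.csv"))
  ev <- utils::read.csv(file.path(dir, "events.csv"))
  events <- stats::setNames(lapply(grf_limbs(), function(limb) {
    list(on = ev$time_s[ev$limb == limb & ev$type == "on"],
         off = ev$time_s[ev$limb == limb & ev$type == "off"])
  }), grf_limbs())
  tg <- utils::read.csv(file.path(dir, "truth_grfz.csv"))
  gp <- meta$gait_params
  params <- gait_params(gp$gait, gp$speed, gp$stride_duration, gp$duty_factor,
                        unlist(gp$footfall_phases), gp$dip_depth,
                        gp$peak_front, gp$peak_hind, gp$walk_minor_ratio,
                        gp$swing_gyro_amp)
  horse <- do.call(horse_spec, as.list(meta$horse))
  sensor <- do.call(sensor_model, as.list(meta$sensor))
  truth <- meta$truth
  truth$t_grf <- tg$t
  truth$grfz <- as.matrix(tg[grf_limbs()])
  truth$amps <- unlist(truth$amps)
  structure(list(horse = horse, gait_params = params, sensor = sensor,
                 t_imu = t_imu, nodes = nodes,
                 grfz = list(t = gr$t, force = as.matrix(gr[grf_limbs()])),
                 omc = list(t = omc$t, ang_mag = omc$ang_mag),
                 events = events, standstill = meta$standstill,
                 duration = meta$duration, truth = truth),
            class = "trial_recording")
}

#' Write / read hoof events and stride windows as CSV
#'
#' @param events a `hoof_event_table`; `windows` a list of `stride_window`s.
#' @param path CSV file path.
#' @name segmentation_io
#' @export
write_events_csv <- function(events, path) {
  df <- do.call(rbind, lapply(grf_limbs(), function(limb) {
    rbind(data.frame(limb = limb, type = "on", time_s = events[[limb]]$on),
          data.frame(limb = limb, type = "off", time_s = events[[limb]]$off))
  }))
  write_num_csv(df, path)
  invisible(path)
}

#' @rdname segmentation_io
#' @export
write_windows_csv <- function(windows, path) {
  df <- do.call(rbind, lapply(windows, function(w) {
    data.frame(horse = w$horse_id %||% NA, gait = w$gait,
               speed = w$speed %||% NA, start_s = w$start, end_s = w$end)
  }))
  write_num_csv(df, path)
  invisible(path)
}

#' Serialize a dataset bundle to a directory of CSV/JSON files
#'
#' Channel order, sample order and all values round-trip bit-exactly.
#'
#' @param bundle a finalized `dataset_bundle`.
#' @param dir output directory.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(horses = bundle$horses, seed = bundle$seed)
  jsonlite::write_json(meta, file.path(dir, "bundle.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  bdf <- do.call(rbind, lapply(names(bundle$bounds), function(sec) {
    b <- bundle$bounds[[sec]]
    data.frame(section = sec,
               channel = rownames(b) %||% as.character(seq_len(nrow(b))),
               min = b[, "min"], max = b[, "max"])
  }))
  write_num_csv(bdf, file.path(dir, "bounds.csv"))
  for (subset in c("train", "val", "test")) {
    ss <- bundle[[subset]]
    if (length(ss) == 0) next
    mat_rows <- list(); meta_rows <- list()
    for (i in seq_along(ss)) {
      s <- ss[[i]]
      inp <- data.frame(sample = i, kind = "input",
                        channel = rownames(s$input))
      crv <- data.frame(sample = i, kind = "curve", channel = grf_limbs())
      mat_rows[[i]] <- cbind(rbind(inp, crv), rbind(s$input, s$curve))
      meta_rows[[i]] <- data.frame(
        sample = i, horse_id = s$meta$horse_id, gait = s$meta$gait,
        speed = s$meta$speed, start = s$meta$start, end = s$meta$end,
        peak_LF = s$peak[1], peak_RF = s$peak[2], peak_LH = s$peak[3],
        peak_RH = s$peak[4], pt_LF = s$peak_time[1], pt_RF = s$peak_time[2],
        pt_LH = s$peak_time[3], pt_RH = s$peak_time[4],
        sf_lo_LF = s$stance_frac[1, 1], sf_hi_LF = s$stance_frac[1, 2],
        sf_lo_RF = s$stance_frac[2, 1], sf_hi_RF = s$stance_frac[2, 2],
        sf_lo_LH = s$stance_frac[3, 1], sf_hi_LH = s$stance_frac[3, 2],
        sf_lo_RH = s$stance_frac[4, 1], sf_hi_RH = s$stance_frac[4, 2])
    }
    M <- do.call(rbind, mat_rows)
    names(M)[-(1:3)] <- paste0("v", seq_len(ncol(M) - 3))
    write_num_csv(M, file.path(dir, paste0(subset, "_matrices.csv")))
    write_num_csv(do.call(rbind, meta_rows),
                  file.path(dir, paste0(subset, "_meta.csv")))
  }
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "bundle.json"),
                              simplifyVector = TRUE)
  bdf <- utils::read.csv(file.path(dir, "bounds.csv"))
  bounds <- lapply(split(bdf, bdf$section), function(d) {
    m <- cbind(min = d$min, max = d$max)
    rownames(m) <- d$channel
    m
  })
  bounds <- bounds[c("input", "curve", "peak")]
  class(bounds) <- "norm_bounds"
  out <- list(horses = meta$horses, seed = meta$seed, bounds = bounds)
  for (subset in c("train", "val", "test")) {
    fm <- file.path(dir, paste0(subset, "_matrices.csv"))
    if (!file.exists(fm)) { out[[subset]] <- list(); next }
    M <- utils::read.csv(fm, check.names = FALSE)
    S <- utils::read.csv(file.path(dir, paste0(subset, "_meta.csv")))
    out[[subset]] <- lapply(S$sample, function(i) {
      mi <- M[M$sample == i, ]
      inp <- as.matrix(mi[mi$kind == "input", -(1:3)])
      rownames(inp) <- mi$channel[mi$kind == "input"]
      dimnames(inp)[[2]] <- NULL
      crv <- as.matrix(mi[mi$kind == "curve", -(1:3)])
      rownames(crv) <- grf_limbs()
      dimnames(crv)[[2]] <- NULL
      r <- S[S$sample == i, ]
      sf <- rbind(c(r$sf_lo_LF, r$sf_hi_LF), c(r$sf_lo_RF, r$sf_hi_RF),
                  c(r$sf_lo_LH, r$sf_hi_LH), c(r$sf_lo_RH, r$sf_hi_RH))
      rownames(sf) <- grf_limbs()
      structure(list(
        input = inp, curve = crv, stance_frac = sf,
        peak = c(r$peak_LF, r$peak_RF, r$peak_LH, r$peak_RH),
        peak_time = c(r$pt_LF, r$pt_RF, r$pt_LH, r$pt_RH),
        single_peak = rep(NA, 4),
        meta = list(horse_id = r$horse_id, gait = r$gait, speed = r$speed,
                    start = r$start, end = r$end)), class = "stride_sample")
    })
  }
  class(out) <- "dataset_bundle"
  out
}

#' Save / load a trained predictor as JSON (weights, config, bounds)
#'
#' @param predictor a `grfz_predictor`.
#' @param path JSON file path.
#' @export
write_predictor <- function(predictor, path) {
  obj <- list(config = unclass(predictor$config),
              n_input_channels = predictor$n_input_channels,
              n_outputs = predictor$n_outputs,
              best_epoch = predictor$best_epoch,
              history = predictor$history,
              params = predictor$params,
              bounds = if (!is.null(predictor$bounds)) {
                lapply(predictor$bounds, function(b) {
                  list(channel = rownames(b), min = b[, "min"], max = b[, "max"])
                })
              })
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_predictor
#' @export
read_predictor <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(model_config, obj$config[c("n_layers", "bidirectional",
                                            "hidden_units", "dropout_p",
                                            "head")])
  params <- lapply(obj$params, function(p) {
    if (is.matrix(p)) p else as.numeric(p)
  })
  bounds <- NULL
  if (!is.null(obj$bounds)) {
    bounds <- lapply(obj$bounds, function(b) {
      m <- cbind(min = b$min, max = b$max); rownames(m) <- b$channel; m
    })
    class(bounds) <- "norm_bounds"
  }
  structure(list(params = params, config = cfg,
                 n_input_channels = obj$n_input_channels,
                 n_outputs = obj$n_outputs, best_epoch = obj$best_epoch,
                 history = obj$history, bounds = bounds),
            class = "grfz_predictor")
}
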