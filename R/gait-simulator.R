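#' Describe one horse of the simulated population
#'
#' @param horse_id identifier string.
#' @param body_mass body mass in kg (population default ~ Normal(526, 32)).
#' @param stride_freq_scale dimensionless multiplier applied to the gait's
#'   nominal stride duration (values > 1 shorten the stride).
#' @param asymmetry_front,asymmetry_hind left/right peak-force ratio
#'   perturbations for the front and hind pairs; must lie in (0.8, 1.2).
#'   Setting the front ratio to `r` makes the left-front peak `r` times the
#'   right-front peak, so the Robinson symmetry index of the truth peaks is
#'   exactly `2 (r - 1) / (r + 1) * 100`.
#' @param rng_seed integer seed controlling every random draw of this horse's
#'   trials; identical specs produce bit-identical trials.
#' @return An object of class `horse_spec`.
#' @export
horse_spec <- function(horse_id, body_mass = 526, stride_freq_scale = 1,
                       asymmetry_front = 1, asymmetry_hind = 1, rng_seed = 1L) {
  assert_that(body_mass > 0, "body_mass must be positive")
  for (a in c(asymmetry_front, asymmetry_hind)) {
    assert_that(a > 0.8 && a < 1.2, "asymmetry ratios must lie in (0.8, 1.2)")
  }
  assert_that(stride_freq_scale > 0.5 && stride_freq_scale < 2,
              "stride_freq_scale out of plausible range")
  structure(list(horse_id = as.character(horse_id), body_mass = body_mass,
                 stride_freq_scale = stride_freq_scale,
                 asymmetry_front = asymmetry_front,
                 asymmetry_hind = asymmetry_hind,
                 rng_seed = as.integer(rng_seed)),
            class = "horse_spec")
}

#' Draw a simulated study population
#'
#' Body masses follow Normal(526, 32) kg; stride-frequency multipliers and
#' left/right asymmetry ratios are mild individual perturbations around 1
#' (sound horses).
#'
#' @param n number of horses.
#' @param seed integer seed.
#' @return list of [horse_spec()] objects.
#' @export
sample_horses <- function(n, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n), function(i) {
      horse_spec(
        horse_id = sprintf("H%02d", i),
        body_mass = max(300, stats::rnorm(1, 526, 32)),
        stride_freq_scale = stats::rnorm(1, 1, 0.04),
        asymmetry_front = pmin(1.19, pmax(0.81, stats::rnorm(1, 1, 0.03))),
        asymmetry_hind = pmin(1.19, pmax(0.81, stats::rnorm(1, 1, 0.03))),
        rng_seed = sample.int(.Machine$integer.max, 1)
      )
    })
  })
}

#' Gait parameters for a simulated treadmill trial
#'
#' Defaults encode the structure of equine treadmill locomotion at the study
#' speeds: walk (1.7, 1.8 m/s) is a four-beat lateral-sequence gait with
#' footfall order LH-LF-RH-RF, duty factor 0.62 (so at least two hooves are
#' always loaded) and a double-peaked GRFz whose mid-stance dip deepens with
#' speed; trot (3.3-5.0 m/s) is a two-beat diagonal gait, duty factor 0.44,
#' with single-peaked GRFz and synchronous diagonal pairs (LH,RF) and (RH,LF).
#'
#' @param gait `"walk"` or `"trot"`.
#' @param speed treadmill speed in m/s.
#' @param stride_duration stride period in s; default scales weakly with speed
#'   from 1.10 s (walk, 1.7 m/s) and 0.72 s (trot, 3.3 m/s).
#' @param duty_factor stance fraction of the stride per limb.
#' @param footfall_phases named stance-onset phases in `[0, 1)` per limb.
#' @param dip_depth walk-only relative depth of the mid-stance dip in `[0, 1)`;
#'   the default grows with speed and vanishes at low speed.
#' @param peak_front,peak_hind waveform peak amplitudes in N/kg before the
#'   force-balance rescaling of [simulate_trial()].
#' @param walk_minor_ratio ratio of the lower to the higher of the two walk
#'   stance peaks (second peak higher for front limbs, first for hind limbs).
#' @param swing_gyro_amp amplitude of the limb sagittal angular-rate swing
#'   wave, dps.
#' @return Object of class `gait_params`.
#' @export
gait_params <- function(gait, speed = if (gait == "walk") 1.7 else 3.3,
                        stride_duration = NULL, duty_factor = NULL,
                        footfall_phases = NULL, dip_depth = NULL,
                        peak_front = NULL, peak_hind = NULL,
                        walk_minor_ratio = 0.85, swing_gyro_amp = NULL) {
  if (!gait %in% c("walk", "trot")) stopf("unknown gait label '%s'", gait)
  assert_that(speed > 0, "speed must be positive")
  if (gait == "walk") {
    stride_duration <- stride_duration %||% (1.10 * (1.7 / speed)^0.25)
    duty_factor <- duty_factor %||% 0.62
    footfall_phases <- footfall_phases %||%
      c(LH = 0, LF = 0.25, RH = 0.5, RF = 0.75)
    dip_depth <- dip_depth %||% min(0.8, max(0, 0.9 * (speed - 1.1)))
    peak_front <- peak_front %||% (6.4 * (1 + 0.10 * (speed - 1.7)))
    peak_hind <- peak_hind %||% (5.2 * (1 + 0.10 * (speed - 1.7)))
    swing_gyro_amp <- swing_gyro_amp %||% 300
  } else {
    stride_duration <- stride_duration %||% (0.72 * (3.3 / speed)^0.12)
    duty_factor <- duty_factor %||% 0.44
    footfall_phases <- footfall_phases %||%
      c(LH = 0, RF = 0, RH = 0.5, LF = 0.5)
    dip_depth <- 0
    peak_front <- peak_front %||% (10.5 * (1 + 0.06 * (speed - 3.3)))
    peak_hind <- peak_hind %||% (9.3 * (1 + 0.06 * (speed - 3.3)))
    swing_gyro_amp <- swing_gyro_amp %||% 450
  }
  assert_that(duty_factor > 0 && duty_factor < 1, "duty_factor must be in (0,1)")
  assert_that(all(sort(names(footfall_phases)) == sort(grf_limbs())),
              "footfall_phases must name all four limbs")
  assert_that(all(footfall_phases >= 0 & footfall_phases < 1),
              "footfall phases must lie in [0, 1)")
  if (gait == "walk") {
    assert_that(duty_factor > 0.5,
                "walk duty_factor must exceed 0.5 (>= 2 hooves loaded)")
    ord <- names(sort(footfall_phases))
    assert_that(identical(paste(ord, collapse = "-"), "LH-LF-RH-RF"),
                "walk footfall order must be LH-LF-RH-RF")
  } else {
    assert_that(footfall_phases["LH"] == footfall_phases["RF"] &&
                  footfall_phases["RH"] == footfall_phases["LF"],
                "trot diagonal pairs must share stance-onset phases")
  }
  assert_that(dip_depth >= 0 && dip_depth < 0.9, "dip_depth must be in [0, 0.9)")
  structure(list(gait = gait, speed = speed, stride_duration = stride_duration,
                 duty_factor = duty_factor,
                 footfall_phases = footfall_phases[grf_limbs()],
                 dip_depth = dip_depth, peak_front = peak_front,
                 peak_hind = peak_hind, walk_minor_ratio = walk_minor_ratio,
                 swing_gyro_amp = swing_gyro_amp),
            class = "gait_params")
}

#' Dual-range IMU and force-plate sensor model
#'
#' Mirrors the hardware configuration the pipeline expects: each node carries
#' a low-g accelerometer (+-8 g upper body, +-16 g limbs; output clipped at its
#' range), an unclipped-in-practice high-g accelerometer (+-100 / +-200 g) and
#' a +-2000 dps gyroscope, all sampled at 200 Hz; the force plate samples GRFz
#' at 512 Hz on a clock offset from the IMU clock by `clock_offset` seconds.
#'
#' @param low_range_ub,low_range_limb low-g accelerometer ranges, g.
#' @param high_range_ub,high_range_limb high-g accelerometer ranges, g.
#' @param gyro_range gyroscope range, dps.
#' @param imu_rate,grf_rate sampling rates, Hz.
#' @param noise_acc,noise_acc_high,noise_gyro white-noise standard deviations
#'   (g, g, dps) of the low-g, high-g and gyroscope channels.
#' @param gyro_bias_range per-axis gyro bias drawn Uniform(-range, range) dps.
#' @param accel_scale_range accelerometer scale error drawn
#'   Uniform(-range, range), dimensionless.
#' @param grf_noise_sd force-plate noise sd, N/kg (output rectified at zero).
#' @param clock_offset force-plate clock minus IMU clock, s.
#' @param impact_mean,impact_sd per-impact hoof-on transient peak amplitude
#'   distribution (g) on the limb nodes; the default exceeds the 16 g limb
#'   low-g range for most impacts, exercising the dual-range merge.
#' @return Object of class `sensor_model`.
#' @export
sensor_model <- function(low_range_ub = 8, low_range_limb = 16,
                         high_range_ub = 100, high_range_limb = 200,
                         gyro_range = 2000, imu_rate = 200, grf_rate = 512,
                         noise_acc = 0.05, noise_acc_high = 0.2,
                         noise_gyro = 1, gyro_bias_range = 2,
                         accel_scale_range = 0.02, grf_noise_sd = 0.01,
                         clock_offset = 0.1, impact_mean = 20, impact_sd = 4) {
  structure(as.list(environment()), class = "sensor_model")
}

# internal: normalized walk stance shape, peak value exactly 1. A tilted
# sine hump minus a raised-cosine mid-stance dip: with no dip the stance is
# a single smooth hump (the low-speed limit); a growing dip carves out the
# characteristic double peak, tilted so the second peak is higher for front
# limbs and the first for hind limbs (lower-peak/higher-peak ratio ~ minor).
walk_stance_shape <- function(s, limb_role, dip_depth, minor = 0.85) {
  a <- (1 - minor) / (1 + minor) / 0.22
  shape_raw <- function(u) {
    tilt <- if (limb_role == "front") 1 + a * (u - 0.5) else 1 - a * (u - 0.5)
    pmax(sin(pi * u)^1.2 * tilt -
           dip_depth * ifelse(abs(u - 0.5) < 0.25,
                              cos(pi * (u - 0.5) / 0.5)^2, 0), 0)
  }
  peak <- max(shape_raw(seq(0, 1, length.out = 4097)))
  shape_raw(s) / peak
}

#' Normalized-amplitude GRFz stance waveform
#'
#' Walk stances are a tilted sine hump minus a raised-cosine mid-stance dip:
#' at the study speeds this yields the characteristic double peak (second
#' peak higher for front limbs, first higher for hind limbs); the dip
#' shallows as speed (hence `dip_depth`) decreases and the stance collapses
#' to a single smooth hump at low speed. Trot stances are a single raised
#' cosine. Values are zero at both stance boundaries and non-negative
#' throughout; the peak equals `peak_front` / `peak_hind` of `params`.
#'
#' @param gait `"walk"` or `"trot"`.
#' @param limb_role `"front"` or `"hind"`.
#' @param params a [gait_params()] object.
#' @param stance_phase_grid monotone vector of normalized stance time in
#'   `[0, 1]`.
#' @return Numeric force trace in N/kg on `stance_phase_grid`.
#' @export
make_grfz_waveform <- function(gait, limb_role, params,
                               stance_phase_grid = seq(0, 1, length.out = 201)) {
  if (!gait %in% c("walk", "trot")) stopf("unknown gait label '%s'", gait)
  assert_that(limb_role %in% c("front", "hind"), "limb_role must be front/hind")
  s <- stance_phase_grid
  assert_that(all(s >= 0 & s <= 1), "stance_phase_grid must lie in [0, 1]")
  assert_that(all(diff(s) >= 0), "stance_phase_grid must be monotone")
  amp <- if (limb_role == "front") params$peak_front else params$peak_hind
  if (gait == "walk") {
    amp * walk_stance_shape(s, limb_role, params$dip_depth, params$walk_minor_ratio)
  } else {
    amp * sin(pi * s)^2
  }
}

#' Upper-body vertical acceleration implied by the limb forces
#'
#' A body-mounted node approximately senses a weighted share of the total
#' mass-normalized limb support: `a_z(t) = w_f (GRFz_LF + GRFz_RF) +
#' w_h (GRFz_LH + GRFz_RH) - g`. The weights must satisfy the static
#' mass-share convention `w_f phi_f + w_h phi_h = 1` (default front share
#' `phi_f = 0.57`) so that a standing horse has zero acceleration. Withers
#' weights tilt toward the front pair, sacrum toward the hind pair; the head
#' uses the withers mix plus a low-frequency head-bob added by the simulator.
#'
#' @param grfz n x 4 matrix of limb GRFz (N/kg) in LF, RF, LH, RH order.
#' @param node `"head"`, `"withers"` or `"sacrum"` (used for defaults only).
#' @param weights `c(w_f, w_h)`; defaults per node.
#' @param front_share static front-pair weight share `phi_f`.
#' @return Vertical acceleration trace, m/s^2 (0 when standing, -g in free
#'   fall).
#' @export
upper_body_accel_from_grfz <- function(grfz, node = "withers", weights = NULL,
                                       front_share = 0.57) {
  assert_that(is.matrix(grfz) && ncol(grfz) == 4, "grfz must be an n x 4 matrix")
  assert_that(node %in% c("head", "withers", "sacrum"), "unknown node '%s'", node)
  weights <- weights %||% upper_body_weights(node, front_share)
  phi_h <- 1 - front_share
  assert_that(abs(weights[1] * front_share + weights[2] * phi_h - 1) < 1e-8,
              "weights must satisfy the static mass-share convention")
  g <- grf_gravity()
  weights[1] * (grfz[, 1] + grfz[, 2]) + weights[2] * (grfz[, 3] + grfz[, 4]) - g
}

# internal: default front/hind mixing weights per upper-body node
upper_body_weights <- function(node, front_share = 0.57) {
  phi_h <- 1 - front_share
  switch(node,
    withers = c(1.3, (1 - 1.3 * front_share) / phi_h),
    head = c(1.3, (1 - 1.3 * front_share) / phi_h),
    sacrum = c((1 - 1.6 * phi_h) / front_share, 1.6),
    stopf("unknown node '%s'", node))
}

# internal: gaussian impact transient centred on each hoof-on
impact_train <- function(t, on_times, amps, sigma = 0.006) {
  out <- numeric(length(t))
  for (i in seq_along(on_times)) {
    idx <- which(abs(t - on_times[i]) < 5 * sigma)
    out[idx] <- out[idx] + amps[i] * exp(-((t[idx] - on_times[i])^2) / (2 * sigma^2))
  }
  out
}

#' Noise-free limb-node IMU signature for a sequence of hoof events
#'
#' The sagittal angular-rate channel is near zero in stance and carries one
#' biphasic protraction/retraction wave per swing; the vertical acceleration
#' carries gravity, a smooth stride-periodic component and a short Gaussian
#' transient at each hoof-on whose peak can exceed the low-g range.
#'
#' @param t time grid, s.
#' @param events list with `on` and `off` vectors (s), strictly alternating.
#' @param params [gait_params()].
#' @param sensor [sensor_model()].
#' @param impact_amps per-impact transient amplitudes in g (default: drawn
#'   from the sensor model outside this function; here defaults to
#'   `impact_mean` for every impact).
#' @param envelope locomotion envelope (scalar or vector on `t`) gating the
#'   stride-periodic components.
#' @return list with `accel` (n x 3, g) and `gyro` (n x 3, dps) truth traces.
#' @export
limb_imu_waveform <- function(t, events, params, sensor,
                              impact_amps = NULL, envelope = 1) {
  on <- events$on; off <- events$off
  assert_that(length(on) > 0, "no hoof events supplied")
  m <- min(length(on), length(off))
  assert_that(all(on[seq_len(m)] < off[seq_len(m)]) &&
                (m < 2 || all(off[seq_len(m - 1)] < on[2:m])),
              "events must alternate")
  impact_amps <- impact_amps %||% rep(sensor$impact_mean, length(on))
  Tbar <- params$stride_duration
  u <- 2 * pi * t / Tbar
  gyr_y <- 5 * sin(u) * envelope          # small stance-phase residual
  acc_x <- numeric(length(t))
  # biphasic swing wave per swing interval (off_i -> on_{i+1})
  for (i in seq_along(off)) {
    nxt <- on[on > off[i]]
    if (length(nxt) == 0) break
    sw <- c(off[i], nxt[1])
    idx <- which(t >= sw[1] & t <= sw[2])
    s <- (t[idx] - sw[1]) / diff(sw)
    gyr_y[idx] <- gyr_y[idx] + params$swing_gyro_amp * sin(2 * pi * s)
    acc_x[idx] <- acc_x[idx] + 0.5 * sin(2 * pi * s)
  }
  imp <- impact_train(t, on, impact_amps)
  acc <- cbind(acc_x + 0.4 * imp,
               0.05 * sin(u + 0.7) * envelope,
               1 + 0.35 * sin(u) * envelope + imp)
  gyr <- cbind(8 * sin(u + 0.4) * envelope, gyr_y, 6 * sin(u + 1.3) * envelope)
  colnames(acc) <- c("acc_x", "acc_y", "acc_z")
  colnames(gyr) <- c("gyr_x", "gyr_y", "gyr_z")
  list(accel = acc, gyro = gyr)
}

# internal: per-limb force trace from stance tables; amps named by limb
force_from_stances <- function(t, stances, amps, gait, params) {
  F <- matrix(0, length(t), 4, dimnames = list(NULL, grf_limbs()))
  for (limb in grf_limbs()) {
    role <- if (limb %in% c("LF", "RF")) "front" else "hind"
    tab <- stances[[limb]]
    for (k in seq_len(nrow(tab))) {
      idx <- which(t >= tab$on[k] & t <= tab$off[k])
      if (!length(idx)) next
      s <- (t[idx] - tab$on[k]) / (tab$off[k] - tab$on[k])
      shape <- if (gait == "walk") {
        walk_stance_shape(s, role, params$dip_depth, params$walk_minor_ratio)
      } else sin(pi * s)^2
      F[idx, limb] <- F[idx, limb] + amps[limb] * shape
    }
  }
  F
}

#' Simulate one treadmill trial
#'
#' Generates a full trial: a standstill calibration segment, a short
#' transition, and steady-state locomotion with jittered stride periods.
#' Per-limb waveform amplitudes are rescaled so that over interior strides the
#' front pair carries `front_share` and the hind pair the remainder of body
#' weight, making the time-average of the summed GRFz exactly g = 9.81 N/kg
#' (force balance). Upper-body vertical accelerations are the weighted limb
#' force combinations of [upper_body_accel_from_grfz()]; limb nodes carry the
#' [limb_imu_waveform()] signature. Sensor streams are then corrupted with the
#' `sensor` model's bias, scale error, noise, range clipping and clock offset;
#' noise-free truth channels are stored alongside for recovery tests.
#'
#' @param horse [horse_spec()].
#' @param gait_params [gait_params()].
#' @param sensor [sensor_model()].
#' @param duration total trial duration, s (>= standstill + 2 strides).
#' @param standstill standstill length at the start, s (>= 10 by default
#'   protocol; shorter values are allowed for reduced test fixtures).
#' @param front_share static front-pair weight share.
#' @param jitter_sd stride-period jitter sd (fraction of the stride).
#' @return Object of class `trial_recording`.
#' @export
simulate_trial <- function(horse, gait_params, sensor = sensor_model(),
                           duration = 30, standstill = 10, front_share = 0.57,
                           jitter_sd = 0.015) {
  p <- gait_params
  g <- grf_gravity()
  T0 <- p$stride_duration / horse$stride_freq_scale
  # reject duty/phase combinations yielding zero-support instants at walk
  if (p$gait == "walk") {
    ph <- seq(0, 1, by = 0.001)
    support <- vapply(ph, function(x) {
      sum(vapply(p$footfall_phases, function(q) {
        d <- (x - q) %% 1
        d < p$duty_factor
      }, logical(1)))
    }, numeric(1))
    if (min(support) < 2) {
      stopf("walk duty/phase combination leaves < 2 limbs loaded at some instants")
    }
  }

  withr::with_seed(horse$rng_seed, {
    t_lead <- standstill + 0.5
    max_off_phase <- max(p$footfall_phases) + p$duty_factor
    # jittered stride periods
    starts <- t_lead; periods <- numeric(0)
    repeat {
      Tk <- T0 * (1 + max(-0.04, min(0.04, stats::rnorm(1, 0, jitter_sd))))
      if (starts[length(starts)] + max_off_phase * Tk > duration) break
      periods <- c(periods, Tk)
      starts <- c(starts, starts[length(starts)] + Tk)
    }
    n_strides <- length(periods)
    assert_that(n_strides >= 2,
                "duration too short: fewer than 2 complete strides")

    stances <- stats::setNames(lapply(grf_limbs(), function(limb) {
      on <- starts[seq_len(n_strides)] + p$footfall_phases[limb] * periods
      data.frame(on = on, off = on + p$duty_factor * periods)
    }), grf_limbs())

    # provisional amplitudes with left/right asymmetry
    amps0 <- c(LF = p$peak_front * horse$asymmetry_front, RF = p$peak_front,
               LH = p$peak_hind * horse$asymmetry_hind, RH = p$peak_hind)

    t_grf <- seq(0, duration, by = 1 / sensor$grf_rate)
    t_imu <- seq(0, duration, by = 1 / sensor$imu_rate)
    env_of <- function(t) pmin(1, pmax(0, (t - standstill) / (t_lead - standstill)))

    F0 <- force_from_stances(t_grf, stances, amps0, p$gait, p)
    # balance window: interior strides
    bw <- if (n_strides >= 4) c(starts[2], starts[n_strides]) else
      c(starts[1], starts[n_strides + 1])
    win <- t_grf >= bw[1] & t_grf < bw[2]
    mean_front <- mean(F0[win, "LF"] + F0[win, "RF"])
    mean_hind <- mean(F0[win, "LH"] + F0[win, "RH"])
    alpha_f <- front_share * g / mean_front
    alpha_h <- (1 - front_share) * g / mean_hind
    amps <- amps0 * c(alpha_f, alpha_f, alpha_h, alpha_h)

    static <- c(LF = front_share * g / 2, RF = front_share * g / 2,
                LH = (1 - front_share) * g / 2, RH = (1 - front_share) * g / 2)
    force_on <- function(t) {
      Fw <- force_from_stances(t, stances, amps, p$gait, p)
      Fw + outer(1 - env_of(t), static)
    }
    F_grf <- force_on(t_grf)      # truth GRFz on the force-plate grid
    F_imu <- force_on(t_imu)      # truth GRFz on the IMU grid

    env_imu <- env_of(t_imu)
    Tbar <- mean(periods)
    u <- 2 * pi * (t_imu - t_lead) / Tbar

    node_truth <- list()
    for (node in c("head", "withers", "sacrum")) {
      w <- upper_body_weights(node, front_share)
      az <- upper_body_accel_from_grfz(F_imu, node, w, front_share)
      if (node == "head") az <- az + 0.25 * sin(2 * pi * 0.35 * t_imu) * env_imu
      fac <- switch(node, head = 1.4, withers = 1, sacrum = 1.2)
      dphi <- switch(node, head = 0.9, withers = 0, sacrum = 0.45)
      acc <- cbind(0.05 * sin(u + 0.3 + dphi) * env_imu,
                   0.04 * sin(2 * u + 1.0 + dphi) * env_imu,
                   (az + g) / g)
      gyr <- fac * cbind(12 * sin(u + 0.3 + dphi), 18 * sin(2 * u + dphi),
                         8 * sin(u + 1.1 + dphi)) * env_imu
      colnames(acc) <- c("acc_x", "acc_y", "acc_z")
      colnames(gyr) <- c("gyr_x", "gyr_y", "gyr_z")
      node_truth[[node]] <- list(accel = acc, gyro = gyr, weights = w)
    }
    for (limb in grf_limbs()) {
      ev <- list(on = stances[[limb]]$on, off = stances[[limb]]$off)
      amps_imp <- pmax(2, stats::rnorm(length(ev$on), sensor$impact_mean,
                                       sensor$impact_sd))
      node_truth[[limb]] <- limb_imu_waveform(t_imu, ev, p, sensor,
                                              impact_amps = amps_imp,
                                              envelope = env_imu)
    }

    # corrupt sensor channels
    biases <- list(); scales <- list(); nodes <- list()
    for (node in grf_nodes()) {
      is_limb <- node %in% grf_limbs()
      lo_rng <- if (is_limb) sensor$low_range_limb else sensor$low_range_ub
      hi_rng <- if (is_limb) sensor$high_range_limb else sensor$high_range_ub
      b <- stats::runif(3, -sensor$gyro_bias_range, sensor$gyro_bias_range)
      sc <- stats::runif(1, -sensor$accel_scale_range, sensor$accel_scale_range)
      biases[[node]] <- b; scales[[node]] <- sc
      tru <- node_truth[[node]]
      n <- nrow(tru$accel)
      noisy <- (1 + sc) * tru$accel
      acc_low <- pmin(pmax(noisy + matrix(stats::rnorm(3 * n, 0, sensor$noise_acc),
                                          n, 3), -lo_rng), lo_rng)
      acc_high <- pmin(pmax(noisy + matrix(stats::rnorm(3 * n, 0,
                                                        sensor$noise_acc_high),
                                           n, 3), -hi_rng), hi_rng)
      gyr <- pmin(pmax(sweep(tru$gyro, 2, b, "+") +
                         matrix(stats::rnorm(3 * n, 0, sensor$noise_gyro), n, 3),
                       -sensor$gyro_range), sensor$gyro_range)
      dimnames(acc_low) <- dimnames(acc_high) <- list(NULL, colnames(tru$accel))
      dimnames(gyr) <- list(NULL, colnames(tru$gyro))
      nodes[[node]] <- list(acc_low = acc_low, acc_high = acc_high, gyro = gyr)
    }

    # force-plate stream on its own (offset) clock, mass-normalized N/kg
    grf_meas <- pmax(F_grf + matrix(stats::rnorm(length(F_grf), 0,
                                                 sensor$grf_noise_sd),
                                    nrow(F_grf), 4), 0)
    # motion-capture surrogate, hardware-synced to the force plate clock
    omc_mag <- sqrt(rowSums(node_truth$withers$gyro^2)) +
      stats::rnorm(length(t_imu), 0, 0.2)

    events <- stats::setNames(lapply(grf_limbs(), function(limb) {
      list(on = stances[[limb]]$on, off = stances[[limb]]$off)
    }), grf_limbs())

    structure(list(
      horse = horse, gait_params = p, sensor = sensor,
      t_imu = t_imu, nodes = nodes,
      grfz = list(t = t_grf + sensor$clock_offset, force = grf_meas),
      omc = list(t = t_imu + sensor$clock_offset, ang_mag = omc_mag),
      events = events, standstill = c(0, standstill),
      duration = duration,
      truth = list(t_grf = t_grf, grfz = F_grf, grfz_imu = F_imu,
                   nodes = node_truth, gyro_bias = biases,
                   accel_scale = scales, clock_offset = sensor$clock_offset,
                   amps = amps, stride_starts = starts, periods = periods,
                   t_lead = t_lead, balance_window = bw,
                   front_share = front_share)
    ), class = "trial_recording")
  })
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> horse %s, %s @ %.1f m/s, %.0f s, %d strides\n",
              x$horse$horse_id, x$gait_params$gait, x$gait_params$speed,
              x$duration, length(x$truth$periods)))
  invisible(x)
}
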