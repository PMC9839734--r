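#' Merge dual-range accelerometer channels
#'
#' The low-g accelerometer saturates at hoof impact; the high-g channel is
#' used only around those saturated regions. Per axis and per sample the
#' merged output is the low-g value where its absolute value is below the
#' threshold and the high-g value otherwise; no smoothing or blending is
#' applied. The per-sample source flag is `"high"` exactly where
#' `|low| >= threshold`.
#'
#' @param low,high n x 3 acceleration matrices in g, sharing timestamps.
#' @param threshold switch threshold in g (default 8).
#' @return list of class `merged_acceleration` with `accel` (n x 3) and
#'   `source` (n x 3 character matrix, `"low"`/`"high"`).
#' @export
merge_low_high_g <- function(low, high, threshold = 8) {
  low <- as.matrix(low); high <- as.matrix(high)
  assert_that(all(dim(low) == dim(high)), "low and high must share dimensions")
  use_high <- abs(low) >= threshold
  merged <- ifelse(use_high, high, low)
  structure(list(accel = merged,
                 source = ifelse(use_high, "high", "low"),
                 threshold = threshold),
            class = "merged_acceleration")
}

#' Estimate the gyroscope bias from a standstill segment
#'
#' The bias is the per-axis mean over the standstill interval; compensation is
#' subtraction everywhere.
#'
#' @param t timestamps, s.
#' @param gyro n x 3 angular-rate matrix, dps.
#' @param standstill `c(start, end)` interval within the trace, s.
#' @param min_duration minimum accepted interval length, s (warning below).
#' @return numeric length-3 bias, dps.
#' @export
estimate_gyro_bias <- function(t, gyro, standstill, min_duration = 10) {
  idx <- which(t >= standstill[1] & t <= standstill[2])
  assert_that(length(idx) > 0, "standstill interval contains no samples")
  if (diff(standstill) < min_duration) {
    warning(sprintf("standstill interval shorter than %g s", min_duration))
  }
  colMeans(as.matrix(gyro)[idx, , drop = FALSE])
}

#' Calibrate the accelerometer scale against gravity
#'
#' During standstill the acceleration vector should read exactly 1 g of
#' gravity; the scale factor is the reciprocal of the magnitude of the mean
#' measured vector over the interval, so that the calibrated standstill
#' gravity reading equals 1 g. (Averaging the vector before taking the
#' magnitude avoids the upward noise-rectification bias of averaging
#' per-sample magnitudes; the orientation is constant at standstill.)
#'
#' @inheritParams estimate_gyro_bias
#' @param accel n x 3 acceleration matrix, g.
#' @return scalar scale factor.
#' @export
calibrate_accel_scale <- function(t, accel, standstill, min_duration = 10) {
  idx <- which(t >= standstill[1] & t <= standstill[2])
  assert_that(length(idx) > 0, "standstill interval contains no samples")
  if (diff(standstill) < min_duration) {
    warning(sprintf("standstill interval shorter than %g s", min_duration))
  }
  m <- sqrt(sum(colMeans(as.matrix(accel)[idx, , drop = FALSE])^2))
  if (m < 0.5) stopf("standstill magnitude %.2f g: not at rest or wrong units", m)
  1 / m
}

#' Synchronize a sensor stream to a reference by angular-velocity magnitude
#'
#' Estimates the clock offset between two streams as the lag maximizing the
#' normalized cross-correlation of their (rotation-invariant) angular-velocity
#' magnitude signals on a common uniform grid, then shifts the target stream
#' timestamps by the offset and linearly resamples any attached target traces
#' onto the reference time base.
#'
#' @param ref_t,ref_mag reference timestamps (s) and magnitude trace.
#' @param tgt_t,tgt_mag target-stream timestamps and magnitude trace; the
#'   target clock is assumed to read `reference clock + offset`.
#' @param targets named list of traces `list(t =, x =)` on the target clock
#'   (`x` may be a matrix) to be shifted and resampled onto `ref_t`.
#' @param max_lag search half-width, s.
#' @param min_corr minimum accepted correlation peak (rejected below).
#' @return list with `offset` (s), `corr` (peak correlation) and `targets`
#'   (each now `list(t = ref_t, x = resampled)`).
#' @export
synchronize_streams <- function(ref_t, ref_mag, tgt_t, tgt_mag,
                                targets = list(), max_lag = 0.5,
                                min_corr = 0.5) {
  dt <- stats::median(diff(ref_t))
  grid <- seq(max(min(ref_t), min(tgt_t) - max_lag),
              min(max(ref_t), max(tgt_t) + max_lag), by = dt)
  r <- interp1(ref_t, ref_mag, grid)
  L <- ceiling(max_lag / dt)
  lags <- -L:L
  cors <- vapply(lags, function(k) {
    # candidate offset k*dt: target values at grid + k*dt align with reference
    tv <- stats::approx(tgt_t, tgt_mag, xout = grid + k * dt, rule = 1)$y
    ok <- !is.na(tv)
    if (sum(ok) < 10 || stats::sd(tv[ok]) == 0 || stats::sd(r[ok]) == 0) {
      return(-Inf)
    }
    stats::cor(r[ok], tv[ok])
  }, numeric(1))
  best <- which.max(cors)
  if (!is.finite(cors[best]) || cors[best] < min_corr) {
    stopf("streams unsyncable: correlation peak %.2f below %.2f",
          max(cors[is.finite(cors)], -1), min_corr)
  }
  offset <- lags[best] * dt
  out_targets <- lapply(targets, function(tr) {
    x <- tr$x
    if (is.matrix(x)) {
      xr <- apply(x, 2, function(col) interp1(tr$t - offset, col, ref_t))
    } else {
      xr <- interp1(tr$t - offset, x, ref_t)
    }
    list(t = ref_t, x = xr)
  })
  list(offset = offset, corr = cors[best], targets = out_targets)
}

#' Normalize a force trace by body mass
#'
#' @param force force trace in N (or already N/kg with `body_mass = 1`).
#' @param body_mass body mass, kg (> 0).
#' @return trace in N/kg.
#' @export
normalize_grfz_by_mass <- function(force, body_mass) {
  assert_that(is.numeric(body_mass) && length(body_mass) == 1 && body_mass > 0,
              "body_mass must be a positive scalar")
  force / body_mass
}

#' Run the full sensor-conditioning chain on a trial
#'
#' Per node: merge the dual-range accelerations at the threshold, estimate the
#' gyro bias and accelerometer scale from the standstill segment, and apply
#' them. Then synchronize the force-plate stream to the IMU clock by
#' cross-correlating angular-velocity magnitudes (the withers node against the
#' motion-capture surrogate hardware-synced to the force plate), resampling
#' GRFz onto the IMU time base. No filtering is applied anywhere in the chain.
#'
#' @param trial a `trial_recording`.
#' @param threshold dual-range merge threshold, g.
#' @param max_lag synchronization search half-width, s.
#' @return the trial with a `proc` element: `t`, per-node calibrated `acc`
#'   (merged, g) and `gyro` (bias-compensated, dps), `grfz` (n x 4 N/kg on the
#'   IMU time base), `offset` and per-node `calib`.
#' @export
process_trial <- function(trial, threshold = 8, max_lag = 0.5) {
  ss <- trial$standstill
  t <- trial$t_imu
  nodes <- list(); calib <- list()
  for (node in grf_nodes()) {
    raw <- trial$nodes[[node]]
    mg <- merge_low_high_g(raw$acc_low, raw$acc_high, threshold)
    scale <- calibrate_accel_scale(t, mg$accel, ss, min_duration = diff(ss))
    bias <- estimate_gyro_bias(t, raw$gyro, ss, min_duration = diff(ss))
    nodes[[node]] <- list(acc = mg$accel * scale,
                          gyro = sweep(raw$gyro, 2, bias, "-"),
                          source = mg$source)
    calib[[node]] <- list(gyro_bias = bias, accel_scale = scale,
                          estimated_from = ss)
  }
  ref_mag <- sqrt(rowSums(nodes$withers$gyro^2))
  sync <- synchronize_streams(t, ref_mag, trial$omc$t, trial$omc$ang_mag,
                              targets = list(grfz = list(t = trial$grfz$t,
                                                         x = trial$grfz$force)),
                              max_lag = max_lag)
  grfz <- sync$targets$grfz$x
  colnames(grfz) <- grf_limbs()
  trial$proc <- list(t = t, nodes = nodes, grfz = grfz,
                     offset = sync$offset, sync_corr = sync$corr,
                     calib = calib)
  trial
}
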