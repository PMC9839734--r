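test_that("walk stance waveform has the canonical double-peak structure", {
  p <- gait_params("walk", 1.7)
  s <- seq(0, 1, length.out = 513)
  for (role in c("front", "hind")) {
    y <- make_grfz_waveform("walk", role, p, s)
    expect_equal(y[1], 0)
    expect_equal(y[length(y)], 0)
    expect_true(all(y >= 0))
    loc <- which(diff(sign(diff(y))) < 0) + 1
    loc <- loc[y[loc] > 0.3 * max(y)]
    expect_length(loc, 2)
    if (role == "front") {
      expect_gt(s[which.max(y)], 0.5)  # second peak higher
    } else {
      expect_lt(s[which.max(y)], 0.5)  # first peak higher
    }
    amp <- if (role == "front") p$peak_front else p$peak_hind
    expect_equal(max(y), amp, tolerance = 1e-3)
  }
})

test_that("the mid-stance dip shrinks with speed and vanishes at low speed", {
  s <- seq(0, 1, length.out = 513)
  mid_rel <- vapply(c(1.3, 1.5, 1.7, 1.9), function(v) {
    y <- make_grfz_waveform("walk", "front", gait_params("walk", v), s)
    y[s == 0.5] / max(y)
  }, numeric(1))
  expect_true(all(diff(mid_rel) < 0))  # deeper dip as speed grows
  y0 <- make_grfz_waveform("walk", "front",
                           gait_params("walk", 1.7, dip_depth = 0), s)
  loc <- which(diff(sign(diff(y0))) < 0) + 1
  expect_length(loc[y0[loc] > 0.3 * max(y0)], 1)  # single smooth hump
})

test_that("trot stance waveform is a single lobe, zero at both ends", {
  p <- gait_params("trot", 4.0)
  s <- seq(0, 1, length.out = 257)
  y <- make_grfz_waveform("trot", "front", p, s)
  expect_equal(y[1], 0)
  expect_equal(y[length(y)], 0)
  loc <- which(diff(sign(diff(y))) < 0) + 1
  expect_length(loc, 1)
  expect_equal(max(y), p$peak_front, tolerance = 1e-9)
  expect_error(make_grfz_waveform("canter", "front", p, s), "unknown gait")
})

test_that("gait parameter invariants are enforced", {
  expect_error(gait_params("walk", duty_factor = 0.45), "duty_factor")
  expect_error(gait_params("walk", footfall_phases =
                             c(LH = 0, RH = 0.25, LF = 0.5, RF = 0.75)),
               "LH-LF-RH-RF")
  expect_error(gait_params("trot", footfall_phases =
                             c(LH = 0, RF = 0.1, RH = 0.5, LF = 0.5)),
               "diagonal")
  expect_error(horse_spec("x", asymmetry_front = 1.4), "asymmetry")
  expect_error(horse_spec("x", body_mass = -1), "body_mass")
})

test_that("simulated trials satisfy force balance within 1%", {
  for (gait in c("walk", "trot")) {
    tr <- fix_trial(gait)
    bw <- tr$truth$balance_window
    idx <- tr$truth$t_grf >= bw[1] & tr$truth$t_grf < bw[2]
    total <- mean(rowSums(tr$truth$grfz[idx, ]))
    expect_lt(abs(total - grf_gravity()) / grf_gravity(), 0.01)
  }
})

test_that("support patterns match the gait during steady-state locomotion", {
  tr <- fix_trial("walk")
  st <- tr$truth$stride_starts
  loc <- tr$truth$t_grf >= st[2] & tr$truth$t_grf < st[length(st)]
  expect_gte(min(rowSums(tr$truth$grfz[loc, ] > 0)), 2)

  tr <- fix_trial("trot")
  st <- tr$truth$stride_starts
  loc <- which(tr$truth$t_grf >= st[2] & tr$truth$t_grf < st[length(st)])
  loaded <- tr$truth$grfz[loc, ] > 0
  # limb columns are LF RF LH RH; diagonals are (LH,RF) and (RH,LF)
  diag1 <- loaded[, 3] & loaded[, 2] & !loaded[, 4] & !loaded[, 1]
  diag2 <- loaded[, 4] & loaded[, 1] & !loaded[, 3] & !loaded[, 2]
  none <- rowSums(loaded) == 0
  expect_true(all(diag1 | diag2 | none))
})

test_that("identical specifications produce bit-identical trials", {
  h <- horse_spec("H1", rng_seed = 7L)
  t1 <- simulate_trial(h, gait_params("walk"), sensor_model(), duration = 16)
  t2 <- simulate_trial(h, gait_params("walk"), sensor_model(), duration = 16)
  expect_identical(t1, t2)
})

test_that("zero-support walk duty/phase combinations are rejected", {
  p <- gait_params("walk", footfall_phases =
                     c(LH = 0, LF = 0.05, RH = 0.1, RF = 0.15),
                   duty_factor = 0.52)
  expect_error(simulate_trial(horse_spec("H1"), p, sensor_model(),
                              duration = 16),
               "< 2 limbs loaded")
})

test_that("default-length trials contain at least 15 complete strides", {
  tr <- fix_memo("trial_default_len", function() {
    simulate_trial(horse_spec("H9", rng_seed = 9L), gait_params("walk", 1.7),
                   sensor_model(), duration = 30)
  })
  expect_gte(length(tr$truth$periods), 15)
})

test_that("asymmetry injection matches the Robinson SI closed form", {
  r <- 1.1
  h <- horse_spec("H1", asymmetry_front = r, asymmetry_hind = 0.95,
                  rng_seed = 3L)
  tr <- simulate_trial(h, gait_params("walk"), sensor_model(), duration = 20)
  si_expect <- 2 * (r - 1) / (r + 1) * 100
  expect_equal(robinson_si(tr$truth$amps["LF"], tr$truth$amps["RF"]),
               si_expect, tolerance = 1e-9, ignore_attr = TRUE)
  # and via peaks extracted from the truth curves
  pk <- vapply(c("LF", "RF"), function(limb) {
    max(tr$truth$grfz[, limb])
  }, numeric(1))
  expect_equal(robinson_si(pk["LF"], pk["RF"]), si_expect, tolerance = 0.1,
               ignore_attr = TRUE)
})

test_that("truth GRFz is positive exactly within each stance", {
  tr <- fix_trial("trot")
  t <- tr$truth$t_grf
  dt <- 1 / tr$sensor$grf_rate
  for (limb in grf_limbs()) {
    ev <- tr$events[[limb]]
    f <- tr$truth$grfz[, limb]
    for (k in seq_along(ev$on)) {
      inside <- t > ev$on[k] + dt & t < ev$off[k] - dt
      expect_true(all(f[inside] > 0))
    }
    # zero in every swing between consecutive stances
    for (k in seq_len(length(ev$on) - 1)) {
      swing <- t > ev$off[k] + dt & t < ev$on[k + 1] - dt
      expect_true(all(f[swing] == 0))
    }
  }
})

test_that("upper-body vertical acceleration follows the limb forces", {
  g <- grf_gravity()
  z4 <- matrix(0, 10, 4)
  expect_equal(upper_body_accel_from_grfz(z4, "withers"), rep(-g, 10))
  # static equilibrium: canonical shares with convention-satisfying weights
  phi <- 0.57
  static <- matrix(rep(c(phi * g / 2, phi * g / 2, (1 - phi) * g / 2,
                         (1 - phi) * g / 2), each = 10), 10, 4)
  for (node in c("withers", "sacrum", "head")) {
    expect_equal(upper_body_accel_from_grfz(static, node), rep(0, 10),
                 tolerance = 1e-9)
  }
  expect_error(upper_body_accel_from_grfz(z4, "withers", weights = c(1, 0.5)),
               "mass-share")
  # sacrum tracks the hind pair more closely than the front pair
  tr <- fix_trial("walk")
  F <- tr$truth$grfz_imu
  az <- upper_body_accel_from_grfz(F, "sacrum",
                                   tr$truth$nodes$sacrum$weights)
  st <- tr$truth$stride_starts
  loc <- tr$t_imu >= st[2] & tr$t_imu < st[length(st)]
  c_h <- cor(az[loc], F[loc, "LH"] + F[loc, "RH"])
  c_f <- cor(az[loc], F[loc, "LF"] + F[loc, "RF"])
  expect_gt(c_h, c_f)
})

test_that("limb IMU waveforms carry the stance/swing and impact signature", {
  p <- gait_params("walk", 1.7)
  sm <- sensor_model()
  t <- seq(0, 6, by = 1 / sm$imu_rate)
  on <- c(1, 2.1, 3.2, 4.3); off <- on + 0.68
  w <- limb_imu_waveform(t, list(on = on, off = off), p, sm,
                         impact_amps = rep(12, 4))
  gy <- abs(w$gyro[, 2])
  stance <- t >= on[1] + 0.05 & t <= off[1] - 0.05
  swing <- t >= off[1] + 0.02 & t <= on[2] - 0.02
  expect_lt(max(gy[stance]), stats::median(gy[swing]))
  # impact transients recover hoof-on times within 10 ms on noise-free traces
  mag <- sqrt(rowSums(w$accel^2))
  hot <- which(mag > 4)
  cl <- split(hot, cumsum(c(1, diff(hot) > 10)))
  t_est <- vapply(cl, function(ix) t[ix[which.max(mag[ix])]], numeric(1))
  expect_equal(length(t_est), 4)
  expect_lt(max(abs(t_est - on)), 0.010)
})

test_that("low-g channels clip at their range while high-g channels do not", {
  # a 12 g impact clips an 8 g low-g range but is read by the high-g channel
  sm <- sensor_model(low_range_limb = 8, impact_mean = 12, impact_sd = 0,
                     noise_acc = 0, noise_acc_high = 0,
                     accel_scale_range = 0, gyro_bias_range = 0)
  tr <- simulate_trial(horse_spec("H1", rng_seed = 11L),
                       gait_params("trot"), sm, duration = 16)
  expect_equal(max(abs(tr$nodes$LF$acc_low)), 8)
  expect_gt(max(tr$nodes$LF$acc_high), 12)   # the 12 g impact is read in full
  expect_lt(max(tr$nodes$LF$acc_high), 200)  # and never clipped in practice
  # at the default 16 g limb range the default impacts still exceed the range
  tr2 <- fix_trial("walk")
  expect_equal(max(abs(tr2$nodes$LF$acc_low)), 16)
  expect_gt(max(tr2$nodes$LF$acc_high), 16)
  expect_true(all(abs(tr2$nodes$head$acc_low) <= 8))
})

test_that("trials round-trip through the CSV directory format", {
  tr <- fix_trial("trot", duration = 22)
  dir <- tempfile("trial")
  write_trial(tr, dir)
  tr2 <- read_trial(dir)
  expect_equal(tr2$nodes, tr$nodes)
  expect_equal(tr2$grfz, tr$grfz)
  expect_equal(tr2$events, tr$events)
  expect_equal(tr2$truth$grfz, tr$truth$grfz, ignore_attr = TRUE)
  expect_equal(tr2$horse, tr$horse)
  unlink(dir, recursive = TRUE)
})
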