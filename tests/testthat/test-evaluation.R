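test_that("stride RMSE matches its closed forms", {
  x <- sin(seq(0, pi, length.out = 200)) * 6
  expect_equal(stride_rmse(x, x), 0)
  expect_equal(stride_rmse(x + 0.7, x), 0.7, tolerance = 1e-12)
  # full-support raised-cosine lobe vs zero: RMSE = A * sqrt(3/8)
  s <- seq(0, 1, length.out = 20001)
  lobe <- 5 * sin(pi * s)^2
  expect_equal(stride_rmse(lobe, 0 * lobe), 5 * sqrt(3 / 8), tolerance = 1e-3)
  expect_error(stride_rmse(1:5, 1:4), "lengths differ")
})

test_that("stride correlation behaves for both methods", {
  x <- sin(seq(0, 2 * pi, length.out = 200)) + 2
  expect_equal(stride_rho(x, x), 1)
  expect_equal(stride_rho(-x, x), -1)
  # rank invariance under monotone distortion
  expect_equal(stride_rho(x^3, x, method = "spearman"), 1)
  expect_lt(stride_rho(x^3, x), 1)
  expect_warning(r <- stride_rho(rep(1, 10), 1:10), "constant")
  expect_true(is.na(r))
})

test_that("swing-phase zeros cap rank correlation but not Pearson", {
  # even a near-perfect prediction cannot reach rank rho ~ 0.99 when ~40%
  # of the reference stride is identically zero: ties carry no ordering
  withr::with_seed(4, {
    s <- seq(0, 1, length.out = 200)
    ref <- ifelse(s < 0.62, sin(pi * pmin(s / 0.62, 1))^2 * 7, 0)
    pred <- ref + rnorm(200, 0, 1e-4)
    expect_lt(stride_rho(pred, ref, method = "spearman"), 0.98)
    expect_gt(stride_rho(pred, ref, method = "pearson"), 0.9999)
  })
})

test_that("peak extraction returns the walk second peak and trot maximum", {
  s <- seq(0, 1, length.out = 200)
  lobes <- 5.8 * ifelse(abs(s - 0.35) < 0.25, cos(pi * (s - 0.35) / 0.5)^2, 0) +
    6.3 * ifelse(abs(s - 0.65) < 0.25, cos(pi * (s - 0.65) / 0.5)^2, 0)
  pk <- extract_pgrfz(lobes, "walk")
  expect_equal(pk$pgrfz, 6.3, tolerance = 1e-3)
  expect_gt(pk$t_pgrfz, 0.5)
  expect_false(pk$single_peak)
  # the simulator's own front walk waveform: second peak = configured amp
  p <- gait_params("walk", 1.7)
  y <- make_grfz_waveform("walk", "front", p, s)
  pk2 <- extract_pgrfz(y, "walk")
  expect_equal(pk2$pgrfz, p$peak_front, tolerance = 0.005 * p$peak_front)
  # trot: single raised cosine peaks mid-stance at its amplitude
  tro <- 9.4 * sin(pi * s)^2
  pkt <- extract_pgrfz(tro, "trot")
  expect_equal(pkt$pgrfz, 9.4, tolerance = 1e-3)
  expect_equal(pkt$t_pgrfz, 0.5, tolerance = 0.01)
  # dip-free walk stance is flagged as single-peaked
  y0 <- make_grfz_waveform("walk", "front",
                           gait_params("walk", dip_depth = 0), s)
  expect_true(extract_pgrfz(y0, "walk")$single_peak)
  expect_error(extract_pgrfz(rep(0, 200), "walk"), "all-zero")
})

test_that("peak extraction honors the stance-of-interest restriction", {
  s <- seq(0, 1, length.out = 200)
  two <- 8 * sin(pi * pmin(pmax((s - 0.05) / 0.35, 0), 1))^2 +
    7.5 * sin(pi * pmin(pmax((s - 0.60) / 0.35, 0), 1))^2
  free <- extract_pgrfz(two, "trot")
  expect_equal(free$pgrfz, 8, tolerance = 1e-3)
  held <- extract_pgrfz(two, "trot", restrict = c(0.55, 1))
  expect_equal(held$pgrfz, 7.5, tolerance = 1e-3)
  expect_gt(held$t_pgrfz, 0.6)
})

test_that("the Robinson symmetry index follows its definition", {
  expect_equal(robinson_si(5, 5), 0)
  expect_equal(robinson_si(6, 4), 40)
  expect_equal(robinson_si(4, 6), -40)
  # antisymmetry property across random positive pairs
  withr::with_seed(6, {
    a <- runif(50, 1, 10); b <- runif(50, 1, 10)
    expect_equal(robinson_si(a, b), -robinson_si(b, a))
    expect_true(all(abs(robinson_si(a, b)) <= 200))
  })
  expect_error(robinson_si(0, 0), "positive")
})

test_that("Bland-Altman bounds equal bias +- 1.96 STD", {
  ref <- c(10, 11, 12, 13)
  est <- ref + 1
  ba <- bland_altman(ref, est)
  expect_equal(ba$bias, 1)
  expect_equal(ba$std, 0)
  expect_equal(c(ba$lower, ba$upper), c(1, 1))
  # a fixed printed difference list
  d <- c(0.2, -0.1, 0.4, 0.0, -0.3, 0.1)
  ba2 <- bland_altman(rep(0, 6), d)
  expect_equal(ba2$bias, mean(d))
  expect_equal(ba2$std, sd(d))
  expect_equal(ba2$upper, mean(d) + 1.96 * sd(d))
  expect_equal(ba2$lower, mean(d) - 1.96 * sd(d))
  # self-agreement is identically zero
  ba3 <- bland_altman(ref, ref)
  expect_equal(c(ba3$bias, ba3$std, ba3$lower, ba3$upper), rep(0, 4))
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("Bland-Altman limits cover ~95% of Normal differences", {
  withr::with_seed(12, {
    ref <- rnorm(1e5, 10, 1)
    est <- ref + rnorm(1e5, 0, 1)
    ba <- bland_altman(ref, est)
    expect_equal(ba$bias, 0, tolerance = 0.02)
    expect_equal(ba$upper, 1.96, tolerance = 0.03)
    inside <- mean(ba$diffs >= ba$lower & ba$diffs <= ba$upper)
    expect_equal(inside, 0.95, tolerance = 0.005)
  })
})

test_that("evaluating the reference against itself is exact", {
  p <- fix_processed("trot")
  wins <- segment_trial(p, source = "truth")
  samples <- lapply(wins[1:5], build_stride_sample, trial = p,
                    nodes = node_set("Sac"))
  for (s in samples) {
    for (li in 1:4) {
      expect_equal(stride_rmse(s$curve[li, ], s$curve[li, ]), 0)
      expect_equal(stride_rho(s$curve[li, ], s$curve[li, ]), 1)
      pk <- extract_pgrfz(s$curve[li, ], "trot",
                          restrict = s$stance_frac[li, ])
      expect_equal(pk$pgrfz, s$peak[li])
    }
  }
})

test_that("the node-set report has the expected structure", {
  p <- fix_processed("walk")
  wins <- segment_trial(p, source = "truth")
  samples <- list()
  for (hid in sprintf("H%02d", 1:3)) {
    for (w in wins[1:3]) {
      w$horse_id <- hid
      samples[[length(samples) + 1]] <-
        build_stride_sample(w, p, node_set("All"))
    }
  }
  bounds <- compute_bounds(samples)
  fits <- list()
  for (ns in c("All", "UB", "Limbs", "Sac", "Wth")) {
    nsamp <- lapply(samples, function(s) {
      rows <- unlist(lapply(node_set(ns)$nodes, function(nd) {
        paste(nd, c("acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z"),
              sep = ".")
      }))
      s$input <- s$input[rows, , drop = FALSE]
      s
    })
    nb <- compute_bounds(nsamp)
    fc <- build_network(model_config(hidden_units = 4, head = "curve"),
                        nrow(nsamp[[1]]$input), seed = 1)
    fc$bounds <- nb
    fp <- build_network(model_config(hidden_units = 4, head = "peak"),
                        nrow(nsamp[[1]]$input), seed = 1)
    fp$bounds <- nb
    fits[[ns]] <- list(curve = fc, peak = fp, test = nsamp)
  }
  rep <- compare_node_sets(fits)
  expect_equal(nrow(rep$peaks), 5 * 2 * 2)  # node sets x routes x limb pairs
  expect_equal(nrow(rep$si), 5 * 2 * 2)
  expect_setequal(unique(rep$curves$node_set),
                  c("All", "UB", "Limbs", "Sac", "Wth"))
  expect_equal(nrow(rep$medians), 5)
  # untrained heads can leave too few valid peak pairs: those rows are NA
  expect_true(all(rep$peaks$upper >= rep$peaks$lower, na.rm = TRUE))
  expect_equal(nrow(rep$curves), 5 * 9 * 4)  # node sets x strides x limbs
})
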