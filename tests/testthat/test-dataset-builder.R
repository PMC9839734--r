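test_that("fixed-length resampling preserves endpoints, constants and peaks", {
  expect_equal(resample_to_fixed_length(rep(3.2, 57), 200), rep(3.2, 200))
  ramp <- resample_to_fixed_length(seq(0, 1, length.out = 513), 200)
  expect_equal(ramp, seq(0, 1, length.out = 200), tolerance = 1e-9)
  # a raised-cosine stance lobe at 512 Hz keeps its peak within 0.5%
  lobe <- sin(pi * seq(0, 1, length.out = 0.68 * 512))^2 * 7
  expect_equal(max(resample_to_fixed_length(lobe, 200)), 7, tolerance = 0.005)
  expect_error(resample_to_fixed_length(1:10, 1), "at least 2")
  expect_error(resample_to_fixed_length(3, 200), "at least 2")
})

test_that("node sets have the documented membership and channel counts", {
  expect_length(node_set("All")$nodes, 7)
  expect_equal(node_set("UB")$nodes, c("head", "withers", "sacrum"))
  expect_equal(node_set("Limbs")$nodes, grf_limbs())
  expect_equal(node_set("Sac")$nodes, "sacrum")
  expect_equal(node_set("Wth")$nodes, "withers")
  expect_error(node_set("Head"), "arg")
})

test_that("stride samples have the (6 x N nodes) x 200 input layout", {
  p <- fix_processed("walk")
  w <- segment_trial(p, source = "truth")
  s_all <- build_stride_sample(w[[1]], p, node_set("All"))
  expect_equal(dim(s_all$input), c(42, 200))
  expect_equal(dim(s_all$curve), c(4, 200))
  expect_length(s_all$peak, 4)
  s_sac <- build_stride_sample(w[[1]], p, node_set("Sac"))
  expect_equal(dim(s_sac$input), c(6, 200))
  expect_equal(rownames(s_sac$input),
               paste("sacrum", c("acc_x", "acc_y", "acc_z",
                                 "gyr_x", "gyr_y", "gyr_z"), sep = "."))
  ns_bad <- node_set("All"); ns_bad$nodes <- c(ns_bad$nodes, "tail")
  expect_error(build_stride_sample(w[[1]], p, ns_bad), "missing node")
})

test_that("trot curve-target maximum equals the peak target", {
  p <- fix_processed("trot")
  w <- segment_trial(p, source = "truth")
  s <- build_stride_sample(w[[2]], p, node_set("All"))
  for (li in 1:4) expect_equal(s$peak[li], max(s$curve[li, ]))
})

test_that("curve targets are supported on the window's stance intervals", {
  p <- fix_processed("trot")
  w <- segment_trial(p, source = "truth")
  s <- build_stride_sample(w[[2]], p, node_set("Sac"))
  tq <- seq(0, 1, length.out = 200)
  for (li in 1:4) {
    inside <- tq >= s$stance_frac[li, 1] & tq <= s$stance_frac[li, 2]
    # outside the (padded) stance band the reference force is plate noise
    expect_lt(max(s$curve[li, !inside]), 0.2)
    expect_gt(max(s$curve[li, inside]), 5)
  }
})

test_that("horse-wise splits are disjoint, seeded and validated", {
  p <- fix_processed("walk")
  wins <- segment_trial(p, source = "truth")
  samples <- list()
  for (hid in sprintf("H%02d", 1:6)) {
    for (w in wins[1:4]) {
      w$horse_id <- hid
      samples[[length(samples) + 1]] <-
        build_stride_sample(w, p, node_set("Sac"))
    }
  }
  b1 <- split_by_horse(samples, c(4, 1, 1), seed = 9)
  expect_length(intersect(b1$horses$train, b1$horses$val), 0)
  expect_length(intersect(b1$horses$train, b1$horses$test), 0)
  expect_length(intersect(b1$horses$val, b1$horses$test), 0)
  expect_length(b1$horses$train, 4)
  expect_length(b1$train, 16)
  b2 <- split_by_horse(samples, c(4, 1, 1), seed = 9)
  expect_identical(b2$horses, b1$horses)
  expect_error(split_by_horse(samples, c(16, 4, 4), seed = 1),
               "must equal")
})

test_that("min-max normalization is the exact invertible map", {
  p <- fix_processed("walk")
  wins <- segment_trial(p, source = "truth")
  samples <- lapply(wins[1:6], build_stride_sample, trial = p,
                    nodes = node_set("Sac"))
  bounds <- compute_bounds(samples)
  normed <- minmax_normalize(samples, bounds)
  for (s in normed) {
    expect_true(all(s$input >= 0 & s$input <= 1))
    expect_true(all(s$curve >= 0 & s$curve <= 1))
  }
  # round trip
  back <- minmax_denormalize(normed[[1]]$curve, bounds$curve)
  expect_equal(back, samples[[1]]$curve, tolerance = 1e-9)
  # an unseen stride with a larger peak maps above 1, unclipped
  big <- samples[[1]]
  big$curve <- big$curve * 1.5
  nb <- minmax_normalize(list(big), bounds)[[1]]
  expect_gt(max(nb$curve), 1)
  # degenerate channel maps to zero with a warning
  flat <- lapply(samples[1:2], function(s) { s$input[1, ] <- 5; s })
  fb <- compute_bounds(flat)
  expect_warning(nf <- minmax_normalize(flat, fb), "max = min")
  expect_true(all(nf[[1]]$input[1, ] == 0))
})

test_that("dataset bundles round-trip bit-exactly through CSV", {
  p <- fix_processed("walk")
  wins <- segment_trial(p, source = "truth")
  samples <- list()
  for (hid in sprintf("H%02d", 1:3)) {
    for (w in wins[1:2]) {
      w$horse_id <- hid
      samples[[length(samples) + 1]] <-
        build_stride_sample(w, p, node_set("Sac"))
    }
  }
  b <- finalize_bundle(split_by_horse(samples, c(1, 1, 1), seed = 4))
  dir <- tempfile("bundle")
  write_bundle(b, dir)
  b2 <- read_bundle(dir)
  expect_identical(rownames(b2$train[[1]]$input),
                   rownames(b$train[[1]]$input))
  expect_identical(b2$train[[1]]$input, b$train[[1]]$input)
  expect_identical(b2$test[[1]]$curve, b$test[[1]]$curve)
  expect_identical(b2$bounds$input, b$bounds$input)
  expect_equal(b2$train[[1]]$peak, b$train[[1]]$peak)
  unlink(dir, recursive = TRUE)
})
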