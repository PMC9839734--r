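#' IMU node sets used as model inputs
#'
#' `All` = head, withers, sacrum and the four limb nodes (7 nodes, 42 input
#' channels); `UB` = the three upper-body nodes; `Limbs` = the four limb
#' nodes; `Sac` and `Wth` = single nodes.
#'
#' @param name one of `"All"`, `"UB"`, `"Limbs"`, `"Sac"`, `"Wth"`.
#' @return list of class `node_set` with `name` and `nodes`.
#' @export
node_set <- function(name = c("All", "UB", "Limbs", "Sac", "Wth")) {
  name <- match.arg(name)
  nodes <- switch(name,
    All = grf_nodes(),
    UB = c("head", "withers", "sacrum"),
    Limbs = grf_limbs(),
    Sac = "sacrum",
    Wth = "withers")
  structure(list(name = name, nodes = nodes), class = "node_set")
}

#' Resample a trace to a fixed number of samples
#'
#' Linear interpolation onto `n` equally spaced points spanning the input,
#' endpoints preserved.
#'
#' @param signal numeric vector (length >= 2).
#' @param n output length (>= 2, default 200).
#' @return length-`n` numeric vector.
#' @export
resample_to_fixed_length <- function(signal, n = 200) {
  assert_that(n >= 2, "n must be at least 2")
  assert_that(length(signal) >= 2, "signal must have at least 2 samples")
  idx <- seq(1, length(signal), length.out = n)
  stats::approx(seq_along(signal), signal, xout = idx)$y
}

#' Build one stride sample from a window of a processed trial
#'
#' Per node of the node set, the 3 merged calibrated acceleration channels and
#' the 3 bias-compensated angular-rate channels are interpolated onto 200
#' equally spaced points spanning the window and stacked in the frozen node
#' order (head, withers, sacrum, LF, RF, LH, RH), 6 rows per node. The
#' per-limb GRFz (N/kg, already synchronized onto the IMU clock) forms the
#' 4 x 200 curve target in LF, RF, LH, RH order; the peak target is the
#' per-limb [extract_pgrfz()] of the window curve (at walk: the second of the
#' two principal stance peaks).
#'
#' @param window a `stride_window`.
#' @param trial processed `trial_recording` containing the window.
#' @param nodes a [node_set()].
#' @param n_samples samples per channel (default 200).
#' @return list of class `stride_sample`: `input` ((6 x N nodes) x 200),
#'   `curve` (4 x 200), `peak` (length 4), `peak_time`, `meta`.
#' @export
build_stride_sample <- function(window, trial, nodes = node_set("All"),
                                n_samples = 200) {
  assert_that(!is.null(trial$proc), "trial must be processed first")
  missing <- setdiff(nodes$nodes, names(trial$proc$nodes))
  assert_that(length(missing) == 0, "missing node(s): %s",
              paste(missing, collapse = ", "))
  t <- trial$proc$t
  tq <- seq(window$start, window$end, length.out = n_samples)
  rows <- list()
  for (node in nodes$nodes) {
    nd <- trial$proc$nodes[[node]]
    for (j in 1:3) rows[[length(rows) + 1]] <- interp1(t, nd$acc[, j], tq)
    for (j in 1:3) rows[[length(rows) + 1]] <- interp1(t, nd$gyro[, j], tq)
  }
  input <- do.call(rbind, rows)
  rownames(input) <- unlist(lapply(nodes$nodes, function(nd)
    paste(nd, node_channels(), sep = ".")))
  curve <- t(vapply(grf_limbs(), function(limb) {
    interp1(t, trial$proc$grfz[, limb], tq)
  }, numeric(n_samples)))
  gait <- window$gait
  span <- window$end - window$start
  stance_frac <- t(vapply(grf_limbs(), function(limb) {
    soi <- window$stance_of_interest[[limb]]
    c(max(0, (soi$on - window$start) / span - 0.02),
      min(1, (soi$off - window$start) / span + 0.02))
  }, numeric(2)))
  pk <- lapply(seq_along(grf_limbs()), function(li) {
    extract_pgrfz(curve[li, ], gait, restrict = stance_frac[li, ])
  })
  structure(list(
    input = input, curve = curve, stance_frac = stance_frac,
    peak = vapply(pk, `[[`, numeric(1), "pgrfz"),
    peak_time = vapply(pk, `[[`, numeric(1), "t_pgrfz"),
    single_peak = vapply(pk, `[[`, logical(1), "single_peak"),
    meta = list(horse_id = window$horse_id %||% trial$horse$horse_id,
                gait = gait, speed = window$speed %||% trial$gait_params$speed,
                start = window$start, end = window$end)
  ), class = "stride_sample")
}

#' Split stride samples horse-wise into train/validation/test
#'
#' Horses are randomly assigned to subsets by seed; all strides of a horse
#' land in one subset (disjoint horse sets), and training strides are
#' shuffled.
#'
#' @param samples list of `stride_sample`s.
#' @param counts integer vector `c(train, val, test)` horse counts; must sum
#'   to the number of distinct horses (default 16-4-4 at full study scale).
#' @param seed integer seed.
#' @return list of class `dataset_bundle` (without normalization bounds; see
#'   [finalize_bundle()]).
#' @export
split_by_horse <- function(samples, counts = c(16, 4, 4), seed = 1L) {
  horses <- sort(unique(vapply(samples, function(s) s$meta$horse_id, "")))
  assert_that(length(horses) == sum(counts),
              "distinct horse count (%d) must equal sum of counts (%d)",
              length(horses), sum(counts))
  withr::with_seed(as.integer(seed), {
    perm <- sample(horses)
    assign <- list(train = perm[seq_len(counts[1])],
                   val = perm[counts[1] + seq_len(counts[2])],
                   test = perm[counts[1] + counts[2] + seq_len(counts[3])])
    subsets <- lapply(assign, function(hs) {
      samples[vapply(samples, function(s) s$meta$horse_id %in% hs, logical(1))]
    })
    subsets$train <- subsets$train[sample(length(subsets$train))]
  })
  structure(list(train = subsets$train, val = subsets$val, test = subsets$test,
                 horses = assign, seed = as.integer(seed)),
            class = "dataset_bundle")
}

#' Per-channel normalization bounds from the training subset
#'
#' @param train list of `stride_sample`s (training subset only).
#' @return list of class `norm_bounds` with `input`, `curve`, `peak` matrices
#'   (`min`/`max` columns, one row per channel).
#' @export
compute_bounds <- function(train) {
  assert_that(length(train) > 0, "empty training subset")
  rng <- function(get) {
    M <- vapply(train, function(s) {
      x <- get(s); cbind(apply(x, 1, min), apply(x, 1, max))
    }, matrix(0, nrow(get(train[[1]])), 2))
    dim(M) <- c(dim(M)[1], 2, length(train))
    out <- cbind(min = apply(M[, 1, , drop = FALSE], 1, min),
                 max = apply(M[, 2, , drop = FALSE], 1, max))
    rownames(out) <- rownames(get(train[[1]]))
    out
  }
  pk <- vapply(train, function(s) s$peak, numeric(4))
  pkb <- cbind(min = apply(pk, 1, min), max = apply(pk, 1, max))
  rownames(pkb) <- grf_limbs()
  structure(list(
    input = rng(function(s) s$input),
    curve = rng(function(s) s$curve),
    peak = pkb
  ), class = "norm_bounds")
}

# internal: (x - min) / (max - min) rowwise; degenerate channels -> 0
norm_mat <- function(x, b, warn = TRUE) {
  span <- b[, "max"] - b[, "min"]
  if (any(span == 0)) {
    if (warn) warning("channel(s) with max = min mapped to 0")
    span[span == 0] <- 1
    x <- x - b[, "min"]  # centred, then zeroed below
    x[b[, "max"] - b[, "min"] == 0, ] <- 0
    return(x / span)
  }
  (x - b[, "min"]) / span
}

denorm_mat <- function(x, b) {
  span <- b[, "max"] - b[, "min"]
  span[span == 0] <- 1
  x * span + b[, "min"]
}

#' Min-max normalize stride samples with training bounds
#'
#' `x' = (x - min) / (max - min)` per channel, using bounds computed from the
#' training subset only; validation/test values may fall outside `[0, 1]` and
#' are not clipped. [minmax_denormalize()] is the exact inverse.
#'
#' @param samples list of `stride_sample`s.
#' @param bounds a `norm_bounds`.
#' @return list of normalized samples.
#' @export
minmax_normalize <- function(samples, bounds) {
  warned <- FALSE
  lapply(samples, function(s) {
    s$input <- norm_mat(s$input, bounds$input, warn = !warned)
    warned <<- TRUE  # warn about degenerate channels once per call
    s$curve <- norm_mat(s$curve, bounds$curve, warn = FALSE)
    s$peak <- as.numeric(norm_mat(matrix(s$peak, ncol = 1), bounds$peak,
                                  warn = FALSE))
    s
  })
}

#' @rdname minmax_normalize
#' @param curves matrix (4 x n) or array of normalized curves.
#' @export
minmax_denormalize <- function(curves, bounds) {
  if (is.matrix(curves)) return(denorm_mat(curves, bounds))
  curves * (bounds[, "max"] - bounds[, "min"]) + bounds[, "min"]
}

#' Attach normalization bounds to a split bundle
#'
#' @param bundle output of [split_by_horse()].
#' @return the bundle with a `bounds` element computed from its training
#'   subset.
#' @export
finalize_bundle <- function(bundle) {
  bundle$bounds <- compute_bounds(bundle$train)
  bundle
}

#' Stack stride samples into dense arrays for training
#'
#' @param samples list of `stride_sample`s.
#' @param bounds optional `norm_bounds`; when given, inputs and targets are
#'   normalized.
#' @return list with `X` (channels x n x 200), `curve` (4 x n x 200), `peak`
#'   (4 x n) arrays and `meta` data frame.
#' @export
samples_to_arrays <- function(samples, bounds = NULL) {
  assert_that(length(samples) > 0, "no samples")
  if (!is.null(bounds)) samples <- minmax_normalize(samples, bounds)
  C <- nrow(samples[[1]]$input); Tn <- ncol(samples[[1]]$input)
  n <- length(samples)
  X <- array(0, c(C, n, Tn)); Yc <- array(0, c(4, n, Tn))
  Yp <- matrix(0, 4, n)
  for (i in seq_len(n)) {
    X[, i, ] <- samples[[i]]$input
    Yc[, i, ] <- samples[[i]]$curve
    Yp[, i] <- samples[[i]]$peak
  }
  meta <- do.call(rbind, lapply(samples, function(s) {
    data.frame(horse_id = s$meta$horse_id, gait = s$meta$gait,
               speed = s$meta$speed, start = s$meta$start, end = s$meta$end)
  }))
  list(X = X, curve = Yc, peak = Yp, meta = meta)
}

#' Deterministically thin a stride-sample collection
#'
#' Keeps `target` evenly spaced samples (in trial/window order), preserving
#' horse and speed coverage; used by the scaled profile to bound training
#' cost while staying above its per-gait stride floor.
#'
#' @param samples list of `stride_sample`s.
#' @param target desired number of samples (no-op if already fewer).
#' @return thinned list.
#' @export
thin_samples <- function(samples, target) {
  n <- length(samples)
  if (is.null(target) || n <= target) return(samples)
  samples[unique(round(seq(1, n, length.out = target)))]
}

#' Build per-gait stride samples from a list of processed trials
#'
#' @param trials list of processed `trial_recording`s (one gait).
#' @param nodes a [node_set()].
#' @param events_source `"detector"` or `"truth"`.
#' @param n_samples samples per channel.
#' @return list of `stride_sample`s.
#' @export
build_samples <- function(trials, nodes = node_set("All"),
                          events_source = "detector", n_samples = 200) {
  out <- list()
  for (trial in trials) {
    wins <- segment_trial(trial, source = events_source)
    for (w in wins) {
      out[[length(out) + 1]] <- build_stride_sample(w, trial, nodes, n_samples)
    }
  }
  out
}
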