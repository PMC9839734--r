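#' Per-stride curve RMSE
#'
#' Root mean squared pointwise difference over the full 200-sample stride
#' (stance plus swing), in denormalized units (N/kg). A stance-only variant
#' is available via `stance_only` together with the stance index range.
#'
#' @param predicted,reference equal-length numeric traces.
#' @param stance_idx optional integer indices to restrict the comparison to.
#' @return RMSE, N/kg.
#' @export
stride_rmse <- function(predicted, reference, stance_idx = NULL) {
  assert_that(length(predicted) == length(reference),
              "trace lengths differ (%d vs %d)", length(predicted),
              length(reference))
  if (!is.null(stance_idx)) {
    predicted <- predicted[stance_idx]; reference <- reference[stance_idx]
  }
  sqrt(mean((predicted - reference)^2))
}

#' Per-stride curve correlation (rho)
#'
#' Correlation between the predicted and reference stride curves. The default
#' is Pearson: the reference GRFz is identically zero throughout the swing
#' phase, so a rank correlation is bounded well below 1 by the swing ties
#' (about 0.97 at walk and 0.91 at trot even for a perfect stance
#' prediction), which makes rank correlation unable to reflect stance
#' accuracy on these curves; Spearman remains available for sensitivity
#' analysis.
#'
#' @param predicted,reference equal-length numeric traces.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return correlation in `[-1, 1]`, or NA (with a warning) if either trace
#'   is constant.
#' @export
stride_rho <- function(predicted, reference,
                       method = c("pearson", "spearman")) {
  method <- match.arg(method)
  assert_that(length(predicted) == length(reference),
              "trace lengths differ (%d vs %d)", length(predicted),
              length(reference))
  if (stats::sd(predicted) == 0 || stats::sd(reference) == 0) {
    warning("constant trace: correlation undefined, returning NA")
    return(NA_real_)
  }
  stats::cor(predicted, reference, method = method)
}

#' Extract the peak GRFz and its time from a stride curve
#'
#' Trot: the global maximum and its normalized time. Walk: within the
#' supra-threshold region of largest area (the complete stance contained in
#' the window), local maxima with prominence of at least `prominence` times
#' the curve maximum are located; the second (later) of the two principal
#' peaks is returned. If the mid-stance dip has vanished (low speeds) and
#' only one principal peak exists, that peak is returned with
#' `single_peak = TRUE`.
#'
#' @param curve denormalized GRFz trace (one limb), N/kg.
#' @param gait `"walk"` or `"trot"`.
#' @param prominence walk peak prominence threshold, fraction of curve max.
#' @param restrict optional normalized interval `c(lo, hi)` of the curve to
#'   search (the limb's stance of interest, known from the IMU hoof events);
#'   windows longer than one stride can contain a second complete stance of
#'   the boundary limbs, and the restriction pins the extraction to the
#'   stance the window was built around. Reported times stay relative to the
#'   whole curve.
#' @return list with `pgrfz` (N/kg), `t_pgrfz` (normalized stride time in
#'   `[0, 1]`) and `single_peak` flag.
#' @export
extract_pgrfz <- function(curve, gait, prominence = 0.05, restrict = NULL) {
  n <- length(curve)
  if (all(curve == 0)) stopf("all-zero curve: no peak to extract")
  off0 <- 0L
  if (!is.null(restrict)) {
    lo <- max(1L, 1L + floor(restrict[1] * (n - 1)))
    hi <- min(n, 1L + ceiling(restrict[2] * (n - 1)))
    assert_that(hi > lo, "empty restriction interval")
    off0 <- lo - 1L
    curve_full <- curve
    curve <- curve[lo:hi]
    if (all(curve == 0)) stopf("all-zero curve in restriction interval")
  }
  if (gait == "trot") {
    i <- which.max(curve)
    return(list(pgrfz = curve[i], t_pgrfz = (off0 + i - 1) / (n - 1),
                single_peak = TRUE))
  }
  if (gait != "walk") stopf("unknown gait label '%s'", gait)
  cmax <- max(curve)
  thr <- prominence * cmax
  above <- curve > thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  reg <- data.frame(start = starts[runs$values], end = ends[runs$values])
  if (nrow(reg) == 0) stopf("no supra-threshold region in curve")
  area <- vapply(seq_len(nrow(reg)), function(i) {
    sum(curve[reg$start[i]:reg$end[i]])
  }, numeric(1))
  r <- reg[which.max(area), ]
  seg <- curve[r$start:r$end]
  # interior local maxima of the principal region
  loc <- which(diff(sign(diff(seg))) < 0) + 1
  if (length(loc) == 0) loc <- which.max(seg)
  # prominence: drop to the deepest valley between a peak and a higher peak
  prom <- vapply(loc, function(i) {
    h <- seg[i]
    left <- loc[loc < i & seg[loc] >= h]; right <- loc[loc > i & seg[loc] >= h]
    vl <- if (length(left)) min(seg[max(left):i]) else min(seg[1:i])
    vr <- if (length(right)) min(seg[i:min(right)]) else min(seg[i:length(seg)])
    h - max(vl, vr)
  }, numeric(1))
  keep <- loc[prom >= prominence * cmax]
  if (length(keep) == 0) keep <- loc[which.max(seg[loc])]
  if (length(keep) >= 2) {
    principal <- keep[order(seg[keep], decreasing = TRUE)][1:2]
    i <- max(principal)  # the later of the two principal peaks
    single <- FALSE
  } else {
    i <- keep[1]
    single <- TRUE
  }
  idx <- r$start + i - 1
  list(pgrfz = curve[idx], t_pgrfz = (off0 + idx - 1) / (n - 1),
       single_peak = single)
}

#' Robinson symmetry index
#'
#' `SI = 2 (L - R) / (L + R) * 100` (percent): 0 is perfect symmetry,
#' positive values indicate a higher left peak, negative a higher right peak.
#'
#' @param p_left,p_right left and right peak GRFz, N/kg.
#' @return SI in percent, in `[-200, 200]`.
#' @export
robinson_si <- function(p_left, p_right) {
  assert_that(all(p_left + p_right > 0), "peak sum must be positive")
  2 * (p_left - p_right) / (p_left + p_right) * 100
}

#' Bland-Altman agreement analysis
#'
#' Differences are `estimate - reference`; the bias is their mean, the
#' precision (STD) their standard deviation, and the 95% limits of agreement
#' are `bias +- 1.96 * STD`.
#'
#' @param reference,estimate paired numeric vectors (length >= 2).
#' @return list of class `bland_altman` with `bias`, `std`, `upper`, `lower`,
#'   and the paired `means`/`diffs` retained for plotting.
#' @export
bland_altman <- function(reference, estimate) {
  assert_that(length(reference) == length(estimate),
              "paired vectors must have equal length")
  assert_that(length(reference) >= 2, "need at least 2 pairs")
  d <- estimate - reference
  bias <- mean(d)
  std <- stats::sd(d)
  structure(list(bias = bias, std = std,
                 upper = bias + 1.96 * std, lower = bias - 1.96 * std,
                 means = (estimate + reference) / 2, diffs = d,
                 n = length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3f [%.3f; %.3f] (STD %.3f, n = %d)\n",
              x$bias, x$lower, x$upper, x$std, x$n))
  invisible(x)
}

#' Per-stride curve metrics for a trained curve predictor
#'
#' @param predictor trained curve-head `grfz_predictor`.
#' @param samples held-out `stride_sample`s (unnormalized).
#' @param method correlation method for [stride_rho()].
#' @return data frame with one row per stride and limb: `rmse`, `rho`,
#'   reference and extracted predicted peaks and peak times.
#' @export
evaluate_curve_predictions <- function(predictor, samples,
                                       method = "pearson") {
  pred <- predict_grfz(predictor, samples)
  gait <- samples[[1]]$meta$gait
  rows <- list()
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    for (li in seq_along(grf_limbs())) {
      limb <- grf_limbs()[li]
      p <- pred[li, i, ]; r <- s$curve[li, ]
      restrict <- if (!is.null(s$stance_frac)) s$stance_frac[li, ]
      pk <- tryCatch(extract_pgrfz(p, gait, restrict = restrict),
                     error = function(e) {
        list(pgrfz = NA_real_, t_pgrfz = NA_real_, single_peak = NA)
      })
      rows[[length(rows) + 1]] <- data.frame(
        stride = i, limb = limb, horse_id = s$meta$horse_id,
        speed = s$meta$speed,
        rmse = stride_rmse(p, r),
        rho = suppressWarnings(stride_rho(p, r, method)),
        ref_pgrfz = s$peak[li], ref_t_pgrfz = s$peak_time[li],
        ext_pgrfz = pk$pgrfz, ext_t_pgrfz = pk$t_pgrfz)
    }
  }
  do.call(rbind, rows)
}

# internal: per-stride SI for a peak matrix (4 x n, limb order LF RF LH RH)
si_from_peaks <- function(pk) {
  data.frame(si_front = robinson_si(pk[1, ], pk[2, ]),
             si_hind = robinson_si(pk[3, ], pk[4, ]))
}

#' Compare IMU node sets on held-out strides
#'
#' For each node set, trained curve and peak predictors are evaluated on the
#' same held-out strides: per-stride curve RMSE and rho distributions,
#' Bland-Altman agreement of the peak GRFz obtained by both routes (extracted
#' from the predicted curves, and directly predicted) per limb pair, and
#' agreement of the front and hind Robinson symmetry indices.
#'
#' @param fits named list (by node-set name) of lists with elements `curve`
#'   (trained curve predictor), `peak` (trained peak predictor, optional) and
#'   `test` (held-out `stride_sample`s).
#' @param method correlation method.
#' @return list of class `node_set_report`: `curves` (per-stride metric
#'   table), `peaks` (Bland-Altman summary table: node set x route x limb
#'   pair), `si` (SI agreement table), `medians` (per node set median
#'   RMSE/rho).
#' @export
compare_node_sets <- function(fits, method = "pearson") {
  assert_that(length(fits) > 0, "no fitted node sets supplied")
  curves <- list(); peaks <- list(); sis <- list()
  for (ns in names(fits)) {
    f <- fits[[ns]]
    assert_that(!is.null(f$curve), "missing curve predictor for %s", ns)
    ev <- evaluate_curve_predictions(f$curve, f$test, method)
    ev$node_set <- ns
    curves[[ns]] <- ev
    ref_pk <- vapply(f$test, function(s) s$peak, numeric(4))
    ext_pk <- t(vapply(grf_limbs(), function(limb) {
      ev$ext_pgrfz[ev$limb == limb][order(ev$stride[ev$limb == limb])]
    }, numeric(length(f$test))))
    routes <- list(extracted = ext_pk)
    if (!is.null(f$peak)) routes$predicted <- predict_grfz(f$peak, f$test)
    ba_row <- function(ref, est, ns, route, pair) {
      if (length(ref) < 2) {
        return(data.frame(node_set = ns, route = route, limb_pair = pair,
                          bias = NA_real_, std = NA_real_, lower = NA_real_,
                          upper = NA_real_, n = length(ref)))
      }
      ba <- bland_altman(ref, est)
      data.frame(node_set = ns, route = route, limb_pair = pair,
                 bias = ba$bias, std = ba$std, lower = ba$lower,
                 upper = ba$upper, n = ba$n)
    }
    for (route in names(routes)) {
      pk <- routes[[route]]
      for (pair in c("front", "hind")) {
        li <- if (pair == "front") 1:2 else 3:4
        ok <- stats::complete.cases(t(pk[li, , drop = FALSE]))
        peaks[[length(peaks) + 1]] <- ba_row(as.numeric(ref_pk[li, ok]),
                                             as.numeric(pk[li, ok]),
                                             ns, route, pair)
      }
      ok <- stats::complete.cases(t(pk)) &
        (pk[1, ] + pk[2, ] > 0) & (pk[3, ] + pk[4, ] > 0)
      si_ref <- si_from_peaks(ref_pk[, ok, drop = FALSE])
      si_est <- si_from_peaks(pk[, ok, drop = FALSE])
      for (pair in c("front", "hind")) {
        col <- paste0("si_", pair)
        sis[[length(sis) + 1]] <- ba_row(si_ref[[col]], si_est[[col]],
                                         ns, route, pair)
      }
    }
  }
  curves <- do.call(rbind, curves)
  med <- do.call(rbind, lapply(split(curves, curves$node_set), function(d) {
    data.frame(node_set = d$node_set[1],
               median_rmse = stats::median(d$rmse),
               median_rho = stats::median(d$rho, na.rm = TRUE))
  }))
  structure(list(curves = curves, peaks = do.call(rbind, peaks),
                 si = do.call(rbind, sis), medians = med),
            class = "node_set_report")
}
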