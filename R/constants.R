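#' Fixed limb and node orderings
#'
#' All matrices produced by this package use a frozen ordering: limbs are
#' LF, RF, LH, RH (left/right front, left/right hind) and IMU nodes are
#' head, withers, sacrum followed by the four limb nodes in limb order.
#' Serialization preserves these orderings bit-exactly.
#'
#' @format Character vectors.
#' @name orderings
NULL

#' @rdname orderings
#' @export
grf_limbs <- function() c("LF", "RF", "LH", "RH")

#' @rdname orderings
#' @export
grf_nodes <- function() c("head", "withers", "sacrum", "LF", "RF", "LH", "RH")

#' Standard gravity used throughout, in m s^-2 (equivalently N kg^-1)
#' @export
grf_gravity <- function() 9.81

# internal: channel names for one node, fixed order
node_channels <- function() c("acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) if (!isTRUE(cond)) stopf(fmt, ...)

# linear interpolation wrapper with boundary extension
interp1 <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, method = "linear", rule = 2, ties = "ordered")$y
}
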