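#' Wrap an angle to the compass range [0, 360)
#'
#' Compass bearings are clockwise-positive degrees with north at 0. All
#' world-frame headings in this package live on this range.
#'
#' @param deg Numeric vector of angles in degrees.
#' @return Numeric vector in `[0, 360)`.
#' @export
#' @examples
#' wrap_heading(c(-10, 370, 360))
wrap_heading <- function(deg) {
  out <- deg %% 360
  # %% can return 360 for tiny negative fuzz; fold it back
  out[out >= 360] <- out[out >= 360] - 360
  out
}

#' Wrap an angle to the signed range (-180, 180]
#'
#' The minimal signed arc between two bearings, i.e. the turn a responder
#' would execute. Positive is clockwise, matching the protocol's sign
#' convention.
#'
#' @param deg Numeric vector of angles in degrees.
#' @return Numeric vector in `(-180, 180]`.
#' @export
wrap_signed <- function(deg) {
  out <- wrap_heading(deg)
  out[out > 180] <- out[out > 180] - 360
  out
}

#' Minimal absolute circular difference between two bearings
#'
#' @param a,b Bearings in degrees (any real value; wrapped internally).
#' @return Absolute difference in `[0, 180]`.
#' @export
circular_difference <- function(a, b) {
  abs(wrap_signed(a - b))
}
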