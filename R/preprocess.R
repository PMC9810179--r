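#' Correct a 180-degree device flip
#'
#' Participants occasionally held the tablet rotated 180 degrees, so the
#' whole stream is recorded in a flipped device frame. Detection uses the
#' gravity axis: a flat-held device reads about +9.81 m/s^2 on the z
#' accelerometer, so a negative median z reading marks a flipped stream.
#' Correction maps the stream back through the 180-degree device-frame
#' rotation (heading + 180 mod 360, sign of the x/z accelerometer and
#' gyroscope channels inverted). Idempotent: a corrected stream is never
#' flipped again.
#'
#' @param stream Sensor-stream tibble (columns `t, ax, ay, az, gx, gy, gz,
#'   heading`).
#' @return The stream, corrected if flipped, with attribute
#'   `flip_corrected` set.
#' @export
correct_flip <- function(stream) {
  stopifnot(all(c("az", "heading") %in% names(stream)))
  flipped <- stats::median(stream$az) < 0
  if (flipped) stream <- flip_device_frame(stream)
  attr(stream, "flip_corrected") <- flipped
  stream
}

#' Unwrap a compass heading series
#'
#' Compass readings live on `[0, 360)`, so a smooth trajectory crossing
#' north appears as a near-360-degree jump. Successive differences larger
#' in magnitude than `threshold_deg` (default 80, the pipeline's gate for
#' sequential compass values) are treated as wraparound and corrected by
#' the multiple of 360 that minimises the step; samples whose step stays
#' above the gate even after correction are rejected as glitches, linearly
#' interpolated, and counted.
#'
#' @param heading Numeric vector of compass degrees in `[0, 360)`.
#' @param threshold_deg Gate on successive compass differences.
#' @return Continuous (unbounded) heading series, same length, with
#'   attribute `n_rejected` giving the number of interpolated glitch
#'   samples. Wrapping the output back to `[0, 360)` recovers the accepted
#'   input samples exactly.
#' @export
#' @examples
#' unwrap_heading(c(10, 5, 0, 355, 350))
unwrap_heading <- function(heading, threshold_deg = 80) {
  n <- length(heading)
  if (n < 2) stop("heading series must have at least 2 samples")
  out <- numeric(n)
  rejected <- logical(n)
  out[1] <- heading[1]
  last_good <- heading[1]
  offset <- 0 # running multiple-of-360 correction
  for (i in 2:n) {
    d <- heading[i] - last_good
    dw <- wrap_signed(d)
    if (abs(dw) > threshold_deg) {
      rejected[i] <- TRUE
      out[i] <- NA_real_
    } else {
      offset <- offset + 360 * round((dw - d) / 360)
      out[i] <- heading[i] + offset
      last_good <- heading[i]
    }
  }
  if (any(rejected)) {
    idx <- seq_len(n)
    out[rejected] <- stats::approx(idx[!rejected], out[!rejected],
      xout = idx[rejected], rule = 2
    )$y
  }
  attr(out, "n_rejected") <- sum(rejected)
  out
}

#' Centred moving-window average
#'
#' The pipeline's smoother: a 100-point moving average of the raw signal.
#' Centred, with truncated windows at the edges so output length equals
#' input length; a constant series is a fixed point and `window = 1` is
#' the identity.
#'
#' @param x Numeric vector.
#' @param window Window length in samples (default 100).
#' @return Smoothed numeric vector, same length as `x`.
#' @export
moving_window_smooth <- function(x, window = 100) {
  if (window < 1) stop("window must be a positive integer")
  window <- as.integer(window)
  n <- length(x)
  if (window == 1 || n == 0) return(x)
  half_lo <- window %/% 2
  half_hi <- window - half_lo - 1L
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(1L, i - half_lo)
  hi <- pmin(n, i + half_hi)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Alternating peak/trough detection
#'
#' Scans a (smoothed) series for alternating local maxima and minima whose
#' swing exceeds a prominence floor, a fixed fraction of the series'
#' dynamic range. Endpoints are never reported as extrema, so strictly
#' monotone or flat series yield no events.
#'
#' @param x Numeric vector, typically a smoothed acceleration magnitude.
#' @param prominence_frac Prominence floor as a fraction of
#'   `max(x) - min(x)` (default 0.05).
#' @return Tibble with columns `index`, `value` and
#'   `type` (`"peak"`/`"trough"`), in index order and strictly alternating.
#' @export
detect_peaks <- function(x, prominence_frac = 0.05) {
  n <- length(x)
  empty <- tibble::tibble(
    index = integer(0), value = numeric(0), type = character(0)
  )
  if (n < 3) return(empty)
  rng <- max(x) - min(x)
  if (rng <= 0) return(empty)
  floor_abs <- prominence_frac * rng

  idx <- integer(0)
  val <- numeric(0)
  typ <- character(0)
  direction <- 0L # +1 looking for a peak, -1 for a trough, 0 undecided
  cand_max <- cand_min <- x[1]
  cand_max_i <- cand_min_i <- 1L
  for (i in 2:n) {
    xi <- x[i]
    if (xi > cand_max) {
      cand_max <- xi
      cand_max_i <- i
    }
    if (xi < cand_min) {
      cand_min <- xi
      cand_min_i <- i
    }
    if (direction >= 0L && cand_max - xi > floor_abs) {
      if (cand_max_i > 1L) { # endpoint maxima are not interior extrema
        idx <- c(idx, cand_max_i)
        val <- c(val, cand_max)
        typ <- c(typ, "peak")
      }
      direction <- -1L
      cand_min <- xi
      cand_min_i <- i
    } else if (direction <= 0L && xi - cand_min > floor_abs) {
      if (cand_min_i > 1L) {
        idx <- c(idx, cand_min_i)
        val <- c(val, cand_min)
        typ <- c(typ, "trough")
      }
      direction <- 1L
      cand_max <- xi
      cand_max_i <- i
    }
  }
  tibble::tibble(index = idx, value = val, type = typ)
}

#' Preprocess one sensor stream
#'
#' Applies the full raw-signal cleanup in order: 180-degree flip
#' correction, then compass unwrapping with the 80-degree sequential gate.
#' Smoothing and peak detection are applied downstream where needed (the
#' hesitation feature), so the clean stream keeps raw channels plus the
#' continuous heading.
#'
#' @param stream Sensor-stream tibble.
#' @param threshold_deg Compass gate passed to [unwrap_heading()].
#' @return The stream with an added `heading_unwrapped` column and
#'   attributes `flip_corrected` and `n_compass_rejections`.
#' @export
preprocess_stream <- function(stream, threshold_deg = 80) {
  out <- correct_flip(stream)
  hu <- unwrap_heading(out$heading, threshold_deg = threshold_deg)
  out$heading_unwrapped <- as.numeric(hu)
  attr(out, "flip_corrected") <- attr(out, "flip_corrected")
  attr(out, "n_compass_rejections") <- attr(hu, "n_rejected")
  out
}
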