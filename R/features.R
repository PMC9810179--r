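#' Names and layout of the movement feature vector
#'
#' The fixed 27-column layout of the per-trial feature vector: end error
#' (1), total angular displacement (1), per-axis tilt (3), per-axis
#' gyroscopic rate of change at 0.1/0.5/1.0 s intervals (9), per-axis
#' average acceleration (3), per-axis average jerk at the three intervals
#' (9), and the hesitation count (1). Importance reports index into this
#' layout, so it never changes order.
#'
#' @return Character vector of 27 feature names.
#' @export
feature_names <- function() {
  ints <- c("0.1", "0.5", "1.0")
  axes <- c("x", "y", "z")
  c(
    "end_error",
    "total_angular_displacement",
    paste0("tilt_", axes),
    paste0("gyro_roc_", rep(axes, each = 3), "_", rep(ints, 3)),
    paste0("avg_accel_", axes),
    paste0("avg_jerk_", rep(axes, each = 3), "_", rep(ints, 3)),
    "hesitations"
  )
}

#' End (pointing) error
#'
#' The task's path-integration proxy: the absolute minimal circular
#' difference, in degrees, between the final heading sample of the
#' response and the recorded reference bearing.
#'
#' @param clean Preprocessed stream (from [preprocess_stream()]).
#' @param reference_heading_deg Reference bearing in degrees.
#' @return Degrees in `[0, 180]`.
#' @export
end_error <- function(clean, reference_heading_deg) {
  h <- clean$heading
  if (length(h) == 0) stop("empty heading trace")
  circular_difference(h[length(h)], reference_heading_deg)
}

#' Total angular displacement
#'
#' The sum of all absolute consecutive heading changes over the response,
#' computed on the unwrapped (continuous) heading. A perfect movement that
#' starts at bearing 90 and returns monotonically to 0 scores exactly 90;
#' any backtracking or longer route increases the score.
#'
#' @param clean Preprocessed stream with `heading_unwrapped`.
#' @return Degrees, non-negative.
#' @export
total_angular_displacement <- function(clean) {
  h <- clean$heading_unwrapped
  if (is.null(h) || length(h) < 2) stop("need an unwrapped heading trace of length >= 2")
  sum(abs(diff(h)))
}

#' Per-axis tilt: largest-magnitude gyroscope value
#'
#' For each gyroscope axis, the sample of greatest absolute value over the
#' trial, returned with its original sign.
#'
#' @param clean Preprocessed stream.
#' @return Named numeric vector `c(x = , y = , z = )` in degrees.
#' @export
tilt_max <- function(clean) {
  vapply(c(x = "gx", y = "gy", z = "gz"), function(ch) {
    v <- clean[[ch]]
    if (length(v) == 0) stop("empty gyro channel ", ch)
    v[which.max(abs(v))]
  }, numeric(1))
}

# split a channel into consecutive non-overlapping blocks of interval_s,
# dropping a trailing partial block; returns a list of index vectors
interval_blocks <- function(n, interval_s, sample_period_s) {
  per <- round(interval_s / sample_period_s)
  if (per < 1) stop("interval shorter than one sample period")
  n_blocks <- n %/% per
  if (n_blocks < 1) stop("trace shorter than one interval")
  lapply(seq_len(n_blocks), function(b) ((b - 1) * per + 1):(b * per))
}

#' Gyroscopic rate of change over fixed time intervals
#'
#' For each axis, the trace is cut into consecutive non-overlapping blocks
#' of `interval_s` seconds; each block's raw gyroscope samples are summed
#' and divided by the number of samples in the block, and the block
#' averages are then averaged. Block averaging over 0.1, 0.5 and 1.0 s
#' suppresses the noise of the 0.003 s refresh rate.
#'
#' @param clean Preprocessed stream.
#' @param interval_s Block length in seconds: 0.1, 0.5 or 1.0.
#' @param sample_period_s Sampling period (default taken from the stream).
#' @return Named numeric vector `c(x = , y = , z = )`.
#' @export
gyro_rate_of_change <- function(clean, interval_s,
                                sample_period_s = attr(clean, "sample_period_s") %||% 0.003) {
  blocks <- interval_blocks(nrow(clean), interval_s, sample_period_s)
  vapply(c(x = "gx", y = "gy", z = "gz"), function(ch) {
    v <- clean[[ch]]
    mean(vapply(blocks, function(b) sum(v[b]) / length(b), numeric(1)))
  }, numeric(1))
}

#' Per-axis average acceleration
#'
#' Arithmetic mean of each accelerometer channel over the response window.
#'
#' @param clean Preprocessed stream.
#' @return Named numeric vector `c(x = , y = , z = )` in m/s^2.
#' @export
average_acceleration <- function(clean) {
  vapply(c(x = "ax", y = "ay", z = "az"), function(ch) {
    v <- clean[[ch]]
    if (length(v) == 0) stop("empty accel channel ", ch)
    mean(v)
  }, numeric(1))
}

#' Per-axis average jerk over fixed time intervals
#'
#' Jerk is the time derivative of acceleration. Per axis, raw accelerometer
#' samples are summed over consecutive `interval_s` blocks; successive
#' differences of those block sums are divided by the interval length, and
#' the result is aggregated over block pairs. The default aggregation is
#' the mean absolute difference (`mode = "absolute"`), since a signed mean
#' cancels to about zero on back-and-forth movements; `mode = "signed"`
#' keeps the raw mean.
#'
#' @param clean Preprocessed stream.
#' @param interval_s Block length in seconds: 0.1, 0.5 or 1.0.
#' @param mode `"absolute"` (default) or `"signed"`.
#' @param sample_period_s Sampling period (default taken from the stream).
#' @return Named numeric vector `c(x = , y = , z = )` in m/s^3.
#' @export
average_jerk <- function(clean, interval_s, mode = c("absolute", "signed"),
                         sample_period_s = attr(clean, "sample_period_s") %||% 0.003) {
  mode <- match.arg(mode)
  blocks <- interval_blocks(nrow(clean), interval_s, sample_period_s)
  if (length(blocks) < 2) stop("need at least 2 complete blocks for jerk")
  vapply(c(x = "ax", y = "ay", z = "az"), function(ch) {
    v <- clean[[ch]]
    sums <- vapply(blocks, function(b) sum(v[b]), numeric(1))
    d <- diff(sums) / interval_s
    if (mode == "absolute") mean(abs(d)) else mean(d)
  }, numeric(1))
}

#' Count hesitations (stop-and-restart events)
#'
#' The accelerometer magnitude, after removal of the static gravity
#' baseline, tracks movement intensity. It is smoothed with the 100-point
#' moving window and scanned by [detect_peaks()]; a hesitation is a trough
#' flanked by peaks on both sides whose smoothed magnitude falls below
#' `stop_frac` of the trace's 95th percentile (i.e. the movement genuinely
#' stops, rather than merely slowing).
#'
#' The gravity baseline is estimated per axis as the median over the first
#' and last `rest_s` seconds of the recording, where the device is held
#' still.
#'
#' @param clean Preprocessed stream.
#' @param window Smoothing window in samples (default 100).
#' @param stop_frac Stop threshold as a fraction of the 95th percentile of
#'   the smoothed magnitude (default 0.10).
#' @param prominence_frac Peak-detection prominence floor (default 0.05).
#' @param rest_s Rest span at each end used for the gravity baseline.
#' @return Integer count, >= 0.
#' @export
count_hesitations <- function(clean, window = 100, stop_frac = 0.10,
                              prominence_frac = 0.05, rest_s = 0.1) {
  a <- cbind(clean$ax, clean$ay, clean$az)
  n <- nrow(a)
  if (n < 3) return(0L)
  edge <- clean$t <= (clean$t[1] + rest_s) | clean$t >= (clean$t[n] - rest_s)
  baseline <- apply(a[edge, , drop = FALSE], 2, stats::median)
  mag <- sqrt(rowSums(sweep(a, 2, baseline)^2))
  sm <- moving_window_smooth(mag, window)
  ev <- detect_peaks(sm, prominence_frac)
  if (nrow(ev) < 3) return(0L)
  thr <- stop_frac * stats::quantile(sm, 0.95, names = FALSE)
  flanked <- ev$type == "trough" &
    seq_len(nrow(ev)) > 1 & seq_len(nrow(ev)) < nrow(ev)
  sum(flanked & ev$value < thr)
}

#' Extract the full feature vector of one trial response
#'
#' Assembles the seven movement features into the fixed 27-column layout
#' of [feature_names()].
#'
#' @param clean Preprocessed stream.
#' @param reference_heading_deg Reference bearing in degrees.
#' @param jerk_mode `"absolute"` or `"signed"`, see [average_jerk()].
#' @param intervals Block lengths in seconds for rate-of-change and jerk.
#' @inheritParams count_hesitations
#' @return One-row tibble with 27 feature columns.
#' @export
extract_features <- function(clean, reference_heading_deg,
                             jerk_mode = "absolute",
                             intervals = c(0.1, 0.5, 1.0),
                             window = 100, stop_frac = 0.10,
                             prominence_frac = 0.05) {
  roc <- lapply(intervals, function(iv) gyro_rate_of_change(clean, iv))
  jrk <- lapply(intervals, function(iv) average_jerk(clean, iv, mode = jerk_mode))
  axes <- c("x", "y", "z")
  vals <- c(
    end_error(clean, reference_heading_deg),
    total_angular_displacement(clean),
    tilt_max(clean),
    unlist(lapply(axes, function(a) vapply(roc, `[[`, numeric(1), a))),
    average_acceleration(clean),
    unlist(lapply(axes, function(a) vapply(jrk, `[[`, numeric(1), a))),
    count_hesitations(clean,
      window = window, stop_frac = stop_frac,
      prominence_frac = prominence_frac
    )
  )
  names(vals) <- feature_names()
  tibble::as_tibble(as.list(vals))
}

#' Build per-trial feature tables for a cohort
#'
#' Preprocesses every stream of a cohort and extracts its feature vector,
#' returning one long table with demographics and the genotype label
#' attached: one row per participant x trial, ready to be split by
#' `trial_id` for per-trial classification.
#'
#' @param cohort A `vrt_cohort` from [generate_cohort()].
#' @param threshold_deg Compass gate for [preprocess_stream()].
#' @inheritParams extract_features
#' @return Tibble: `participant_id`, `trial_id`, `group`, `age`, `sex`,
#'   `occupation`, then the 27 feature columns.
#' @export
extract_feature_table <- function(cohort, threshold_deg = 80,
                                  jerk_mode = "absolute", window = 100,
                                  stop_frac = 0.10, prominence_frac = 0.05) {
  stopifnot(inherits(cohort, "vrt_cohort"))
  feats <- purrr::map_dfr(seq_len(nrow(cohort$trials)), function(i) {
    row <- cohort$trials[i, ]
    clean <- preprocess_stream(row$stream[[1]], threshold_deg = threshold_deg)
    fv <- extract_features(clean, row$reference_heading_deg,
      jerk_mode = jerk_mode, window = window,
      stop_frac = stop_frac, prominence_frac = prominence_frac
    )
    dplyr::bind_cols(
      tibble::tibble(
        participant_id = row$participant_id,
        trial_id = row$trial_id
      ),
      fv
    )
  })
  demo <- dplyr::select(
    cohort$participants,
    "participant_id", "group", "age", "sex", "occupation"
  )
  dplyr::left_join(feats, demo, by = "participant_id") |>
    dplyr::relocate("group", "age", "sex", "occupation", .after = "trial_id")
}

#' Drop one of each highly correlated feature pair
#'
#' Optional dimensionality filter: among numeric feature columns, for any
#' pair with absolute Pearson correlation above `cutoff`, the
#' later-indexed column is dropped. Disabled by default in the pipeline.
#'
#' @param table Feature table.
#' @param cutoff Absolute correlation above which one column is dropped.
#' @param protect Columns never dropped (identifiers, label, demographics).
#' @return The table with correlated columns removed.
#' @export
filter_correlated <- function(table, cutoff = 0.95,
                              protect = c(
                                "participant_id", "trial_id", "group",
                                "age", "sex", "occupation"
                              )) {
  num <- setdiff(names(table)[vapply(table, is.numeric, logical(1))], protect)
  if (length(num) < 2) return(table)
  cm <- suppressWarnings(stats::cor(table[num]))
  cm[is.na(cm)] <- 0
  drop <- character(0)
  for (j in seq_along(num)[-1]) {
    for (i in seq_len(j - 1)) {
      if (!(num[i] %in% drop) && abs(cm[i, j]) > cutoff) {
        drop <- c(drop, num[j])
        break
      }
    }
  }
  dplyr::select(table, -dplyr::all_of(drop))
}
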