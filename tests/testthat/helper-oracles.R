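# Independent brute-force oracles, coded as plain loops so they share no
# machinery with the implementation they check.

oracle_min_arc <- function(a, b) {
  d <- abs(a - b) %% 360
  min(d, 360 - d)
}

oracle_total_displacement <- function(h) {
  s <- 0
  for (i in 2:length(h)) s <- s + abs(h[i] - h[i - 1])
  s
}

oracle_max_magnitude <- function(v) {
  best <- v[1]
  for (x in v) if (abs(x) > abs(best)) best <- x
  best
}

oracle_mean <- function(v) {
  s <- 0
  for (x in v) s <- s + x
  s / length(v)
}

oracle_block_average <- function(v, interval_s, dt) {
  per <- round(interval_s / dt)
  n_blocks <- length(v) %/% per
  means <- numeric(n_blocks)
  for (b in seq_len(n_blocks)) {
    s <- 0
    for (i in ((b - 1) * per + 1):(b * per)) s <- s + v[i]
    means[b] <- s / per
  }
  oracle_mean(means)
}

oracle_jerk <- function(v, interval_s, dt, absolute = TRUE) {
  per <- round(interval_s / dt)
  n_blocks <- length(v) %/% per
  sums <- numeric(n_blocks)
  for (b in seq_len(n_blocks)) {
    s <- 0
    for (i in ((b - 1) * per + 1):(b * per)) s <- s + v[i]
    sums[b] <- s
  }
  d <- numeric(n_blocks - 1)
  for (b in 2:n_blocks) {
    step <- (sums[b] - sums[b - 1]) / interval_s
    d[b - 1] <- if (absolute) abs(step) else step
  }
  oracle_mean(d)
}

oracle_confusion <- function(truth, pred, positive) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == positive && pred[i] == positive) tp <- tp + 1
    if (truth[i] != positive && pred[i] == positive) fp <- fp + 1
    if (truth[i] == positive && pred[i] != positive) fn <- fn + 1
    if (truth[i] != positive && pred[i] != positive) tn <- tn + 1
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# independently coded hesitation counter: plain-loop smoothing, a
# different alternating-extrema scan, and the same documented rules
# (gravity baseline from the rest edges, 5% prominence floor, troughs
# flanked by peaks and below 10% of the 95th percentile)
oracle_count_hesitations <- function(cl, window = 100, stop_frac = 0.10,
                                     prominence_frac = 0.05, rest_s = 0.1) {
  n <- nrow(cl)
  a <- cbind(cl$ax, cl$ay, cl$az)
  edge <- cl$t <= cl$t[1] + rest_s | cl$t >= cl$t[n] - rest_s
  base <- c(
    stats::median(a[edge, 1]), stats::median(a[edge, 2]),
    stats::median(a[edge, 3])
  )
  mag <- numeric(n)
  for (i in seq_len(n)) {
    mag[i] <- sqrt(sum((a[i, ] - base)^2))
  }
  half_lo <- window %/% 2
  half_hi <- window - half_lo - 1
  sm <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half_lo)
    hi <- min(n, i + half_hi)
    sm[i] <- sum(mag[lo:hi]) / (hi - lo + 1)
  }
  floor_abs <- prominence_frac * (max(sm) - min(sm))
  if (max(sm) - min(sm) <= 0) return(0L)
  # forward scan committing an extremum each time the series reverses by
  # more than the prominence floor
  ev_idx <- integer(0)
  ev_type <- character(0)
  dir <- 0
  cmax <- cmin <- sm[1]
  imax <- imin <- 1
  for (i in 2:n) {
    if (sm[i] > cmax) {
      cmax <- sm[i]
      imax <- i
    }
    if (sm[i] < cmin) {
      cmin <- sm[i]
      imin <- i
    }
    if (dir >= 0 && cmax - sm[i] > floor_abs) {
      if (imax > 1) {
        ev_idx <- c(ev_idx, imax)
        ev_type <- c(ev_type, "max")
      }
      dir <- -1
      cmin <- sm[i]
      imin <- i
    } else if (dir <= 0 && sm[i] - cmin > floor_abs) {
      if (imin > 1) {
        ev_idx <- c(ev_idx, imin)
        ev_type <- c(ev_type, "min")
      }
      dir <- 1
      cmax <- sm[i]
      imax <- i
    }
  }
  thr <- stop_frac * stats::quantile(sm, 0.95, names = FALSE)
  count <- 0L
  if (length(ev_type) >= 3) {
    for (e in 2:(length(ev_type) - 1)) {
      if (ev_type[e] == "min" && sm[ev_idx[e]] < thr &&
        ev_type[e - 1] == "max" && ev_type[e + 1] == "max") {
        count <- count + 1L
      }
    }
  }
  count
}

# a random sensor-stream tibble with no physical structure, for oracle
# equivalence checks of the arithmetic feature definitions
random_stream <- function(n = 400, dt = 0.003) {
  s <- tibble::tibble(
    t = seq(0, by = dt, length.out = n),
    ax = stats::rnorm(n), ay = stats::rnorm(n), az = stats::rnorm(n, 9.81),
    gx = stats::rnorm(n, 0, 0.1), gy = stats::rnorm(n, 0, 0.1),
    gz = stats::rnorm(n, 0, 0.3),
    heading = stats::runif(n, 0, 360)
  )
  attr(s, "sample_period_s") <- dt
  s
}

# a smooth noiseless profile (all stochastic phenotype components zero)
noiseless_profile <- function(duration = 2) {
  tibble::tibble(
    group = "e33", age = 60, sex = "female", occupation = "occ1",
    heading_error_sd_deg = 0, heading_bias_deg = 0, hesitation_rate = 0,
    jerk_scale = 0, tilt_wobble_sd = 0, movement_duration_s = duration
  )
}

# small quick cohort for structural tests
small_config <- function(...) {
  cohort_config(n_e33 = 8, n_e34 = 6, ...)
}

# separable two-cluster feature table: group signal in every column
separable_table <- function(n_per = 12, p = 5, sep = 10, seed = 1) {
  set.seed(seed)
  X <- rbind(
    matrix(stats::rnorm(n_per * p, 0), n_per),
    matrix(stats::rnorm(n_per * p, sep), n_per)
  )
  colnames(X) <- paste0("f", seq_len(p))
  dplyr::bind_cols(
    tibble::tibble(group = rep(c("e33", "e34"), each = n_per)),
    tibble::as_tibble(as.data.frame(X))
  )
}
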