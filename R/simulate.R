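#' Cohort configuration for the synthetic rotation-task generator
#'
#' Describes a cohort of participants for the simulator: group sizes
#' (default 32 e3e3 non-carriers and 21 e3e4 carriers, the task's study
#' population), the strength of the group difference in movement
#' phenotype, and the rates of the two sensor artifacts the preprocessing
#' stage corrects.
#'
#' `effect_size` multiplies every between-group phenotype difference:
#' 0 yields a null cohort in which the two genotype groups are drawn from
#' identical distributions, 1 the default group separation, larger values
#' proportionally larger separations.
#'
#' @param n_e33,n_e34 Number of e3e3 / e3e4 participants.
#' @param effect_size Non-negative multiplier on the group phenotype deltas.
#' @param flip_prob Per-stream probability that the device is held rotated
#'   180 degrees, so the stream is emitted in the flipped device frame.
#' @param wrap_guaranteed If `TRUE`, every pointing trajectory is placed so
#'   that it crosses compass north, guaranteeing a wraparound discontinuity
#'   in the emitted heading.
#' @param phenotype Named list of generator parameters; see
#'   [phenotype_defaults()]. Entries override the defaults.
#' @param seed Integer master seed; the whole cohort is reproducible from it.
#' @return A list of class `vrt_config`.
#' @export
cohort_config <- function(n_e33 = 32, n_e34 = 21, effect_size = 1,
                          flip_prob = 0.05, wrap_guaranteed = FALSE,
                          phenotype = list(), seed = 1L) {
  stopifnot(
    n_e33 >= 0, n_e34 >= 0, effect_size >= 0,
    flip_prob >= 0, flip_prob <= 1
  )
  ph <- utils::modifyList(phenotype_defaults(), phenotype)
  structure(
    list(
      n_e33 = as.integer(n_e33), n_e34 = as.integer(n_e34),
      effect_size = effect_size, flip_prob = flip_prob,
      wrap_guaranteed = isTRUE(wrap_guaranteed),
      phenotype = ph, seed = as.integer(seed)
    ),
    class = "vrt_config"
  )
}

#' Default latent phenotype parameters of the simulator
#'
#' The generator draws, per participant, a latent movement phenotype that
#' controls the pointing response: the spread and bias of the pointing
#' (end) error, the expected number of mid-movement hesitations, a
#' dimensionless vigour scale for hand acceleration and its roughness, the
#' amplitude of off-axis tilt wobble, and the movement duration.
#'
#' `base` holds the e3e3 group means; `delta` the e3e4 minus e3e3 group
#' mean difference at `effect_size = 1` (the carrier group points less
#' precisely, hesitates more and moves more jerkily); `sd` the
#' between-participant standard deviations, shared by both groups.
#'
#' @return A list with elements `base`, `delta` and `sd`, each a named
#'   numeric vector over the six phenotype parameters.
#' @export
phenotype_defaults <- function() {
  list(
    base = c(
      heading_error_sd_deg = 12, heading_bias_deg = 0,
      hesitation_rate = 0.6, jerk_scale = 1.0,
      tilt_wobble_sd = 2.0, movement_duration_s = 2.0
    ),
    delta = c(
      heading_error_sd_deg = 8, heading_bias_deg = 0,
      hesitation_rate = 0.8, jerk_scale = 0.25,
      tilt_wobble_sd = 0, movement_duration_s = 0
    ),
    sd = c(
      heading_error_sd_deg = 3, heading_bias_deg = 4,
      hesitation_rate = 0.15, jerk_scale = 0.2,
      tilt_wobble_sd = 0.5, movement_duration_s = 0.15
    )
  )
}

#' Draw one participant profile
#'
#' Samples demographics (age, sex, occupation, matched approximately to the
#' study's marginals: mean age about 63 years, mixed sex with more male
#' non-carriers) and a latent movement phenotype from the group-specific
#' distributions of `config`. Uses the current RNG state; seed outside.
#'
#' @param group `"e33"` or `"e34"`.
#' @param config A [cohort_config()].
#' @return One-row tibble with demographics and phenotype columns.
#' @export
sample_participant <- function(group, config = cohort_config()) {
  group <- match.arg(group, c("e33", "e34"))
  ph <- config$phenotype
  mu <- ph$base
  if (group == "e34") mu <- mu + config$effect_size * ph$delta
  draw <- stats::rnorm(length(mu), mean = mu, sd = ph$sd)
  names(draw) <- names(mu)
  # scale parameters cannot be negative; sds are small enough relative to
  # the means that this floor is a numerical safety net, not a bias
  nonneg <- c("heading_error_sd_deg", "hesitation_rate", "jerk_scale", "tilt_wobble_sd")
  draw[nonneg] <- pmax(draw[nonneg], 0.01)
  # the 1.0 s feature intervals need two complete blocks, i.e. a trace
  # of at least 2 s including the rest pads
  draw["movement_duration_s"] <- max(draw["movement_duration_s"], 1.6)
  age <- if (group == "e33") stats::rnorm(1, 63.6, 5.8) else stats::rnorm(1, 63.0, 5.5)
  sex <- if (stats::runif(1) < (if (group == "e33") 17 / 32 else 6 / 21)) "male" else "female"
  occupation <- sample(paste0("occ", 1:5), 1)
  tibble::tibble(
    group = group, age = age, sex = sex, occupation = occupation,
    !!!as.list(draw)
  )
}

# 180-degree device-frame rotation about the lateral (y) axis: the
# transform is its own inverse, shifts the compass by 180 degrees and
# inverts the gravity axis, which is what the flip detector keys on.
flip_device_frame <- function(stream) {
  stream$heading <- wrap_heading(stream$heading + 180)
  for (ch in c("ax", "az", "gx", "gz")) stream[[ch]] <- -stream[[ch]]
  stream
}

# minimum-jerk unit velocity shape on tau in [0, 1]
minjerk_velocity <- function(tau) {
  v <- 30 * tau^2 - 60 * tau^3 + 30 * tau^4
  v[tau < 0 | tau > 1] <- 0
  v
}

# smooth stop gate around a hesitation centre: exactly zero on the flat
# core, smoothstep ramps on both sides
hesitation_gate <- function(t, centre, flat = 0.35, ramp = 0.10) {
  d <- abs(t - centre) - flat / 2
  u <- pmin(pmax(d / ramp, 0), 1)
  u * u * (3 - 2 * u)
}

#' Simulate the sensor stream of one pointing response
#'
#' Generates the tablet's recording of the response window of one trial:
#' the participant starts at the post-rotation body bearing
#' (`reference - net rotation`, wrapped), rests briefly, then turns along a
#' minimum-jerk angular trajectory to `reference + pointing error`, with
#' Poisson-many inserted hesitations (intervals where angular velocity
#' drops to zero and resumes), and rests again. Gyroscope channels are
#' per-sample angular increments in degrees (rate times the 0.003 s sample
#' period); accelerometer channels combine centripetal and tangential
#' components of the arm swing, gravity on the z axis, and white roughness
#' noise scaled by the jerk phenotype; compass heading is emitted wrapped
#' to `[0, 360)`.
#'
#' Uses the current RNG state. The returned tibble carries a `truth`
#' attribute recording the inserted hesitation count, the pointing error,
#' whether the stream was emitted device-flipped, and the continuous
#' (unwrapped) heading trace, so downstream recovery is directly testable.
#'
#' @param profile One-row profile tibble from [sample_participant()].
#' @param net_rotation_deg Signed net chair rotation of the trial.
#' @param reference_heading_deg Compass bearing of the remembered reference.
#' @param flip Emit the stream in the 180-degree flipped device frame.
#' @param wrap_centre Re-centre the world so the trajectory crosses north.
#' @param sample_period_s Sensor sampling period (default 0.003 s).
#' @param rest_pad_s Still rest recorded before and after the movement.
#' @return Tibble with columns `t, ax, ay, az, gx, gy, gz, heading`.
#' @export
simulate_trial_response <- function(profile, net_rotation_deg,
                                    reference_heading_deg,
                                    flip = FALSE, wrap_centre = FALSE,
                                    sample_period_s = 0.003,
                                    rest_pad_s = 0.2) {
  stopifnot(nrow(profile) == 1, sample_period_s > 0)
  dt <- sample_period_s
  err <- stats::rnorm(1, profile$heading_bias_deg, profile$heading_error_sd_deg)
  h0 <- wrap_heading(reference_heading_deg - net_rotation_deg)
  turn <- wrap_signed(net_rotation_deg + err)

  # hesitations: a Poisson count of stop intervals; each stop adds its
  # length to the movement phase (a pausing responder takes longer), and
  # stops are placed in jittered slots so they remain distinct events
  k <- stats::rpois(1, profile$hesitation_rate)
  pause_len <- 0.35 + 2 * 0.10 # flat core plus both smoothstep ramps
  dur <- profile$movement_duration_s + k * pause_len
  t <- seq(0, dur + 2 * rest_pad_s, by = dt)
  n <- length(t)

  v <- minjerk_velocity((t - rest_pad_s) / dur)
  centres <- numeric(0)
  if (k > 0) {
    span_start <- rest_pad_s + 0.15 * dur
    width <- 0.7 * dur / k
    centres <- span_start +
      width * (seq_len(k) - 1 + 0.25 + 0.5 * stats::runif(k))
    for (c_i in centres) v <- v * hesitation_gate(t, c_i)
  }

  # position by trapezoidal integration, normalised to land exactly on the
  # target bearing; omega is then the exact analytic derivative
  inc <- (v[-1] + v[-n]) / 2 * dt
  cum <- c(0, cumsum(inc))
  heading_cont <- h0 + turn * cum / cum[n]
  omega_deg <- turn * v / cum[n]

  if (isTRUE(wrap_centre)) {
    shift <- -(h0 + turn / 2)
    heading_cont <- heading_cont + shift
    reference_heading_deg <- reference_heading_deg + shift
  }

  omega_rad <- omega_deg * pi / 180
  alpha_rad <- c(diff(omega_rad) / dt, 0)
  arm_r <- 0.3 # metres, device held at arm's length
  js <- profile$jerk_scale
  ax <- js * (arm_r * omega_rad^2 + stats::rnorm(n, 0, 0.04))
  ay <- js * (arm_r * alpha_rad + stats::rnorm(n, 0, 0.04))
  az <- 9.81 + js * stats::rnorm(n, 0, 0.02)

  tw <- profile$tilt_wobble_sd
  gx <- gy <- numeric(n)
  if (tw > 0) {
    wob <- function() {
      f <- stats::runif(1, 0.4, 1.2)
      phase <- stats::runif(1, 0, 2 * pi)
      ang <- tw * sqrt(2) * sin(2 * pi * f * t + phase)
      c(0, diff(ang)) + stats::rnorm(n, 0, 0.02 * tw * dt / 0.003)
    }
    gx <- wob()
    gy <- wob()
  }
  gz <- omega_deg * dt

  stream <- tibble::tibble(
    t = t, ax = ax, ay = ay, az = az,
    gx = gx, gy = gy, gz = gz,
    heading = wrap_heading(heading_cont)
  )
  if (isTRUE(flip)) stream <- flip_device_frame(stream)
  attr(stream, "sample_period_s") <- dt
  attr(stream, "truth") <- list(
    hesitations_inserted = length(centres),
    pointing_error_deg = err,
    turn_deg = turn,
    flipped = isTRUE(flip),
    heading_continuous = heading_cont,
    reference_heading_deg = wrap_heading(reference_heading_deg)
  )
  stream
}

#' Generate a full synthetic cohort
#'
#' One session per participant: a recorded reference bearing plus one
#' sensor stream per protocol trial. Fully deterministic given
#' `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param protocol Protocol tibble, default [vrt_protocol()].
#' @return A list of class `vrt_cohort` with elements `participants`
#'   (tibble: `participant_id`, demographics, phenotype) and `trials`
#'   (tibble: `participant_id`, `trial_id`, `reference_heading_deg`,
#'   ground-truth columns `true_hesitations`, `flipped`,
#'   `pointing_error_deg`, and list-column `stream`).
#' @export
generate_cohort <- function(config = cohort_config(), protocol = vrt_protocol()) {
  validate_protocol(protocol)
  if (config$n_e33 + config$n_e34 == 0) {
    stop("cohort has no participants: n_e33 + n_e34 must be positive")
  }
  set.seed(config$seed)
  groups <- c(rep("e33", config$n_e33), rep("e34", config$n_e34))
  nets <- net_rotation(protocol)

  participants <- purrr::map2_dfr(groups, seq_along(groups), function(g, i) {
    dplyr::bind_cols(
      tibble::tibble(participant_id = sprintf("P%03d", i)),
      sample_participant(g, config)
    )
  })

  trials <- purrr::map_dfr(seq_len(nrow(participants)), function(i) {
    prof <- participants[i, ]
    ref <- if (config$wrap_guaranteed) {
      wrap_heading(stats::runif(1, -20, 20))
    } else {
      stats::runif(1, 0, 360)
    }
    purrr::map_dfr(seq_len(nrow(nets)), function(j) {
      flip <- stats::runif(1) < config$flip_prob
      s <- simulate_trial_response(
        prof, nets$net_rotation_deg[j], ref,
        flip = flip, wrap_centre = config$wrap_guaranteed
      )
      truth <- attr(s, "truth")
      tibble::tibble(
        participant_id = prof$participant_id,
        trial_id = nets$trial_id[j],
        reference_heading_deg = truth$reference_heading_deg,
        true_hesitations = truth$hesitations_inserted,
        flipped = truth$flipped,
        pointing_error_deg = truth$pointing_error_deg,
        stream = list(s)
      )
    })
  })

  structure(
    list(participants = participants, trials = trials, config = config),
    class = "vrt_cohort"
  )
}

#' @export
print.vrt_cohort <- function(x, ...) {
  cat(
    "<vrt_cohort> ", nrow(x$participants), " participants (",
    sum(x$participants$group == "e33"), " e33 / ",
    sum(x$participants$group == "e34"), " e34), ",
    nrow(x$trials), " trial streams, effect_size = ",
    x$config$effect_size, ", seed = ", x$config$seed, "\n",
    sep = ""
  )
  invisible(x)
}
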