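# Synthetic accelerometer recordings for the nine activity classes.
#
# Measurement model: a tri-axial accelerometer rigidly mounted on the body
# reads the specific force rotated into the sensor frame,
#
#   a(t) = R(t)' (a_i(t) + g) + e(t),   g = (0, 0, 9.81) m/s^2 (Z up),
#
# where R(t) is the body-to-inertial rotation, a_i(t) the kinematic
# acceleration in the inertial frame and e isotropic Gaussian noise. A
# static upright sensor therefore reads (0, 0, 9.81) and |a| = 9.81
# everywhere when sigma_e = 0.

GRAVITY <- 9.81

child_seed <- function(seed, k) {
  x <- ((as.numeric(seed) %% 2147483647) * 48271) %% 2147483647
  as.integer((x + as.numeric(k) * 100003) %% 2147483647)
}

#' Default activity script
#'
#' One pass through the eight scripted activities (transitions are inserted
#' automatically between segments by [simulate_recording()]). Durations are
#' chosen so that a subject's session stays compact while every class still
#' contributes thousands of 100 Hz samples; longer protocol-length sessions
#' are obtained by passing larger durations.
#'
#' @param rest_s,gait_s,fall_s Segment durations in seconds for the resting
#'   classes, for walking/jogging, and for the fall.
#' @return Tibble with columns `activity` and `duration` (seconds).
#' @export
default_script <- function(rest_s = 10, gait_s = 15, fall_s = 3) {
  tibble::tibble(
    activity = c("Standing", "Sitting", "LFU", "LFD", "LS",
                 "Walking", "Jogging", "Falling"),
    duration = c(rest_s, rest_s, rest_s, rest_s, rest_s,
                 gait_s, gait_s, fall_s)
  )
}

default_sim_params <- function() {
  list(
    sway = list(amp = 0.05, freq = 0.3),  # m/s^2, Hz: resting micro-motion
    standing = list(sway_scale = 1.6),    # postural sway larger when standing
    sitting = list(sway_scale = 0.6, pitch_ear = 0.15, pitch_waist = 0.35),
    walking = list(freq = 1.8, amp_v = 2, amp_f = 1),    # steps/s, m/s^2
    jogging = list(freq = 2.8, amp_v = 6, amp_f = 2.5),
    falling = list(pulse_amp = 15),                      # impact peak, m/s^2
    trn = list(jitter_amp = 1.0, jitter_freq = 1.2),
    pulse_width_frac = 0.3,               # heel-strike width as fraction of a step
    mount = list(roll = 0, pitch = 0)     # per-subject mounting misalignment
  )
}

#' Simulation configuration
#'
#' Bundles everything [simulate_recording()] needs: the activity script, the
#' sampling rate, the noise level, seeded randomness and the sensor
#' placements to emit.
#'
#' @param script Tibble with columns `activity`, `duration` (s); see
#'   [default_script()].
#' @param fs Sampling frequency in Hz.
#' @param sigma_e Per-axis Gaussian noise standard deviation, m/s^2.
#' @param seed Integer seed; the same seed reproduces the recording bit for
#'   bit.
#' @param placements Subset of `"ear_left"`, `"ear_right"`, `"waist"`.
#' @param trn_duration Duration (s, `>= 0`) of the transitioning segment
#'   inserted between consecutive scripted activities; 0 disables insertion.
#' @param subject_id Identifier carried into the output.
#' @param params Named list of overrides merged over the built-in motion
#'   parameters (gait frequencies and amplitudes, sway, fall impact, ...).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(script = default_script(), fs = 100, sigma_e = 0.05,
                       seed = 1L,
                       placements = c("ear_left", "ear_right", "waist"),
                       trn_duration = 1.5, subject_id = "S01",
                       params = list()) {
  stopifnot(is.data.frame(script), all(c("activity", "duration") %in% names(script)))
  if (nrow(script) == 0) abort("`script` must contain at least one segment.")
  bad <- setdiff(unique(script$activity), setdiff(activity_levels(), "TRN"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown activity name(s) in script: %s.",
                  paste(bad, collapse = ", ")))
  }
  if (any(script$duration <= 0)) abort("Every scripted duration must be > 0.")
  if (trn_duration < 0) abort("`trn_duration` must be >= 0.")
  if (fs <= 0) abort("`fs` must be positive.")
  if (sigma_e < 0) abort("`sigma_e` must be >= 0.")
  placements <- match.arg(placements, c("ear_left", "ear_right", "waist"),
                          several.ok = TRUE)
  p <- modifyList(default_sim_params(), params)
  structure(
    list(script = tibble::as_tibble(script), fs = fs, sigma_e = sigma_e,
         seed = as.integer(seed), placements = placements,
         trn_duration = trn_duration, subject_id = subject_id, params = p),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", nrow(x$script), "scripted segments,",
      sum(x$script$duration) , "s scripted +", x$trn_duration,
      "s transitions; fs =", x$fs, "Hz; sigma_e =", x$sigma_e,
      "m/s^2; placements:", paste(x$placements, collapse = ", "), "\n")
  invisible(x)
}

# Orientation offsets of each mounting site relative to the trunk/head.
placement_offset <- function(placement, mount) {
  off <- switch(placement,
    ear_left  = c(roll = 0.05, pitch = 0.02, yaw = 0.08),
    ear_right = c(roll = -0.05, pitch = 0.02, yaw = -0.08),
    waist     = c(roll = 0, pitch = 0.05, yaw = 0)
  )
  off[["roll"]] <- off[["roll"]] + mount$roll
  off[["pitch"]] <- off[["pitch"]] + mount$pitch
  off
}

# scale factors expressing that gait impacts are stronger at the waist while
# head micro-motion makes resting sway larger at the ears
placement_gait_scale <- function(placement) {
  switch(placement, ear_left = 1, ear_right = 1, waist = 1.1)
}
placement_sway_scale <- function(placement) {
  switch(placement, ear_left = 1.2, ear_right = 1.2, waist = 0.8)
}

# Base body orientation of an activity at one placement, as a 1 x 4
# quaternion. `draws` holds the per-segment random choices shared by all
# placements (lying side, fall end posture).
activity_quaternion <- function(activity, placement, params, draws) {
  off <- placement_offset(placement, params$mount)
  base <- switch(activity,
    Standing = c(0, 0),
    Sitting = c(0, if (placement == "waist") params$sitting$pitch_waist
                   else params$sitting$pitch_ear),
    LFU = c(0, -pi / 2),
    LFD = c(0, pi / 2),
    LS = c(draws$ls_side * pi / 2, 0),
    Walking = c(0, 0),
    Jogging = c(0, 0),
    c(0, 0)
  )
  quat_from_euler(roll = base[1] + off[["roll"]],
                  pitch = base[2] + off[["pitch"]],
                  yaw = off[["yaw"]])
}

# Hann pulse train with unit peak, period T, centers at (k + 1/2) T,
# width W = frac * T; the per-period mean (frac / 2) is subtracted so the
# waveform has zero DC.
hann_pulse_train <- function(t, period, frac) {
  u <- (t / period) %% 1
  d <- (u - 0.5) * period
  w <- frac * period
  p <- ifelse(abs(d) <= w / 2, 0.5 * (1 + cos(2 * pi * d / w)), 0)
  p - frac / 2
}

# Inertial-frame kinematic acceleration of one segment (n x 3 matrix).
segment_inertial_accel <- function(activity, t, params, draws, gait_scale,
                                   sway_scale) {
  n <- length(t)
  out <- matrix(0, n, 3)
  if (activity %in% c("Standing", "Sitting", "LFU", "LFD", "LS")) {
    amp <- params$sway$amp * sway_scale *
      switch(activity, Standing = params$standing$sway_scale,
             Sitting = params$sitting$sway_scale, 1)
    f <- params$sway$freq
    out[, 1] <- amp * sin(2 * pi * f * t + draws$phase[1])
    out[, 2] <- amp * sin(2 * pi * f * 0.8 * t + draws$phase[2])
  } else if (activity %in% c("Walking", "Jogging")) {
    gp <- params[[tolower(activity)]]
    amp_v <- gp$amp_v * gait_scale
    amp_f <- gp$amp_f * gait_scale
    # vertical: heel-strike pulse train dominates, plus a smooth
    # oscillation at the step frequency phase-locked to the strikes (gait
    # harmonics ride on the foot-fall cycle, they are not free-running);
    # the lock also keeps the step frequency the dominant spectral line
    out[, 3] <- amp_v * (-0.3 * cos(2 * pi * gp$freq * t) +
                           hann_pulse_train(t, 1 / gp$freq,
                                            params$pulse_width_frac))
    out[, 1] <- amp_f * sin(2 * pi * gp$freq * t + draws$phase[2])
    out[, 2] <- 0.3 * amp_f * sin(pi * gp$freq * t + draws$phase[3])
  } else if (activity == "Falling") {
    dur <- t[n] + (t[2] - t[1])
    centre <- 0.8 * dur
    w <- 0.3 * dur
    pulse <- ifelse(abs(t - centre) <= w / 2,
                    0.5 * (1 + cos(2 * pi * (t - centre) / w)), 0)
    out[, 3] <- params$falling$pulse_amp * pulse
    out[, 1] <- draws$fall_x_sign * 0.3 * params$falling$pulse_amp * pulse
  } else if (activity == "TRN") {
    tp <- params$trn
    out[, 1] <- tp$jitter_amp * sin(2 * pi * tp$jitter_freq * t + draws$phase[1])
    out[, 2] <- tp$jitter_amp * sin(2 * pi * tp$jitter_freq * 0.9 * t + draws$phase[2])
    out[, 3] <- tp$jitter_amp * sin(2 * pi * tp$jitter_freq * 1.15 * t + draws$phase[3])
  }
  out
}

# Insert TRN segments between scripted activities.
expand_script <- function(script, trn_duration) {
  segs <- purrr::pmap(script, function(activity, duration, ...) {
    list(activity = activity, duration = duration)
  })
  if (trn_duration > 0 && length(segs) > 1) {
    out <- list(segs[[1]])
    for (i in seq(2, length(segs))) {
      out <- c(out, list(list(activity = "TRN", duration = trn_duration)),
               segs[i])
    }
    segs <- out
  }
  segs
}

#' Simulate a labeled multi-sensor recording
#'
#' Generates, for every configured placement, a 100 Hz tri-axial
#' accelerometer stream following the configured activity script under the
#' specific-force measurement model (orientation-rotated gravity plus
#' kinematic acceleration plus isotropic Gaussian noise). Resting classes
#' hold a class-characteristic orientation with low-amplitude postural
#' sway; walking and jogging superimpose a periodic gait waveform (a
#' sinusoid plus a heel-strike pulse train) at the gait frequency; falling
#' is a short transient that rotates the body into a lying posture with an
#' impact spike; transitioning (TRN) segments interpolate the orientation
#' between neighboring activities.
#'
#' @param config A [sim_config()] object.
#' @return Tibble with columns `time_s`, `ax`, `ay`, `az` (m/s^2), `label`
#'   (factor over [activity_levels()]), `placement`, `subject_id`; one row
#'   per sample per placement.
#' @export
#' @examples
#' rec <- simulate_recording(sim_config(default_script(rest_s = 2, gait_s = 2,
#'                                                     fall_s = 1)))
#' dplyr::count(rec, placement, label)
simulate_recording <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  segs <- expand_script(config$script, config$trn_duration)
  fs <- config$fs
  n_seg <- vapply(segs, function(s) {
    n <- s$duration * fs
    if (abs(n - round(n)) > 1e-8) {
      abort(sprintf("Segment '%s' duration %g s is not a whole number of samples at fs = %g Hz.",
                    s$activity, s$duration, fs))
    }
    as.integer(round(n))
  }, integer(1))

  # per-segment random draws shared by all placements (one physical body)
  draws <- withr::with_seed(child_seed(config$seed, 0), {
    lapply(segs, function(s) {
      list(phase = runif(3, 0, 2 * pi),
           ls_side = sample(c(-1, 1), 1),
           fall_end = sample(c("LFU", "LFD", "LS"), 1),
           fall_x_sign = sample(c(-1, 1), 1))
    })
  })

  out <- purrr::map(seq_along(config$placements), function(pi_) {
    placement <- config$placements[[pi_]]
    gait_scale <- placement_gait_scale(placement)
    sway_scale <- placement_sway_scale(placement)

    # endpoint orientations per segment (TRN/falling interpolate)
    q_start <- vector("list", length(segs))
    q_end <- vector("list", length(segs))
    for (i in seq_along(segs)) {
      act <- segs[[i]]$activity
      if (act == "Falling") {
        end_draw <- list(ls_side = draws[[i]]$ls_side)
        q_start[[i]] <- activity_quaternion("Standing", placement,
                                            config$params, draws[[i]])
        q_end[[i]] <- activity_quaternion(draws[[i]]$fall_end, placement,
                                          config$params, end_draw)
      } else if (act != "TRN") {
        q <- activity_quaternion(act, placement, config$params, draws[[i]])
        q_start[[i]] <- q
        q_end[[i]] <- q
      }
    }
    for (i in seq_along(segs)) {
      if (segs[[i]]$activity == "TRN") {
        q_start[[i]] <- if (i > 1) q_end[[i - 1]] else
          activity_quaternion("Standing", placement, config$params, draws[[i]])
        q_end[[i]] <- if (i < length(segs)) q_start[[i + 1]] else
          activity_quaternion("Standing", placement, config$params, draws[[i]])
      }
    }

    acc <- matrix(0, sum(n_seg), 3)
    labels <- character(sum(n_seg))
    pos <- 0L
    for (i in seq_along(segs)) {
      act <- segs[[i]]$activity
      n <- n_seg[i]
      t_loc <- (seq_len(n) - 1) / fs
      ai <- segment_inertial_accel(act, t_loc, config$params, draws[[i]],
                                   gait_scale, sway_scale)
      if (act %in% c("Falling", "TRN")) {
        s <- (1 - cos(pi * t_loc / segs[[i]]$duration)) / 2
        qt <- quat_slerp(q_start[[i]], q_end[[i]], s)
      } else {
        qt <- q_start[[i]]
      }
      g <- matrix(c(0, 0, GRAVITY), 1, 3)
      f <- quat_rotate(quat_conj(qt), ai + g[rep(1, n), , drop = FALSE])
      acc[pos + seq_len(n), ] <- f
      labels[pos + seq_len(n)] <- act
      pos <- pos + n
    }
    if (config$sigma_e > 0) {
      noise <- withr::with_seed(
        child_seed(config$seed, pi_),
        matrix(rnorm(length(acc), 0, config$sigma_e), ncol = 3)
      )
      acc <- acc + noise
    }
    tibble::tibble(
      time_s = (seq_len(nrow(acc)) - 1) / fs,
      ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
      label = activity_factor(labels),
      placement = placement,
      subject_id = config$subject_id
    )
  })
  dplyr::bind_rows(out)
}

#' Simulate a cohort of subjects
#'
#' Repeats [simulate_recording()] for `n_subjects` subjects, applying
#' per-subject random jitter to gait frequency and amplitudes, posture
#' angles, sway and mounting alignment so that subjects differ the way
#' individuals in a wearable study do. Deterministic under `seed`.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param base_config A [sim_config()] used as template for every subject.
#' @param seed Root seed; subject `j` receives a derived seed (subject 1
#'   keeps the base seed, so a one-subject, zero-jitter cohort reproduces
#'   `simulate_recording(base_config)` exactly).
#' @param jitter Scale factor for the between-subject variability; 0 turns
#'   jitter off, 1 is the default calibration.
#' @return Tibble of all subjects' recordings in the format of
#'   [simulate_recording()].
#' @export
make_cohort <- function(n_subjects, base_config = sim_config(),
                        seed = base_config$seed, jitter = 1) {
  if (n_subjects < 1) abort("`n_subjects` must be >= 1.")
  purrr::map_dfr(seq_len(n_subjects), function(j) {
    cfg <- base_config
    cfg$subject_id <- sprintf("S%02d", j)
    cfg$seed <- child_seed(seed, 900000 + (j - 1) * 17)
    if (j == 1) cfg$seed <- as.integer(seed)
    if (jitter > 0) {
      jd <- withr::with_seed(child_seed(seed, 7e6 + j), list(
        wf = runif(1, -0.15, 0.15), jf = runif(1, -0.25, 0.25),
        wa = runif(1, 0.85, 1.2), ja = runif(1, 0.85, 1.2),
        pitch = runif(1, 0.8, 1.2), sway = runif(1, 0.8, 1.2),
        fall = runif(1, 0.85, 1.2),
        mroll = runif(1, -0.06, 0.06), mpitch = runif(1, -0.06, 0.06)
      ))
      p <- cfg$params
      p$walking$freq <- p$walking$freq + jitter * jd$wf
      p$jogging$freq <- p$jogging$freq + jitter * jd$jf
      p$walking$amp_v <- p$walking$amp_v * (1 + jitter * (jd$wa - 1))
      p$walking$amp_f <- p$walking$amp_f * (1 + jitter * (jd$wa - 1))
      p$jogging$amp_v <- p$jogging$amp_v * (1 + jitter * (jd$ja - 1))
      p$jogging$amp_f <- p$jogging$amp_f * (1 + jitter * (jd$ja - 1))
      p$sitting$pitch_ear <- p$sitting$pitch_ear * (1 + jitter * (jd$pitch - 1))
      p$sitting$pitch_waist <- p$sitting$pitch_waist * (1 + jitter * (jd$pitch - 1))
      p$sway$amp <- p$sway$amp * (1 + jitter * (jd$sway - 1))
      p$falling$pulse_amp <- p$falling$pulse_amp * (1 + jitter * (jd$fall - 1))
      p$mount$roll <- p$mount$roll + jitter * jd$mroll
      p$mount$pitch <- p$mount$pitch + jitter * jd$mpitch
      cfg$params <- p
    }
    simulate_recording(cfg)
  })
}

#' Number of steps injected into a synthetic gait segment
#'
#' Heel-strike pulses are centered at `(k + 1/2) / freq` seconds into the
#' segment; this counts how many fall inside a segment of the given
#' duration, which is the ground-truth step count for step-detection
#' experiments.
#'
#' @param freq Gait (step) frequency in steps/s.
#' @param duration Segment duration in seconds.
#' @return Integer step count.
#' @export
injected_steps <- function(freq, duration) {
  floor(freq * duration + 0.5)
}
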