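#' Generate a horizontal-saccade task schedule
#'
#' Builds the stimulus sequence of the horizontal saccade task: the target
#' starts at screen centre and, on each trial, jumps to the left or right
#' periphery (default 16 degrees of visual angle) and back to centre, so
#' every trial contributes two target jumps. Left/right order is
#' pseudorandom with balanced counts (within one), and every target
#' presentation (including the initial centre fixation) dwells for an
#' independent uniform draw from `dwell_bounds`.
#'
#' @param n_trials number of saccade trials (default 20).
#' @param amplitude_deg target eccentricity in degrees (default 16).
#' @param dwell_bounds length-2 numeric, dwell-duration interval in seconds
#'   (default `c(1.3, 2)`).
#' @param fs sampling rate in Hz; only recorded on the schedule.
#' @param seed integer RNG seed; the same seed reproduces the schedule.
#' @return An object of class `target_schedule`: list with
#'   `trial_directions` (`"left"`/`"right"`), `onset_times` (s, the
#'   centre-to-periphery jump of each trial), `dwell_durations` (s, one per
#'   target presentation: initial centre, then periphery/centre per trial),
#'   `amplitude_deg`, `fs`, `total_duration`, and a `jumps` data frame
#'   (`time`, `position_deg`) giving the piecewise-constant target position.
#' @export
#' @examples
#' sched <- generate_schedule(n_trials = 20, seed = 1)
#' nrow(sched$jumps)  # 40 target jumps
generate_schedule <- function(n_trials = 20, amplitude_deg = 16,
                              dwell_bounds = c(1.3, 2), fs = 240, seed = 1) {
  if (n_trials < 1) stop("`n_trials` must be >= 1", call. = FALSE)
  if (amplitude_deg <= 0) stop("`amplitude_deg` must be positive", call. = FALSE)
  if (length(dwell_bounds) != 2 || dwell_bounds[1] <= 0 ||
      dwell_bounds[2] < dwell_bounds[1]) {
    stop("`dwell_bounds` must be an increasing positive interval", call. = FALSE)
  }
  with_seed(seed, {
    n_right <- floor(n_trials / 2) + sample(0:(n_trials %% 2), 1L)
    dirs <- sample(c(rep("right", n_right), rep("left", n_trials - n_right)))
    n_dwell <- 2L * n_trials + 1L
    dwells <- stats::runif(n_dwell, dwell_bounds[1], dwell_bounds[2])
    ends <- cumsum(dwells)
    onsets <- ends[seq(1L, by = 2L, length.out = n_trials)]
    sign_of <- ifelse(dirs == "right", 1, -1)
    jump_time <- ends[-n_dwell]
    jump_pos <- as.vector(rbind(sign_of * amplitude_deg, 0))
    structure(list(
      trial_directions = dirs,
      onset_times = onsets,
      dwell_durations = dwells,
      amplitude_deg = amplitude_deg,
      fs = fs,
      total_duration = ends[n_dwell],
      jumps = data.frame(time = jump_time, position_deg = jump_pos)
    ), class = "target_schedule")
  })
}

#' Subject generative profiles
#'
#' A `subject_profile` holds the generative parameters of one synthetic
#' subject: the per-saccade primary gain distribution (ratio of initial
#' saccade amplitude to target step), the dysmetria mode, corrective-saccade
#' behaviour, and nuisance levels (blinks, drift, measurement noise,
#' left-right asymmetry). `control_profile()` and `dysmetric_profile()`
#' provide the two study conditions.
#'
#' In hypermetric saccades the initial amplitude overshoots the target and a
#' corrective saccade returns toward it; in hypometric saccades the initial
#' amplitude falls short and a same-direction corrective saccade follows.
#' `mode = "mixed"` draws each saccade's gain from a 50/50 hypo/hyper
#' mixture.
#'
#' @param group_label `"control"` or `"dysmetric"`.
#' @param dysmetria_mode `"none"`, `"hypometric"`, `"hypermetric"` or
#'   `"mixed"`.
#' @param primary_gain_mean,primary_gain_sd per-saccade gain distribution.
#'   For `"mixed"`, `primary_gain_mean` is length 2 (hypo, hyper).
#' @param corrective_latency_mean seconds between primary-saccade offset and
#'   the corrective saccade (dysmetric modes only).
#' @param corrective_gain fraction of the residual target error removed by
#'   the corrective saccade.
#' @param blink_rate blink events per minute.
#' @param drift_amplitude slow (< 0.08 Hz) drift amplitude, raw NIC units.
#' @param noise_sd additive white measurement noise SD, raw NIC units.
#' @param left_right_asymmetry SD of the multiplicative per-saccade gain
#'   perturbation applied to the right eye only; 0 means perfectly yoked
#'   eyes up to noise.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(group_label = c("control", "dysmetric"),
                            dysmetria_mode = c("none", "hypometric",
                                               "hypermetric", "mixed"),
                            primary_gain_mean = 0.94, primary_gain_sd = 0.02,
                            corrective_latency_mean = 0.15,
                            corrective_gain = 0.85,
                            blink_rate = 4, drift_amplitude = 0.02,
                            noise_sd = 0.01, left_right_asymmetry = 0.02) {
  group_label <- match.arg(group_label)
  dysmetria_mode <- match.arg(dysmetria_mode)
  if (any(c(primary_gain_sd, corrective_latency_mean, blink_rate,
            drift_amplitude, noise_sd, left_right_asymmetry) < 0)) {
    stop("rates and SDs must be non-negative", call. = FALSE)
  }
  if (group_label == "control") {
    if (dysmetria_mode != "none") {
      stop("control profiles must have dysmetria_mode = \"none\"", call. = FALSE)
    }
    if (any(primary_gain_mean < 0.90) || any(primary_gain_mean > 0.98)) {
      stop("control primary_gain_mean must lie in [0.90, 0.98]", call. = FALSE)
    }
  } else {
    if (dysmetria_mode == "none") {
      stop("dysmetric profiles need a dysmetria_mode", call. = FALSE)
    }
    if (dysmetria_mode == "hypometric" && primary_gain_mean[1] >= 0.85) {
      stop("hypometric primary_gain_mean must be < 0.85", call. = FALSE)
    }
    if (dysmetria_mode == "hypermetric" && primary_gain_mean[1] <= 1.10) {
      stop("hypermetric primary_gain_mean must be > 1.10", call. = FALSE)
    }
    if (dysmetria_mode == "mixed" && length(primary_gain_mean) != 2) {
      stop("mixed mode needs primary_gain_mean = c(hypo, hyper)", call. = FALSE)
    }
  }
  structure(list(
    group_label = group_label, dysmetria_mode = dysmetria_mode,
    primary_gain_mean = primary_gain_mean, primary_gain_sd = primary_gain_sd,
    corrective_latency_mean = corrective_latency_mean,
    corrective_gain = corrective_gain, blink_rate = blink_rate,
    drift_amplitude = drift_amplitude, noise_sd = noise_sd,
    left_right_asymmetry = left_right_asymmetry
  ), class = "subject_profile")
}

#' @rdname subject_profile
#' @export
control_profile <- function(primary_gain_mean = 0.94, ...) {
  subject_profile("control", "none", primary_gain_mean = primary_gain_mean, ...)
}

#' @rdname subject_profile
#' @param mode dysmetria mode for `dysmetric_profile()`.
#' @param ... further arguments to `subject_profile()`.
#' @export
dysmetric_profile <- function(mode = c("hypometric", "hypermetric", "mixed"),
                              primary_gain_mean = NULL,
                              left_right_asymmetry = 0.06, ...) {
  mode <- match.arg(mode)
  if (is.null(primary_gain_mean)) {
    primary_gain_mean <- switch(mode,
      hypometric = 0.72, hypermetric = 1.25, mixed = c(0.72, 1.25))
  }
  subject_profile("dysmetric", mode, primary_gain_mean = primary_gain_mean,
                  primary_gain_sd = 0.05,
                  left_right_asymmetry = left_right_asymmetry, ...)
}

# Raised-cosine sigmoidal step: 0 before onset, 1 after onset + dur, smooth
# monotone transition in between. Compact support keeps fixation segments
# exactly flat.
smooth_step <- function(t, onset, dur) {
  u <- (t - onset) / dur
  u[u < 0] <- 0
  u[u > 1] <- 1
  (1 - cos(pi * u)) / 2
}

# Main-sequence saccade duration (s) for an amplitude in degrees.
saccade_duration <- function(amp_deg) 0.0022 * abs(amp_deg) + 0.021

# Draw one primary gain from a profile.
draw_gain <- function(profile) {
  mu <- profile$primary_gain_mean
  if (profile$dysmetria_mode == "mixed") {
    mu <- mu[sample(1:2, 1L)]
  }
  stats::rnorm(1L, mu, profile$primary_gain_sd)
}

#' Simulate one binocular gaze recording
#'
#' Renders a `target_schedule` through a `subject_profile` into a
#' two-channel horizontal normalized-iris-centre (NIC) trace. The eye
#' follows each target jump after a reaction latency with a sigmoidal
#' primary saccade of amplitude `gain * step` whose duration follows a
#' main-sequence rule; dysmetric profiles add a corrective saccade toward
#' the target after `corrective_latency_mean`. Blinks are inserted as brief
#' large excursions that return exactly to the pre-blink level; slow
#' sinusoidal drift (< 0.08 Hz, modelling residual head-motion
#' compensation error, hence common to both eyes) and independent white
#' measurement noise per eye are added. Both eyes share the saccade and
#' blink events; the right eye's gains receive an independent
#' multiplicative perturbation (`left_right_asymmetry`), so the channels
#' are strongly but imperfectly coupled.
#'
#' Degrees map linearly to raw NIC units (16 degrees = 0.4 units);
#' downstream range normalization removes the absolute scale.
#'
#' @param schedule a `target_schedule`.
#' @param profile a `subject_profile`.
#' @param fs sampling rate, Hz.
#' @param duration recording length in seconds. The clinical task outlasts
#'   the 42-s recordings, so by default a schedule longer than `duration`
#'   is truncated at the recording end; set `on_overrun = "error"` to
#'   require the whole schedule to fit.
#' @param seed integer RNG seed.
#' @param reaction_latency saccade reaction latency, seconds.
#' @param on_overrun `"truncate"` (default) or `"error"`.
#' @return Object of class `gaze_recording`: list with `fs`, `duration`,
#'   `time`, `left_x`, `right_x`, `label`, `schedule`, `profile`, plus
#'   diagnostic traces `target` (noise-free target staircase in NIC units),
#'   `left_clean`/`right_clean` (blink-free twins) and `blinks` (data frame
#'   of inserted blink events).
#' @export
#' @examples
#' rec <- simulate_recording(generate_schedule(seed = 1), control_profile(),
#'                           duration = 42, seed = 1)
#' length(rec$left_x) == 42 * 240
simulate_recording <- function(schedule, profile, fs = 240, duration = 42,
                               seed = 1, reaction_latency = 0.2,
                               on_overrun = c("truncate", "error")) {
  stopifnot(inherits(schedule, "target_schedule"),
            inherits(profile, "subject_profile"))
  on_overrun <- match.arg(on_overrun)
  if (fs <= 0 || duration <= 0) {
    stop("`fs` and `duration` must be positive", call. = FALSE)
  }
  if (schedule$total_duration > duration && on_overrun == "error") {
    stop(sprintf(
      "schedule lasts %.2f s but the recording is only %.2f s; increase `duration` to at least %.2f s or allow truncation",
      schedule$total_duration, duration, schedule$total_duration), call. = FALSE)
  }
  n <- round(fs * duration)
  t <- (seq_len(n) - 1L) / fs
  deg2nic <- 0.4 / 16  # 16 deg targets at +/- 0.4 raw NIC units

  with_seed(seed, {
    jumps <- schedule$jumps[schedule$jumps$time < duration, , drop = FALSE]
    # Target staircase (piecewise constant).
    target <- numeric(n)
    pos_deg <- 0
    lvl <- c(0, jumps$position_deg) * deg2nic
    brk <- c(-Inf, jumps$time)
    target <- lvl[findInterval(t, brk)]

    # Saccade event list shared by both eyes: per target jump, a primary
    # gain draw, the right-eye asymmetry perturbation, and (for dysmetric
    # modes) a corrective saccade.
    n_j <- nrow(jumps)
    gains <- vapply(seq_len(n_j), function(i) draw_gain(profile), numeric(1))
    asym <- stats::rnorm(n_j, 0, profile$left_right_asymmetry)
    corr_lat <- pmax(0.05, stats::rnorm(n_j, profile$corrective_latency_mean, 0.02))

    # Joint binocular rendering: saccadic commands are conjugate (Hering's
    # law) and are computed from the left (reference) eye's error; the
    # right eye executes the same command scaled by its gain perturbation
    # plus a partial vergence re-alignment, so inter-eye disconjugacy is
    # stationary rather than a random walk.
    xl <- numeric(n); xr <- numeric(n)
    prev_l <- 0; prev_r <- 0
    vergence_k <- 0.5
    for (i in seq_len(n_j)) {
      tgt_deg <- jumps$position_deg[i]
      amp_l <- gains[i] * (tgt_deg - prev_l)
      amp_r <- amp_l * (1 + asym[i]) + vergence_k * (prev_l - prev_r)
      dur1 <- saccade_duration(amp_l)
      on1 <- jumps$time[i] + reaction_latency
      s1 <- smooth_step(t, on1, dur1)
      xl <- xl + amp_l * deg2nic * s1
      xr <- xr + amp_r * deg2nic * s1
      prev_l <- prev_l + amp_l
      prev_r <- prev_r + amp_r
      if (profile$dysmetria_mode != "none") {
        err_deg <- tgt_deg - prev_l
        if (abs(err_deg) > 0.25) {
          amp2 <- profile$corrective_gain * err_deg   # conjugate command
          on2 <- on1 + dur1 + corr_lat[i]
          s2 <- smooth_step(t, on2, saccade_duration(amp2))
          xl <- xl + amp2 * deg2nic * s2
          xr <- xr + amp2 * deg2nic * s2
          prev_l <- prev_l + amp2
          prev_r <- prev_r + amp2
        }
      }
    }
    left_sacc <- xl
    right_sacc <- xr

    # Shared blink events: brief raised-cosine excursions returning exactly
    # to the pre-blink level.
    n_blinks <- stats::rpois(1L, profile$blink_rate * duration / 60)
    blink_tab <- data.frame(time = numeric(0), duration = numeric(0),
                            amplitude = numeric(0))
    blink_wave <- numeric(n)
    if (n_blinks > 0) {
      bt <- sort(stats::runif(n_blinks, 0.5, max(0.6, duration - 0.7)))
      bd <- stats::runif(n_blinks, 0.1, 0.2)
      ba <- stats::runif(n_blinks, 0.2, 0.35) * sample(c(-1, 1), n_blinks, TRUE)
      for (i in seq_len(n_blinks)) {
        u <- (t - bt[i]) / bd[i]
        inside <- u >= 0 & u <= 1
        blink_wave[inside] <- blink_wave[inside] +
          ba[i] * (1 - cos(2 * pi * u[inside])) / 2
      }
      blink_tab <- data.frame(time = bt, duration = bd, amplitude = ba)
    }

    # Drift models residual head-motion compensation error in the NIC
    # coordinate: common mode, so the same slow waveform enters both eyes.
    drift <- if (profile$drift_amplitude == 0) numeric(n) else {
      f <- stats::runif(1L, 0.01, 0.06)
      ph <- stats::runif(1L, 0, 2 * pi)
      profile$drift_amplitude * sin(2 * pi * f * t + ph)
    }
    noise_of <- function() {
      if (profile$noise_sd == 0) return(numeric(n))
      stats::rnorm(n, 0, profile$noise_sd)
    }

    left_clean <- left_sacc + drift + noise_of()
    right_clean <- right_sacc + drift + noise_of()

    structure(list(
      fs = fs, duration = duration, time = t,
      left_x = left_clean + blink_wave,
      right_x = right_clean + blink_wave,
      label = profile$group_label,
      schedule = schedule, profile = profile,
      target = target,
      left_clean = left_clean, right_clean = right_clean,
      blinks = blink_tab
    ), class = "gaze_recording")
  })
}

#' Generate a labelled synthetic cohort
#'
#' Draws per-subject profiles from configured distributions and simulates
#' one recording per subject. Dysmetric subjects are spread across
#' hypometric, hypermetric and mixed modes. All randomness descends
#' deterministically from `seed`.
#'
#' @param n_dysmetric,n_control group sizes.
#' @param fs,duration recording parameters (defaults: 240 Hz, 42 s).
#' @param n_trials trials per task (default 20).
#' @param seed cohort seed; per-subject seeds are derived from it.
#' @param profile_distributions optional list overriding the cohort draw
#'   ranges; see Details. Elements: `mode_probs` (hypo/hyper/mixed),
#'   `control_gain`, `hypo_gain`, `hyper_gain` (uniform ranges for the gain
#'   mean), `control_asym`, `dysmetric_asym`, `blink_rate` (uniform ranges),
#'   `noise_sd`, `drift_amplitude` (scalars).
#' @return A list of `gaze_recording` objects named by subject id, with a
#'   `labels` attribute.
#' @export
generate_cohort <- function(n_dysmetric, n_control, fs = 240, duration = 42,
                            n_trials = 20, seed = 1,
                            profile_distributions = list()) {
  if (n_dysmetric < 0 || n_control < 0) {
    stop("group sizes must be non-negative", call. = FALSE)
  }
  pd <- modifyList(list(
    mode_probs = c(hypometric = 0.4, hypermetric = 0.3, mixed = 0.3),
    control_gain = c(0.91, 0.97),
    hypo_gain = c(0.65, 0.80),
    hyper_gain = c(1.15, 1.35),
    control_asym = c(0.01, 0.03),
    dysmetric_asym = c(0.04, 0.08),
    blink_rate = c(2, 6),
    noise_sd = 0.01,
    drift_amplitude = 0.02
  ), profile_distributions)

  make_subject <- function(label, k) {
    s <- derive_seed(seed, k)
    with_seed(s, {
      blink <- stats::runif(1, pd$blink_rate[1], pd$blink_rate[2])
      if (label == "control") {
        prof <- control_profile(
          primary_gain_mean = stats::runif(1, pd$control_gain[1], pd$control_gain[2]),
          blink_rate = blink, noise_sd = pd$noise_sd,
          drift_amplitude = pd$drift_amplitude,
          left_right_asymmetry = stats::runif(1, pd$control_asym[1], pd$control_asym[2]))
      } else {
        mode <- sample(names(pd$mode_probs), 1L, prob = pd$mode_probs)
        gm <- switch(mode,
          hypometric = stats::runif(1, pd$hypo_gain[1], pd$hypo_gain[2]),
          hypermetric = stats::runif(1, pd$hyper_gain[1], pd$hyper_gain[2]),
          mixed = c(stats::runif(1, pd$hypo_gain[1], pd$hypo_gain[2]),
                    stats::runif(1, pd$hyper_gain[1], pd$hyper_gain[2])))
        prof <- dysmetric_profile(
          mode = mode, primary_gain_mean = gm, blink_rate = blink,
          noise_sd = pd$noise_sd, drift_amplitude = pd$drift_amplitude,
          left_right_asymmetry = stats::runif(1, pd$dysmetric_asym[1], pd$dysmetric_asym[2]))
      }
    })
    sched <- generate_schedule(n_trials = n_trials, fs = fs,
                               seed = derive_seed(s, 1L))
    simulate_recording(sched, prof, fs = fs, duration = duration,
                       seed = derive_seed(s, 2L))
  }

  ids <- c(sprintf("dys_%03d", seq_len(n_dysmetric)),
           sprintf("ctl_%03d", seq_len(n_control)))
  labels <- c(rep("dysmetric", n_dysmetric), rep("control", n_control))
  recs <- lapply(seq_along(ids), function(k) make_subject(labels[k], k))
  names(recs) <- ids
  attr(recs, "labels") <- stats::setNames(labels, ids)
  recs
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf("<gaze_recording> %s, %.0f Hz, %.1f s (%d samples/channel)\n",
              x$label %||% "unlabelled", x$fs, x$duration, length(x$left_x)))
  invisible(x)
}

#' @export
print.target_schedule <- function(x, ...) {
  cat(sprintf("<target_schedule> %d trials, %.0f deg, %.1f s total\n",
              length(x$trial_directions), x$amplitude_deg, x$total_duration))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
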