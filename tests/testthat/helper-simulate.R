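# Shared fixtures built in code.

# Noiseless, blink-free, drift-free profile for deterministic traces.
pure_profile <- function(group = "control", mode = "none", gain = 0.94,
                         gain_sd = 0, asym = 0) {
  p <- if (group == "control") {
    control_profile(primary_gain_mean = gain, blink_rate = 0, noise_sd = 0,
                    drift_amplitude = 0, left_right_asymmetry = asym)
  } else {
    dysmetric_profile(mode = mode, primary_gain_mean = gain, blink_rate = 0,
                      noise_sd = 0, drift_amplitude = 0,
                      left_right_asymmetry = asym)
  }
  p$primary_gain_sd <- gain_sd
  p
}

# Alternating 0 / +0.4 staircase with raised-cosine 40 ms transitions:
# a miniature saccade trace with exactly known structure.
test_staircase <- function(fs = 240, dwell = 2, n_steps = 10, level = 0.4) {
  t <- seq(0, n_steps * dwell, by = 1 / fs)
  x <- numeric(length(t))
  lvl <- 0
  for (k in seq_len(n_steps - 1)) {
    target <- if (k %% 2 == 1) level else 0
    u <- pmin(pmax((t - k * dwell) / 0.04, 0), 1)
    x <- x + (target - lvl) * (1 - cos(pi * u)) / 2
    lvl <- target
  }
  list(time = t, x = x, fs = fs)
}

# Add one raised-cosine blink bump (returns exactly to baseline).
add_blink <- function(x, fs, at_s, dur_s = 0.15, amp = 0.3) {
  t <- (seq_along(x) - 1) / fs
  u <- (t - at_s) / dur_s
  inside <- u >= 0 & u <= 1
  x[inside] <- x[inside] + amp * (1 - cos(2 * pi * u[inside])) / 2
  x
}
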