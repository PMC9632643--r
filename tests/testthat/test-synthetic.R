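test_that("schedules have the task structure: trials, jumps, dwells, balance", {
  sch <- generate_schedule(n_trials = 20, amplitude_deg = 16,
                           dwell_bounds = c(1.3, 2), seed = 11)
  expect_s3_class(sch, "target_schedule")
  expect_length(sch$trial_directions, 20)
  expect_equal(nrow(sch$jumps), 40)           # centre->periphery->centre
  expect_true(all(sch$dwell_durations >= 1.3 & sch$dwell_durations <= 2))
  expect_true(all(diff(sch$onset_times) > 0))
  expect_lte(abs(sum(sch$trial_directions == "left") -
                 sum(sch$trial_directions == "right")), 1)
  expect_equal(sch$total_duration, sum(sch$dwell_durations))
  # peripheral jumps alternate with returns to centre
  expect_true(all(sch$jumps$position_deg[seq(2, 40, by = 2)] == 0))
  expect_true(all(abs(sch$jumps$position_deg[seq(1, 39, by = 2)]) == 16))
})

test_that("degenerate dwell interval gives exact dwells; single trial works", {
  sch <- generate_schedule(n_trials = 1, dwell_bounds = c(1.5, 1.5), seed = 2)
  expect_length(sch$trial_directions, 1)
  expect_equal(sch$dwell_durations, rep(1.5, 3))
})

test_that("schedules are reproducible under a seed and vary across seeds", {
  expect_identical(generate_schedule(seed = 7), generate_schedule(seed = 7))
  dirs <- vapply(1:100, function(s) {
    paste(generate_schedule(seed = s)$trial_directions, collapse = "")
  }, character(1))
  expect_gt(length(unique(dirs)), 90)
})

test_that("invalid schedule parameters error", {
  expect_error(generate_schedule(n_trials = 0), "n_trials")
  expect_error(generate_schedule(dwell_bounds = c(2, 1)), "dwell_bounds")
  expect_error(generate_schedule(amplitude_deg = -1), "amplitude_deg")
})

test_that("noiseless control recording is a flat staircase between saccades", {
  sch <- generate_schedule(seed = 3)
  rec <- simulate_recording(sch, pure_profile(), seed = 5)
  expect_equal(length(rec$left_x), round(240 * 42))
  expect_equal(length(rec$right_x), length(rec$left_x))
  jumps <- sch$jumps$time[sch$jumps$time < 42]
  step_nic <- 0.4
  # outside [jump, jump + latency + saccade duration + margin] the trace is
  # exactly constant (raised-cosine transitions have compact support)
  segs <- cbind(c(0, jumps + 0.35), c(jumps, 42))
  wobble <- vapply(seq_len(nrow(segs)), function(i) {
    sel <- rec$time >= segs[i, 1] & rec$time < segs[i, 2]
    if (sum(sel) < 2) return(0)
    diff(range(rec$left_x[sel]))
  }, numeric(1))
  expect_lt(max(wobble), 1e-9 * step_nic)
})

test_that("measured primary gains recover the profile gain within 1%", {
  sch <- generate_schedule(seed = 9)
  prof <- pure_profile(gain = 0.95, gain_sd = 0.005)
  rec <- simulate_recording(sch, prof, duration = 70, seed = 13,
                            on_overrun = "error")
  jumps <- sch$jumps
  deg2nic <- 0.4 / 16
  lvl_at <- function(tm) rec$left_x[which.min(abs(rec$time - tm))]
  gains <- vapply(seq_len(nrow(jumps)), function(i) {
    before <- lvl_at(jumps$time[i] + 0.15)        # after jump, before saccade
    after <- lvl_at(jumps$time[i] + 0.45)         # after saccade settles
    tgt <- jumps$position_deg[i] * deg2nic
    (after - before) / (tgt - before)
  }, numeric(1))
  expect_lt(abs(mean(gains) - 0.95), 0.01 * 0.95)
})

test_that("hypermetric primary saccades overshoot by the configured gain", {
  sch <- generate_schedule(seed = 21)
  prof <- pure_profile("dysmetric", "hypermetric", gain = 1.25)
  rec <- simulate_recording(sch, prof, duration = 70, seed = 2,
                            on_overrun = "error")
  jumps <- sch$jumps
  deg2nic <- 0.4 / 16
  lvl_at <- function(tm) rec$left_x[which.min(abs(rec$time - tm))]
  # primary landing (before the corrective saccade) overshoots by ~25%
  over <- vapply(seq_len(nrow(jumps)), function(i) {
    before <- lvl_at(jumps$time[i] + 0.15)
    peak <- lvl_at(jumps$time[i] + 0.29)          # after primary, before corrective
    tgt <- jumps$position_deg[i] * deg2nic
    (peak - before) / (tgt - before)
  }, numeric(1))
  expect_equal(mean(over), 1.25, tolerance = 0.02)
  # and the corrective saccade moves the eye back toward the target
  settled <- vapply(seq_len(nrow(jumps)), function(i) {
    before <- lvl_at(jumps$time[i] + 0.15)
    after <- lvl_at(jumps$time[i] + 0.8)
    tgt <- jumps$position_deg[i] * deg2nic
    abs(after - tgt) < abs(before + 1.25 * (tgt - before) - tgt)
  }, logical(1))
  expect_true(mean(settled) > 0.9)
})

test_that("blink counts follow the Poisson event model", {
  lambda <- 12 * 20 / 60                          # rate 12/min for 20 s
  sch <- generate_schedule(n_trials = 5, seed = 1)
  prof <- control_profile(blink_rate = 12, noise_sd = 0, drift_amplitude = 0)
  counts <- vapply(1:200, function(s) {
    nrow(simulate_recording(sch, prof, duration = 20, seed = s)$blinks)
  }, numeric(1))
  expect_lt(abs(mean(counts) - lambda), 2 * sqrt(lambda / 200))
})

test_that("blink excursions return to the pre-blink baseline", {
  sch <- generate_schedule(seed = 4)
  prof <- control_profile(blink_rate = 10, noise_sd = 0.005,
                          drift_amplitude = 0)
  rec <- simulate_recording(sch, prof, seed = 6)
  expect_gt(nrow(rec$blinks), 0)
  fs <- rec$fs
  for (i in seq_len(nrow(rec$blinks))) {
    i0 <- round(rec$blinks$time[i] * fs)
    i1 <- round((rec$blinks$time[i] + rec$blinks$duration[i]) * fs) + 2L
    # blink waveform itself is closed: trace minus blink-free twin vanishes
    # at both edges of the event
    resid <- rec$left_x - rec$left_clean
    expect_lt(abs(resid[max(1, i0 - 1)]), 1e-9)
    expect_lt(abs(resid[min(length(resid), i1 + 1)]), 1e-9)
  }
})

test_that("recording simulation validates inputs", {
  sch <- generate_schedule(seed = 1)
  expect_error(simulate_recording(sch, pure_profile(), fs = -1), "positive")
  expect_error(simulate_recording(sch, pure_profile(), duration = 0), "positive")
  expect_error(
    simulate_recording(sch, pure_profile(), duration = 42, on_overrun = "error"),
    "at least")
})

test_that("profile invariants are enforced", {
  expect_error(control_profile(primary_gain_mean = 1.05), "0.90, 0.98")
  expect_error(subject_profile("control", "hypometric"), "none")
  expect_error(dysmetric_profile("hypometric", primary_gain_mean = 0.9), "0.85")
  expect_error(dysmetric_profile("hypermetric", primary_gain_mean = 1.0), "1.10")
  expect_error(control_profile(noise_sd = -1), "non-negative")
})

test_that("cohorts have requested sizes, labels, and mode diversity", {
  recs <- generate_cohort(8, 5, duration = 10, n_trials = 2, seed = 3)
  expect_length(recs, 13)
  labs <- attr(recs, "labels")
  expect_equal(sum(labs == "dysmetric"), 8)
  expect_equal(sum(labs == "control"), 5)
  modes <- vapply(recs[1:8], function(r) r$profile$dysmetria_mode, character(1))
  expect_gt(length(unique(modes)), 1)
  one <- generate_cohort(0, 1, duration = 10, n_trials = 2, seed = 1)
  expect_length(one, 1)
  expect_equal(attr(one, "labels")[[1]], "control")
  expect_error(generate_cohort(-1, 2), "non-negative")
})

test_that("cohort generation is deterministic under a fixed seed", {
  a <- generate_cohort(2, 2, duration = 12, n_trials = 3, seed = 17)
  b <- generate_cohort(2, 2, duration = 12, n_trials = 3, seed = 17)
  expect_identical(lapply(a, `[[`, "left_x"), lapply(b, `[[`, "left_x"))
  expect_identical(lapply(a, `[[`, "right_x"), lapply(b, `[[`, "right_x"))
})

test_that("recordings round-trip through the CSV + sidecar dialect", {
  dir <- withr::local_tempdir()
  recs <- generate_cohort(1, 1, duration = 10, n_trials = 2, seed = 5)
  write_cohort(recs, dir)
  back <- read_cohort(dir)
  expect_setequal(names(back), names(recs))
  for (id in names(recs)) {
    expect_equal(back[[id]]$left_x, recs[[id]]$left_x, tolerance = 1e-12)
    expect_equal(back[[id]]$label, recs[[id]]$label)
    expect_equal(back[[id]]$fs, recs[[id]]$fs)
  }
})
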