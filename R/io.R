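#' Write / read gaze recordings as CSV + JSON sidecar
#'
#' The on-disk dialect is a per-subject CSV with header
#' `time,left_x,right_x` plus a sidecar JSON (same basename, `.json`)
#' holding the sampling rate, label, and -- when present -- the subject
#' profile and target schedule.
#'
#' @param recording a `gaze_recording`.
#' @param path CSV file path (`.csv`; the sidecar replaces the extension
#'   with `.json`).
#' @return `write_recording()` returns `path` invisibly;
#'   `read_recording()` returns a `gaze_recording`.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "gaze_recording"))
  utils::write.csv(data.frame(time = recording$time,
                              left_x = recording$left_x,
                              right_x = recording$right_x),
                   path, row.names = FALSE)
  side <- list(fs = recording$fs, duration = recording$duration,
               label = recording$label)
  if (!is.null(recording$profile)) {
    side$profile <- unclass(recording$profile)
  }
  if (!is.null(recording$schedule)) {
    s <- recording$schedule
    side$schedule <- list(trial_directions = s$trial_directions,
                          onset_times = s$onset_times,
                          dwell_durations = s$dwell_durations,
                          amplitude_deg = s$amplitude_deg, fs = s$fs,
                          total_duration = s$total_duration,
                          jumps = s$jumps)
  }
  jsonlite::write_json(side, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("time", "left_x", "right_x") %in% names(tab))) {
    stop("recording CSV must have columns time, left_x, right_x", call. = FALSE)
  }
  side_path <- sub("\\.csv$", ".json", path)
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path,
                                                          simplifyVector = TRUE)
          else list()
  fs <- side$fs %||% (1 / stats::median(diff(tab$time)))
  rec <- list(fs = fs,
              duration = side$duration %||% (nrow(tab) / fs),
              time = tab$time, left_x = tab$left_x, right_x = tab$right_x,
              label = side$label)
  if (!is.null(side$schedule)) {
    sch <- side$schedule
    rec$schedule <- structure(sch, class = "target_schedule")
  }
  if (!is.null(side$profile)) {
    rec$profile <- structure(side$profile, class = "subject_profile")
  }
  structure(rec, class = "gaze_recording")
}

#' Write / read a whole cohort directory
#'
#' @param recordings named list of `gaze_recording`s.
#' @param dir directory (created if needed).
#' @return `write_cohort()` returns the file paths invisibly;
#'   `read_cohort()` a named list of recordings.
#' @export
write_cohort <- function(recordings, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- names(recordings) %||% paste0("subj_", seq_along(recordings))
  paths <- file.path(dir, paste0(ids, ".csv"))
  for (i in seq_along(recordings)) write_recording(recordings[[i]], paths[i])
  invisible(paths)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  paths <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (!length(paths)) stop("no recording CSVs in ", dir, call. = FALSE)
  recs <- lapply(paths, read_recording)
  names(recs) <- sub("\\.csv$", "", basename(paths))
  recs
}
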