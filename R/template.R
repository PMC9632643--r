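#' Ideal saccade template
#'
#' The matched-filter reference waveform: a centre-to-target-and-back
#' pulse -- zero baseline, smooth sigmoidal rise to +0.5 over `rise_s`,
#' hold for `hold_s` (default 1.5 s, the midpoint of the 1.3-2 s target
#' dwell), and smooth return to zero. The stored samples peak at 0.5; the
#' matched filter normalizes energy internally.
#'
#' @param fs sampling rate, Hz.
#' @param hold_s plateau duration, seconds.
#' @param rise_s rise/fall duration, seconds.
#' @return Object of class `saccade_template`.
#' @export
#' @examples
#' tpl <- ideal_template(240)
#' max(tpl$samples)
ideal_template <- function(fs, hold_s = 1.5, rise_s = 0.05) {
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  if (hold_s < 0 || rise_s < 0) stop("durations must be non-negative", call. = FALSE)
  total <- 2 * rise_s + hold_s
  t <- seq(0, total, by = 1 / fs)
  up <- if (rise_s > 0) smooth_step(t, 0, rise_s) else as.numeric(t >= 0)
  down <- if (rise_s > 0) smooth_step(t, rise_s + hold_s, rise_s) else
    as.numeric(t >= rise_s + hold_s)
  structure(list(samples = 0.5 * (up - down), fs = fs,
                 hold_s = hold_s, rise_s = rise_s),
            class = "saccade_template")
}

# Zero-normalized cross-correlation of x with template h at every window
# position: equivalent to the Pearson correlation between each length-L
# window of x and h, hence invariant to local offset and scale.
zncc <- function(x, h) {
  n <- length(x)
  L <- length(h)
  h0 <- h - mean(h)
  eh <- sqrt(sum(h0^2))
  # convolve(x, y, type = "filter") is the sliding dot product
  # num[t] = sum_k x[t + k - 1] * y[k].
  num <- as.numeric(stats::convolve(x, h0, type = "filter"))
  ones <- rep(1, L)
  s1 <- as.numeric(stats::convolve(x, ones, type = "filter"))
  s2 <- as.numeric(stats::convolve(x^2, ones, type = "filter"))
  varw <- pmax(s2 - s1^2 / L, 0)
  den <- sqrt(varw) * eh
  out <- numeric(length(num))
  ok <- den > 1e-12 * eh
  out[ok] <- num[ok] / den[ok]
  out
}

# Local extrema (strict rises into, non-rises out of) with a detection
# floor relative to the strongest candidate and greedy minimum separation
# (keep larger values first). Returns indices sorted by time.
find_peaks <- function(v, min_sep, min_frac = 0) {
  n <- length(v)
  if (n < 3) return(integer(0))
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  cand <- cand[v[cand] > 0]
  if (length(cand) && min_frac > 0) {
    cand <- cand[v[cand] >= min_frac * max(v[cand])]
  }
  if (!length(cand)) return(integer(0))
  ord <- cand[order(v[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Matched-filter template similarity score
#'
#' Correlates the band-passed, normalized gaze trace with the ideal
#' saccade template (zero-normalized cross-correlation, so the score is
#' unitless in \[-1, 1\] and invariant to local offset and scale). Every 42-s
#' task contains at least four leftward and four rightward
#' centre-periphery-centre excursions, so the score averages the first
#' four positive correlation peaks and the first four absolute negative
#' troughs in temporal order (peaks at rightward excursions, troughs at
#' leftward ones, or vice versa; `select = "largest"` instead takes the
#' strongest four of each sign). Fewer than four on either side are used
#' as available and flagged.
#'
#' @param x numeric vector: 0.08-5 Hz band-passed, range-normalized trace.
#' @param template a [ideal_template()]; default is built at `fs`.
#' @param fs sampling rate, Hz.
#' @param min_separation minimum peak separation in seconds (default 1.3,
#'   the shortest target dwell).
#' @param n_extrema extrema retained per sign (default 4).
#' @param select `"temporal"` (first `n_extrema` in time, default) or
#'   `"largest"` (the `n_extrema` strongest per sign).
#' @param min_peak_frac detection floor: candidate extrema below this
#'   fraction of the strongest same-sign extremum are treated as noise,
#'   not saccade detections (default 0.5).
#' @return Object of class `template_score`: list with `score` (mean of
#'   the selected extrema), `peak_times`/`trough_times` (s, window
#'   centres), `peak_values`/`trough_values`, and `incomplete` (TRUE if
#'   fewer than `n_extrema` extrema were available on either side).
#' @export
matched_filter_score <- function(x, template = NULL, fs,
                                 min_separation = 1.3, n_extrema = 4,
                                 select = c("temporal", "largest"),
                                 min_peak_frac = 0.5) {
  select <- match.arg(select)
  stop_if_not_numeric(x)
  if (is.null(template)) template <- ideal_template(fs)
  stopifnot(inherits(template, "saccade_template"))
  h <- template$samples
  if (length(x) <= length(h)) {
    stop("`x` must be longer than the template", call. = FALSE)
  }
  cc <- zncc(x, h)
  sep <- round(min_separation * fs)
  pk <- find_peaks(cc, sep, min_peak_frac)
  tr <- find_peaks(-cc, sep, min_peak_frac)
  pick <- function(idx, v) {
    if (select == "largest" && length(idx) > n_extrema) {
      idx <- sort(idx[order(v[idx], decreasing = TRUE)][seq_len(n_extrema)])
    }
    utils::head(idx, n_extrema)
  }
  pk_sel <- pick(pk, cc)
  tr_sel <- pick(tr, -cc)
  incomplete <- length(pk_sel) < n_extrema || length(tr_sel) < n_extrema
  if (incomplete) {
    warning("fewer than ", n_extrema,
            " matched-filter extrema available on one side", call. = FALSE)
  }
  vals <- c(cc[pk_sel], abs(cc[tr_sel]))
  centre <- (length(h) - 1) / 2
  structure(list(
    score = if (length(vals)) mean(vals) else NA_real_,
    peak_times = (pk_sel - 1 + centre) / fs,
    trough_times = (tr_sel - 1 + centre) / fs,
    peak_values = cc[pk_sel],
    trough_values = cc[tr_sel],
    incomplete = incomplete
  ), class = "template_score")
}

#' @export
print.template_score <- function(x, ...) {
  cat(sprintf("<template_score> %.4f (%d peaks, %d troughs%s)\n", x$score,
              length(x$peak_values), length(x$trough_values),
              if (x$incomplete) ", incomplete" else ""))
  invisible(x)
}

#' Threshold-based surface area
#'
#' Area between the gaze curve and fixed amplitude thresholds: the area of
#' the signal above `thr_pos` plus the area below `thr_neg`, by
#' trapezoidal integration, in amplitude x seconds. Hypermetric saccades
#' produce sharp peaked excursions that spend little time beyond the
#' thresholds, so dysmetric recordings yield smaller areas than the
#' sustained plateaus of accurate saccades.
#'
#' @param x numeric vector, band-passed and normalized to \[-0.5, +0.5\].
#' @param fs sampling rate, Hz.
#' @param thr_pos,thr_neg thresholds, defaults +0.35 / -0.35; must satisfy
#'   `-0.5 <= thr_neg < 0 < thr_pos <= 0.5`.
#' @return Area (amplitude x seconds).
#' @export
#' @examples
#' threshold_surface(rep(0.5, 241), fs = 240) # 0.15 amplitude x 1 s
threshold_surface <- function(x, fs, thr_pos = 0.35, thr_neg = -0.35) {
  stop_if_not_numeric(x)
  if (!(thr_neg >= -0.5 && thr_neg < 0 && thr_pos > 0 && thr_pos <= 0.5)) {
    stop("thresholds must satisfy -0.5 <= thr_neg < 0 < thr_pos <= 0.5",
         call. = FALSE)
  }
  trapz_uniform(pmax(x - thr_pos, 0), 1 / fs) +
    trapz_uniform(pmax(thr_neg - x, 0), 1 / fs)
}
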