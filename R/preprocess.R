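#' Scale a signal to the range \[-0.5, +0.5\]
#'
#' Affine range normalization: the minimum maps to -0.5 and the maximum to
#' +0.5. Amplitude-sensitive features (template matching, threshold
#' surface, some connectivity indices) require a common amplitude scale;
#' dysmetria detection depends on amplitude *change*, not absolute
#' amplitude, so the raw NIC scale is discarded.
#'
#' @param x numeric vector, length >= 2, not constant.
#' @return Numeric vector with `min == -0.5` and `max == +0.5`.
#' @export
#' @examples
#' normalize_range(c(0, 5, 10))
normalize_range <- function(x) {
  stop_if_not_numeric(x)
  if (length(x) < 2L) stop("`x` must have length >= 2", call. = FALSE)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    stop("`x` is constant: range normalization is undefined", call. = FALSE)
  }
  (x - rng[1]) / (rng[2] - rng[1]) - 0.5
}

#' FIR band-pass filter specification
#'
#' @param band length-2 numeric, passband in Hz.
#' @param fs sampling rate, Hz.
#' @param order filter order (number of taps minus one), default 200.
#' @param window_kind taper applied to the sinc design; only `"hamming"`
#'   is provided.
#' @return Object of class `filter_spec` carrying the designed coefficients.
#' @export
filter_spec <- function(band, fs, order = 200, window_kind = "hamming") {
  if (length(band) != 2 || band[1] < 0 || band[2] <= band[1] ||
      band[2] >= fs / 2) {
    stop(sprintf("band [%s] Hz is infeasible at fs = %g Hz (need 0 <= lo < hi < fs/2)",
                 paste(band, collapse = ", "), fs), call. = FALSE)
  }
  if (order < 1) stop("`order` must be >= 1", call. = FALSE)
  window_kind <- match.arg(window_kind, "hamming")
  h <- signal::fir1(order, band / (fs / 2), type = "pass",
                    window = signal::hamming(order + 1))
  structure(list(band = band, fs = fs, order = order,
                 window_kind = window_kind, coefficients = as.numeric(h)),
            class = "filter_spec")
}

#' Apply a linear-phase FIR band-pass filter
#'
#' Single-pass application of the windowed-sinc filter in `spec`, with
#' group-delay compensation (the filter is linear phase, delay =
#' `order / 2` samples) and reflect padding by one filter length, so the
#' output is time-aligned with the input and of equal length.
#'
#' @param x numeric vector, longer than the filter order.
#' @param spec a [filter_spec()].
#' @return Filtered numeric vector, `length(x)`.
#' @export
#' @examples
#' fs <- 240
#' lowband <- filter_spec(c(0.08, 5), fs)
#' t <- seq(0, 10, by = 1 / fs)
#' y <- bandpass_fir(sin(2 * pi * 2 * t), lowband)
bandpass_fir <- function(x, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  stop_if_not_numeric(x)
  n <- length(x)
  h <- spec$coefficients
  L <- length(h)
  if (n <= spec$order) stop("`x` must be longer than the filter order", call. = FALSE)
  pad <- min(L, n - 1L)
  xp <- reflect_pad(x, L)
  # Full convolution; sample i of the aligned output corresponds to index
  # pad + i + delay of the full convolution (delay = order/2).
  conv <- stats::convolve(xp, rev(h), type = "open")
  delay <- round(spec$order / 2)
  conv[seq.int(pad + delay + 1, length.out = n)]
}

#' Remove eye blinks with a running-median comparison
#'
#' Computes an order-`median_order` running median `m(t)` and flags samples
#' whose deviation `|x - m|` exceeds `threshold_mad` times the median
#' absolute deviation of the residual. Flagged samples are grouped into
#' events; an event is treated as a blink only if the signal level after
#' the event returns to (within tolerance of) the level before it and the
#' event is shorter than `max_blink` seconds. Blink samples are replaced by
#' the running median. Excursions that do not return to their starting
#' level -- saccadic overshoots and undershoots, the very events the
#' analysis must keep -- are left untouched.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param median_order running-median order (window = order + 1 samples,
#'   forced odd), default 200.
#' @param threshold_mad deviation threshold in robust SDs, default 5.
#' @param max_blink maximum blink duration in seconds, default 0.5.
#' @param return_tol absolute tolerance for the pre/post level comparison;
#'   default `0.1 *` the robust signal range (5th-95th percentile span),
#'   a proxy for the local step size.
#' @param flank_s flank window for the pre/post level medians, seconds.
#' @return `x` with blink events replaced; attribute `"blinks"` holds a
#'   data frame of the replaced events (start/end sample).
#' @export
remove_blinks <- function(x, fs, median_order = 200, threshold_mad = 5,
                          max_blink = 0.5, return_tol = NULL,
                          flank_s = 0.05) {
  stop_if_not_numeric(x)
  n <- length(x)
  if (median_order >= n) stop("`median_order` must be below length(x)", call. = FALSE)
  k <- median_order + 1L
  if (k %% 2L == 0L) k <- k + 1L
  xp <- reflect_pad(x, k)
  pad <- min(k, n - 1L)
  m <- stats::runmed(xp, k)[seq.int(pad + 1L, length.out = n)]
  resid <- x - m
  sigma <- stats::mad(resid)
  if (sigma == 0) sigma <- stats::sd(resid)
  events <- data.frame(start = integer(0), end = integer(0))
  out <- x
  if (is.null(return_tol)) {
    q <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
    return_tol <- 0.1 * (q[2] - q[1])
  }
  if (sigma > 0) {
    flagged <- abs(resid) > threshold_mad * sigma
    # merge flagged runs separated by < 25 ms into one event
    gap <- max(1L, round(0.025 * fs))
    r <- rle(flagged)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    runs <- data.frame(start = idx_start[r$values], end = idx_end[r$values])
    # hysteresis: grow each event outward while the deviation stays above
    # a lower threshold, so the full excursion (not just its tip) is covered
    lo <- threshold_mad / 5 * sigma
    for (i in seq_len(nrow(runs))) {
      s <- runs$start[i]
      while (s > 1L && abs(resid[s - 1L]) > lo) s <- s - 1L
      e <- runs$end[i]
      while (e < n && abs(resid[e + 1L]) > lo) e <- e + 1L
      runs$start[i] <- s; runs$end[i] <- e
    }
    if (nrow(runs) > 1) {
      keep <- list(runs[1, ])
      for (i in 2:nrow(runs)) {
        last <- keep[[length(keep)]]
        if (runs$start[i] - last$end <= gap) {
          keep[[length(keep)]]$end <- runs$end[i]
        } else {
          keep[[length(keep) + 1]] <- runs[i, ]
        }
      }
      runs <- do.call(rbind, keep)
    }
    flank <- max(1L, round(flank_s * fs))
    for (i in seq_len(nrow(runs))) {
      s <- runs$start[i]; e <- runs$end[i]
      if ((e - s + 1) / fs > max_blink) next
      pre_i <- max(1L, s - flank):max(1L, s - 1L)
      post_i <- min(n, e + 1L):min(n, e + flank)
      pre <- stats::median(x[pre_i])
      post <- stats::median(x[post_i])
      if (abs(pre - post) <= return_tol) {
        out[s:e] <- m[s:e]
        events <- rbind(events, data.frame(start = s, end = e))
      }
    }
  }
  attr(out, "blinks") <- events
  out
}

#' Relative power spectral density
#'
#' Welch averaged-periodogram estimate (Hamming-tapered overlapping
#' segments), normalized so the relative power sums to one over the
#' evaluated band 0 to fs/2.
#'
#' @param x numeric vector, length >= 256.
#' @param fs sampling rate, Hz.
#' @param seg_s segment length in seconds (default 4).
#' @param overlap fractional segment overlap (default 0.5).
#' @return Object of class `relative_spectrum`: list with `frequencies`
#'   (Hz) and `relative_power` (sums to 1).
#' @export
relative_psd <- function(x, fs, seg_s = 4, overlap = 0.5) {
  stop_if_not_numeric(x)
  if (length(x) < 256L) stop("`x` must have length >= 256", call. = FALSE)
  w <- welch_csd(x, fs = fs, seg_s = seg_s, overlap = overlap)
  structure(list(frequencies = w$frequencies,
                 relative_power = w$sxx / sum(w$sxx)),
            class = "relative_spectrum")
}

#' Preprocess one channel for a given analysis band
#'
#' The per-subject preprocessing chain: range-normalize, band-pass filter,
#' remove blinks, and re-normalize the band signal to \[-0.5, +0.5\] (the
#' amplitude convention the template and threshold statistics assume).
#'
#' @param x raw channel.
#' @param spec a [filter_spec()].
#' @param config a [default_config()] list (median filter and blink
#'   parameters are read from it).
#' @return Preprocessed numeric vector.
#' @export
preprocess_channel <- function(x, spec, config = default_config()) {
  x <- normalize_range(x)
  x <- bandpass_fir(x, spec)
  x <- remove_blinks(x, fs = spec$fs, median_order = config$median_order,
                     threshold_mad = config$blink$threshold_mad,
                     max_blink = config$blink$max_blink,
                     flank_s = config$blink$flank_s)
  normalize_range(as.numeric(x))
}
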