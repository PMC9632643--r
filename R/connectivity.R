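#' Linear (Pearson) correlation between the two eyes
#'
#' @param x,y equal-length numeric vectors (length >= 3), non-constant.
#' @return Pearson product-moment coefficient in `[-1, 1]`.
#' @export
linear_correlation <- function(x, y) {
  stop_if_not_numeric(x); stop_if_not_numeric(y)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: correlation undefined", call. = FALSE)
  }
  stats::cor(x, y)
}

# One direction of the binned nonlinear regression index: fraction of
# var(y) explained by a piecewise-linear regression of y on x over
# equal-count bins (a least-squares line per bin; degenerate bins fall
# back to the bin mean).
h2_directed <- function(x, y, n_bins) {
  n <- length(x)
  ord <- order(x)
  bin <- ceiling(seq_len(n) / (n / n_bins))[order(ord)]  # bin of each sample
  if (length(unique(bin)) < 2) {
    stop("too few distinct bins for the h2 regression", call. = FALSE)
  }
  pred <- numeric(n)
  for (b in unique(bin)) {
    sel <- bin == b
    xb <- x[sel]; yb <- y[sel]
    vx <- stats::var(xb)
    if (length(xb) >= 2 && vx > 0) {
      slope <- stats::cov(xb, yb) / vx
      pred[sel] <- mean(yb) + slope * (xb - mean(xb))
    } else {
      pred[sel] <- mean(yb)
    }
  }
  vy <- stats::var(y)
  max(0, min(1, 1 - stats::var(y - pred) / vy))
}

#' Nonlinear correlation index h2
#'
#' The classic nonparametric h2 association index: `x` is split into
#' `n_bins` equal-count bins, `y` is regressed on `x` piecewise-linearly
#' (a least-squares segment per bin), and h2 is the explained variance
#' fraction `(var(y) - var(resid)) / var(y)`, clipped to `[0, 1]`. The index is
#' symmetrized as the maximum over both directions, so it captures any
#' (possibly non-monotone) functional dependence between the eyes.
#'
#' @param x,y equal-length numeric vectors.
#' @param n_bins number of bins (default 10).
#' @return h2 in `[0, 1]`.
#' @export
#' @examples
#' x <- rnorm(2000); nonlinear_correlation_h2(x, x^3)
nonlinear_correlation_h2 <- function(x, y, n_bins = 10) {
  stop_if_not_numeric(x); stop_if_not_numeric(y)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (n_bins < 2) stop("`n_bins` must be >= 2", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("constant input: h2 undefined", call. = FALSE)
  }
  max(h2_directed(x, y, n_bins), h2_directed(y, x, n_bins))
}

#' Band-averaged magnitude-squared coherence
#'
#' Welch estimator: Hamming-tapered overlapping segments (default 4 s,
#' 50% overlap), magnitude-squared coherence
#' `|Sxy|^2 / (Sxx * Syy)` per frequency bin, averaged over the bins
#' inside `band`.
#'
#' @param x,y equal-length numeric vectors; length must cover at least 4
#'   segments.
#' @param fs sampling rate, Hz.
#' @param band length-2 numeric, averaging band in Hz, inside `(0, fs/2)`.
#' @param seg_s,overlap Welch segmentation (seconds, fraction).
#' @return Mean coherence in `[0, 1]` over the band.
#' @export
band_coherence <- function(x, y, fs, band, seg_s = 4, overlap = 0.5) {
  stop_if_not_numeric(x); stop_if_not_numeric(y)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (band[1] <= 0 || band[2] <= band[1] || band[2] >= fs / 2) {
    stop("`band` must lie inside (0, fs/2)", call. = FALSE)
  }
  L <- round(seg_s * fs)
  if (length(x) < 4 * L) {
    stop("`x` must cover at least 4 Welch segments", call. = FALSE)
  }
  w <- welch_csd(x, y, fs = fs, seg_s = seg_s, overlap = overlap)
  coh <- Mod(w$sxy)^2 / (w$sxx * w$syy)
  sel <- w$frequencies >= band[1] & w$frequencies <= band[2]
  if (!any(sel)) stop("no frequency bins inside `band`", call. = FALSE)
  mean(coh[sel])
}

# Residual sum of squares of a least-squares fit (rank-deficiency safe).
rss_fit <- function(X, y) {
  fit <- stats::.lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Granger causality index
#'
#' Time-domain linear Granger causality on (band-filtered) channels. For
#' direction x -> y, autoregressive models of `y` on its own past
#' (restricted) and on both pasts (full) are fitted by least squares on a
#' common sample; the model order is chosen by BIC up to `max_order`, and
#' the index is `ln(RSS_restricted / RSS_full)`, the log residual-variance
#' ratio (0 when the other channel adds no predictive information). The
#' returned value is the mean of the two directions; both directions and
#' the selected orders are kept as attributes.
#'
#' @param x,y equal-length numeric vectors, length >= 10 * max_order.
#' @param max_order maximum autoregressive order (default 20).
#' @return Symmetrized Granger index (>= 0 up to estimation noise) with
#'   attributes `xy`, `yx`, `order_xy`, `order_yx`.
#' @export
granger_index <- function(x, y, max_order = 20) {
  stop_if_not_numeric(x); stop_if_not_numeric(y)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 10 * max_order) stop("`x` too short for max_order = ", max_order, call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: Granger index undefined", call. = FALSE)
  }
  xs <- as.numeric(scale(x)); ys <- as.numeric(scale(y))

  one_direction <- function(from, to) {
    # common sample: drop max_order leading values
    emb_to <- stats::embed(to, max_order + 1L)
    emb_from <- stats::embed(from, max_order + 1L)
    yy <- emb_to[, 1L]
    nobs <- length(yy)
    best <- NULL
    for (p in seq_len(max_order)) {
      Xr <- cbind(1, emb_to[, 1L + seq_len(p), drop = FALSE])
      Xf <- cbind(Xr, emb_from[, 1L + seq_len(p), drop = FALSE])
      rss_r <- rss_fit(Xr, yy)
      rss_f <- rss_fit(Xf, yy)
      bic <- nobs * log(rss_f / nobs) + log(nobs) * (2 * p + 1)
      if (is.null(best) || bic < best$bic) {
        best <- list(bic = bic, p = p,
                     index = max(0, log(rss_r / rss_f)))
      }
    }
    best
  }

  xy <- one_direction(xs, ys)
  yx <- one_direction(ys, xs)
  structure(mean(c(xy$index, yx$index)),
            xy = xy$index, yx = yx$index,
            order_xy = xy$p, order_yx = yx$p)
}

#' All four left-right connectivity indices for one band
#'
#' @param x,y band-filtered left/right channels.
#' @param fs sampling rate, Hz.
#' @param band analysis band in Hz (used by the coherence average and
#'   recorded on the result).
#' @param config a [default_config()] list.
#' @return Object of class `connectivity_result`: list with `correlation`,
#'   `h2`, `coherence`, `granger` and `band`.
#' @export
connectivity_indices <- function(x, y, fs, band, config = default_config()) {
  cc <- config$connectivity
  structure(list(
    correlation = linear_correlation(x, y),
    h2 = nonlinear_correlation_h2(x, y, n_bins = cc$n_bins),
    coherence = band_coherence(x, y, fs, band, seg_s = cc$seg_s,
                               overlap = cc$overlap),
    granger = granger_index(x, y, max_order = cc$max_order),
    band = band
  ), class = "connectivity_result")
}
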