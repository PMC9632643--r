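#' Sample entropy
#'
#' SampEn(m, r): the negative natural logarithm of the conditional
#' probability that two subsequences similar for `m` points (Chebyshev
#' distance below `r` times the signal SD) remain similar at the next
#' point, self-matches excluded. Larger values indicate a more irregular
#' signal.
#'
#' @param x numeric vector, length >= 10 * m.
#' @param m embedding dimension (default 2).
#' @param r tolerance as a fraction of `sd(x)` (default 0.2).
#' @return SampEn value; `NA` with a warning when no template matches
#'   exist (the estimate is undefined).
#' @export
#' @examples
#' sample_entropy(sin(seq(0, 20 * pi, length.out = 2000)))
sample_entropy <- function(x, m = 2, r = 0.2) {
  stop_if_not_numeric(x)
  if (m < 1) stop("`m` must be >= 1", call. = FALSE)
  if (r <= 0) stop("`r` must be positive", call. = FALSE)
  if (length(x) < 10 * m) stop("`x` too short for m = ", m, call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) return(0) # constant series: perfectly predictable
  counts <- .sampen_counts(as.numeric(x), as.integer(m), r * s)
  if (counts[["A"]] == 0 || counts[["B"]] == 0) {
    warning("sample entropy undefined: no template matches", call. = FALSE)
    return(NA_real_)
  }
  -log(counts[["A"]] / counts[["B"]])
}

#' Local fuzzy entropy
#'
#' A fuzzy-membership modification of sample entropy: embedding vectors
#' are locally centred (each minus its own mean) and the Heaviside match
#' criterion is replaced by the fuzzy similarity
#' `exp(-(d / r)^fuzzy_power)`, giving a smooth, more stable estimate on
#' short noisy series.
#'
#' @inheritParams sample_entropy
#' @param fuzzy_power exponent of the fuzzy membership function (default 2).
#' @return LocFuzEn value.
#' @export
local_fuzzy_entropy <- function(x, m = 2, r = 0.2, fuzzy_power = 2) {
  stop_if_not_numeric(x)
  if (m < 1) stop("`m` must be >= 1", call. = FALSE)
  if (r <= 0 || fuzzy_power <= 0) {
    stop("`r` and `fuzzy_power` must be positive", call. = FALSE)
  }
  if (length(x) < 10 * m) stop("`x` too short for m = ", m, call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) return(0)
  phis <- .locfuzen_phis(as.numeric(x), as.integer(m), r * s, fuzzy_power)
  -log(phis[["phi_m1"]] / phis[["phi_m"]])
}

# Map a series to dispersion classes 1..c via the normal CDF fitted to
# (mu, sigma), then round-half-up linear quantization.
dispersion_classes <- function(x, c, mu, sigma) {
  y <- stats::pnorm(x, mu, sigma)
  pmin(pmax(floor(c * y + 1), 1L), as.integer(c))
}

# Delayed embedding indices as an (n_vectors x m) matrix of x positions.
delay_embed <- function(n, m, d) {
  nv <- n - (m - 1L) * d
  if (nv < 1L) stop("series too short for the requested embedding", call. = FALSE)
  outer(seq_len(nv), (seq_len(m) - 1L) * d, `+`)
}

#' Dispersion entropy
#'
#' Shannon entropy (natural log) of the empirical distribution of
#' dispersion patterns: the signal is mapped through the normal CDF
#' (fitted mean/SD) into `c` classes and overlapping `m`-length delayed
#' class vectors are tallied over the `c^m` possible patterns.
#'
#' @param x numeric vector.
#' @param m embedding dimension (default 2).
#' @param c number of classes (default 6).
#' @param d embedding delay (default 1).
#' @param mu,sigma optional normal-CDF parameters; default fitted to `x`.
#'   Multiscale profiles fix these at scale 1 and reuse them.
#' @return DispEn value in `[0, m * log(c)]`.
#' @export
#' @examples
#' dispersion_entropy(rnorm(1000))
dispersion_entropy <- function(x, m = 2, c = 6, d = 1, mu = NULL, sigma = NULL) {
  stop_if_not_numeric(x)
  if (c < 2) stop("`c` must be >= 2", call. = FALSE)
  if (m < 1 || d < 1) stop("`m` and `d` must be >= 1", call. = FALSE)
  n <- length(x)
  if (n <= (m - 1) * d + 1) stop("`x` too short for the embedding", call. = FALSE)
  if (is.null(mu)) mu <- mean(x)
  if (is.null(sigma)) sigma <- stats::sd(x)
  if (sigma == 0) stop("`x` has zero variance: dispersion mapping degenerate",
                       call. = FALSE)
  if (n - (m - 1) * d < 10 * c^m) {
    warning("fewer than 10 * c^m dispersion vectors: estimate may be unreliable",
            call. = FALSE)
  }
  z <- dispersion_classes(x, c, mu, sigma)
  idx <- delay_embed(n, m, d)
  codes <- matrix(z[idx], nrow = nrow(idx)) %*% c^(seq_len(m) - 1L)
  p <- tabulate(as.integer(factor(codes)))
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Fluctuation-based dispersion entropy
#'
#' As [dispersion_entropy()], but each pattern is the vector of `m - 1`
#' successive class differences (values in `-(c-1) .. c-1`), so the
#' statistic reflects the variability of fluctuations rather than of
#' levels.
#'
#' @inheritParams dispersion_entropy
#' @return FDispEn value in `[0, (m - 1) * log(2c - 1)]`.
#' @export
fluctuation_dispersion_entropy <- function(x, m = 2, c = 6, d = 1,
                                           mu = NULL, sigma = NULL) {
  stop_if_not_numeric(x)
  if (m < 2) stop("`m` must be >= 2 for fluctuation patterns", call. = FALSE)
  if (c < 2) stop("`c` must be >= 2", call. = FALSE)
  if (d < 1) stop("`d` must be >= 1", call. = FALSE)
  n <- length(x)
  if (n <= (m - 1) * d + 1) stop("`x` too short for the embedding", call. = FALSE)
  if (is.null(mu)) mu <- mean(x)
  if (is.null(sigma)) sigma <- stats::sd(x)
  if (sigma == 0) stop("`x` has zero variance: dispersion mapping degenerate",
                       call. = FALSE)
  z <- dispersion_classes(x, c, mu, sigma)
  idx <- delay_embed(n, m, d)
  zm <- matrix(z[idx], nrow = nrow(idx))
  dz <- zm[, -1L, drop = FALSE] - zm[, -m, drop = FALSE] # in -(c-1)..(c-1)
  base <- 2L * c - 1L
  codes <- (dz + (c - 1L)) %*% base^(seq_len(m - 1L) - 1L)
  p <- tabulate(as.integer(factor(codes)))
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Higuchi fractal dimension
#'
#' Estimates the fractal dimension of a time series from the scaling of
#' the Higuchi curve length L(k) over lags `k = 1..kmax`: FD is the
#' negative least-squares slope of `log L(k)` versus `log k`. Smooth
#' curves give FD near 1; uncorrelated noise approaches 2.
#'
#' @param x numeric vector, length >= 10 * kmax.
#' @param kmax maximum lag (default 10).
#' @return FD estimate, typically in `[1, 2]`.
#' @export
#' @examples
#' higuchi_fd(seq_len(500)) # straight line: FD ~ 1
higuchi_fd <- function(x, kmax = 10) {
  stop_if_not_numeric(x)
  n <- length(x)
  if (kmax < 2) stop("`kmax` must be >= 2", call. = FALSE)
  if (n < 10 * kmax) stop("`x` too short for kmax = ", kmax, call. = FALSE)
  lk <- vapply(seq_len(kmax), function(k) {
    lm_k <- vapply(seq_len(k), function(m0) {
      idx <- seq.int(m0, n, by = k)
      nm <- length(idx)
      if (nm < 2) return(NA_real_)
      norm <- (n - 1) / ((nm - 1) * k)
      sum(abs(diff(x[idx]))) * norm / k
    }, numeric(1))
    mean(lm_k, na.rm = TRUE)
  }, numeric(1))
  fit <- stats::lm.fit(cbind(1, log(seq_len(kmax))), log(lk))
  -unname(fit$coefficients[2])
}

#' Lempel-Ziv complexity
#'
#' Binarizes the series at its median and counts LZ76
#' exhaustive-parsing phrases C(n); returns the normalized complexity
#' `C(n) * log2(n) / n`, which approaches 1 for i.i.d. random binary
#' sequences. The raw phrase count is attached as attribute `"count"`.
#'
#' @param x numeric vector (length >= 100 recommended).
#' @return Normalized Lempel-Ziv complexity.
#' @export
lempel_ziv <- function(x) {
  stop_if_not_numeric(x)
  n <- length(x)
  if (n < 2) stop("`x` must have length >= 2", call. = FALSE)
  s <- as.integer(x > stats::median(x))
  cnt <- .lz76_count(s)
  structure(cnt * log2(n) / n, count = cnt)
}
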