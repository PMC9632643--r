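#' Coarse-grain a series at scale tau
#'
#' Non-overlapping window means: `y[j] = mean(x[(j-1)*tau + 1 .. j*tau])`,
#' the standard multiscale-entropy coarse-graining, which acts as a
#' low-pass filter with cutoff about `fs / (2 * tau)`.
#'
#' @param x numeric vector.
#' @param tau integer scale factor >= 1.
#' @return Numeric vector of length `floor(length(x) / tau)`.
#' @export
#' @examples
#' coarse_grain(c(1, 2, 3, 4), 2)
coarse_grain <- function(x, tau) {
  stop_if_not_numeric(x)
  tau <- as.integer(tau)
  if (tau < 1) stop("`tau` must be >= 1", call. = FALSE)
  n <- length(x)
  if (tau > n) stop("`tau` exceeds the series length", call. = FALSE)
  if (tau == 1L) return(x)
  nb <- n %/% tau
  colMeans(matrix(x[seq_len(nb * tau)], nrow = tau))
}

#' Multiscale complexity profile
#'
#' Computes a base irregularity measure on coarse-grained versions of the
#' signal at scales `1..tau_max`:
#' * `"mde"` -- multiscale dispersion entropy,
#' * `"mfe"` -- multiscale (local) fuzzy entropy,
#' * `"mfde"` -- multiscale fluctuation-based dispersion entropy.
#'
#' For MDE/MFDE the normal-CDF mapping parameters are fitted on the
#' original (scale-1) series and reused at every scale; for MFE the
#' tolerance `r` is likewise fixed from the scale-1 SD
#' (set `refit_per_scale = TRUE` to refit at each scale).
#'
#' @param x numeric vector.
#' @param measure `"mde"`, `"mfe"` or `"mfde"`.
#' @param m,c,d,r,fuzzy_power base-measure parameters (see
#'   [dispersion_entropy()], [local_fuzzy_entropy()]).
#' @param tau_max largest scale (default 10).
#' @param refit_per_scale refit the mapping at every scale (default FALSE).
#' @param band optional label (Hz) recorded on the result.
#' @return Object of class `multiscale_profile`: list with `measure`,
#'   `scales`, `values` (NA where the base measure failed, with the
#'   failure message in `flags`), and `band`.
#' @export
#' @examples
#' multiscale_profile(rnorm(3000), "mde", tau_max = 5)
multiscale_profile <- function(x, measure = c("mde", "mfe", "mfde"),
                               m = 2, c = 6, d = 1, r = 0.2, fuzzy_power = 2,
                               tau_max = 10, refit_per_scale = FALSE,
                               band = NULL) {
  measure <- match.arg(measure)
  stop_if_not_numeric(x)
  if (tau_max < 1) stop("`tau_max` must be >= 1", call. = FALSE)
  mu1 <- mean(x)
  sigma1 <- stats::sd(x)
  vals <- rep(NA_real_, tau_max)
  flags <- character(tau_max)
  for (tau in seq_len(tau_max)) {
    y <- coarse_grain(x, tau)
    res <- tryCatch({
      if (measure == "mde") {
        if (refit_per_scale) dispersion_entropy(y, m = m, c = c, d = d)
        else dispersion_entropy(y, m = m, c = c, d = d, mu = mu1, sigma = sigma1)
      } else if (measure == "mfde") {
        if (refit_per_scale) fluctuation_dispersion_entropy(y, m = m, c = c, d = d)
        else fluctuation_dispersion_entropy(y, m = m, c = c, d = d,
                                            mu = mu1, sigma = sigma1)
      } else {
        if (refit_per_scale || sigma1 == 0) {
          local_fuzzy_entropy(y, m = m, r = r, fuzzy_power = fuzzy_power)
        } else {
          # fixed absolute tolerance r * sd(scale-1 series)
          s_y <- stats::sd(y)
          if (s_y == 0) 0
          else local_fuzzy_entropy(y, m = m, r = r * sigma1 / s_y,
                                   fuzzy_power = fuzzy_power)
        }
      }
    }, error = function(e) e)
    if (inherits(res, "condition")) {
      flags[tau] <- conditionMessage(res)
    } else {
      vals[tau] <- res
    }
  }
  structure(list(measure = measure, scales = seq_len(tau_max),
                 values = vals, flags = flags, band = band),
            class = "multiscale_profile")
}

#' @export
print.multiscale_profile <- function(x, ...) {
  cat(sprintf("<multiscale_profile> %s, scales 1-%d%s\n", toupper(x$measure),
              length(x$scales),
              if (!is.null(x$band)) paste0(", band ",
                                           paste(x$band, collapse = "-"), " Hz")
              else ""))
  print(round(stats::setNames(x$values, paste0("s", x$scales)), 4))
  invisible(x)
}
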