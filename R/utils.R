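# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Deterministic child seed derivation; keeps results inside 32-bit range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 1299709) %% 2147483587) + 1L
}

stop_if_not_numeric <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || anyNA(x)) {
    stop(sprintf("`%s` must be a numeric vector without NA values", name),
         call. = FALSE)
  }
  invisible(x)
}

# Reflect-pad a series by `pad` samples on each side.
reflect_pad <- function(x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  c(x[(pad + 1L):2L], x, x[(n - 1L):(n - pad)])
}

# Welch averaged (cross-)spectral estimator: Hamming-tapered segments with
# overlap, per-segment demeaning. Returns one-sided auto spectra and, when
# `y` is given, the complex cross spectrum on the same frequency grid.
welch_csd <- function(x, y = NULL, fs, seg_s = 4, overlap = 0.5) {
  n <- length(x)
  L <- min(n, max(8L, round(seg_s * fs)))
  step <- max(1L, floor(L * (1 - overlap)))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * seq_len(L) / (L + 1))
  nf <- floor(L / 2) + 1L
  freqs <- (seq_len(nf) - 1L) * fs / L
  sxx <- numeric(nf)
  syy <- if (!is.null(y)) numeric(nf) else NULL
  sxy <- if (!is.null(y)) complex(nf) else NULL
  for (s in starts) {
    seg_x <- x[s:(s + L - 1L)]
    fx <- stats::fft((seg_x - mean(seg_x)) * w)[seq_len(nf)]
    sxx <- sxx + Re(fx * Conj(fx))
    if (!is.null(y)) {
      seg_y <- y[s:(s + L - 1L)]
      fy <- stats::fft((seg_y - mean(seg_y)) * w)[seq_len(nf)]
      syy <- syy + Re(fy * Conj(fy))
      sxy <- sxy + fx * Conj(fy)
    }
  }
  k <- length(starts)
  scale <- 1 / (k * fs * sum(w^2))
  out <- list(frequencies = freqs, sxx = sxx * scale, n_segments = k,
              segment_length = L)
  if (!is.null(y)) {
    out$syy <- syy * scale
    out$sxy <- sxy * scale
  }
  out
}

# Trapezoidal integral of y sampled at uniform spacing dt.
trapz_uniform <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(0)
  dt * (sum(y) - (y[1L] + y[n]) / 2)
}
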