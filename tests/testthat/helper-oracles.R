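# Independent brute-force oracles, written directly from the definitions
# (plain double loops, no shared code with the package internals).

bf_sampen <- function(x, m, r_frac) {
  r <- r_frac * sd(x)
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm < r) {
        B <- B + 1
        if (max(dm, abs(x[i + m] - x[j + m])) < r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

bf_locfuzen <- function(x, m, r_frac, p) {
  r <- r_frac * sd(x)
  n <- length(x)
  nt <- n - m
  phi <- function(mm) {
    tot <- 0
    for (i in seq_len(nt - 1)) {
      for (j in (i + 1):nt) {
        vi <- x[i:(i + mm - 1)]; vi <- vi - mean(vi)
        vj <- x[j:(j + mm - 1)]; vj <- vj - mean(vj)
        d <- max(abs(vi - vj))
        tot <- tot + exp(-(d / r)^p)
      }
    }
    tot / (nt * (nt - 1) / 2)
  }
  -log(phi(m + 1) / phi(m))
}

bf_classes <- function(x, c) {
  y <- pnorm(x, mean(x), sd(x))
  z <- floor(c * y + 1)
  pmin(pmax(z, 1), c)
}

bf_dispen <- function(x, m, c, d) {
  z <- bf_classes(x, c)
  n <- length(x)
  pats <- character(0)
  for (i in seq_len(n - (m - 1) * d)) {
    pats <- c(pats, paste(z[i + (0:(m - 1)) * d], collapse = "-"))
  }
  p <- table(pats) / length(pats)
  -sum(p * log(p))
}

bf_fdispen <- function(x, m, c, d) {
  z <- bf_classes(x, c)
  n <- length(x)
  pats <- character(0)
  for (i in seq_len(n - (m - 1) * d)) {
    v <- z[i + (0:(m - 1)) * d]
    pats <- c(pats, paste(diff(v), collapse = "-"))
  }
  p <- table(pats) / length(pats)
  -sum(p * log(p))
}

# LZ76 exhaustive parsing straight from the definition: at position j the
# next phrase is the shortest prefix of the remainder that is NOT a
# substring of everything before the phrase's last symbol.
bf_lz76 <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  j <- 1; count <- 0
  while (j <= n) {
    k <- 0
    while (j + k <= n &&
           grepl(substr(s, j, j + k), substr(s, 1, j + k - 1), fixed = TRUE)) {
      k <- k + 1
    }
    count <- count + 1
    j <- j + k + 1
  }
  count
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled (tie-free) values to group 1.
bf_mwu_exact <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  u_of <- function(idx) {
    g1 <- pooled[idx]; g2 <- pooled[-idx]
    sum(outer(g1, g2, ">"))
  }
  u_obs <- sum(outer(a, b, ">"))
  combos <- combn(n1 + n2, n1)
  us <- apply(combos, 2, u_of)
  mu <- n1 * n2 / 2
  p <- mean(abs(us - mu) >= abs(u_obs - mu))
  list(u = u_obs, p = p)
}

bf_hedges <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp <- sqrt(((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2))
  (1 - 3 / (4 * (n1 + n2) - 9)) * (mean(a) - mean(b)) / sp
}
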