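test_that("sample entropy matches a brute-force oracle on short inputs", {
  for (s in 1:25) {
    set.seed(s)
    x <- rnorm(sample(30:50, 1))
    got <- sample_entropy(x, m = 2, r = 0.2)
    want <- bf_sampen(x, 2, 0.2)
    expect_equal(got, want, tolerance = 1e-9, label = paste("seed", s))
  }
})

test_that("sample entropy handles degenerate and ordered cases", {
  expect_equal(sample_entropy(rep(3, 100)), 0)
  x <- rep(c(1, 2, 3), 10)
  expect_equal(sample_entropy(x, 2, 0.2), bf_sampen(x, 2, 0.2),
               tolerance = 1e-9)
  expect_error(sample_entropy(rnorm(15), m = 2), "short")
  expect_warning(got <- sample_entropy(seq_len(50), 2, 0.01), "undefined")
  expect_true(is.na(got))
})

test_that("noise is more irregular than a sinusoid by SampEn", {
  t <- seq(0, 5, length.out = 5000)
  sin_se <- sample_entropy(sin(2 * pi * t))
  for (s in 1:20) {
    set.seed(s)
    expect_gt(sample_entropy(rnorm(5000)), sin_se)
  }
})

test_that("SampEn is non-increasing in the tolerance r and SD-invariant", {
  set.seed(33)
  x <- rnorm(300)
  vals <- vapply(c(0.1, 0.15, 0.2, 0.3, 0.5),
                 function(r) sample_entropy(x, 2, r), numeric(1))
  expect_true(all(diff(vals) <= 0))
  expect_equal(sample_entropy(5 * x + 2, 2, 0.2), sample_entropy(x, 2, 0.2),
               tolerance = 1e-9)
})

test_that("local fuzzy entropy matches a brute-force oracle", {
  for (s in 1:25) {
    set.seed(100 + s)
    x <- rnorm(sample(20:40, 1))
    expect_equal(local_fuzzy_entropy(x, 2, 0.2, 2),
                 bf_locfuzen(x, 2, 0.2, 2), tolerance = 1e-9,
                 label = paste("seed", s))
  }
  set.seed(7)
  y <- rnorm(30)
  expect_equal(local_fuzzy_entropy(y, 3, 0.25, 3),
               bf_locfuzen(y, 3, 0.25, 3), tolerance = 1e-9)
})

test_that("fuzzy entropy limits: constant series and infinite tolerance", {
  expect_equal(local_fuzzy_entropy(rep(2, 50)), 0)
  set.seed(5)
  x <- rnorm(100)
  expect_lt(local_fuzzy_entropy(x, 2, r = 1e6), 1e-6)
})

test_that("dispersion entropy matches exhaustive pattern enumeration", {
  x_spec <- c(9, 8, 1, 12, 5, -3, 1.5, 8.01, 2.99, 4, -1, 10)
  expect_equal(dispersion_entropy(x_spec, m = 2, c = 3, d = 1),
               bf_dispen(x_spec, 2, 3, 1), tolerance = 1e-12)
  for (s in 1:25) {
    set.seed(200 + s)
    x <- rnorm(sample(30:50, 1))
    expect_equal(dispersion_entropy(x, 2, 6, 1), bf_dispen(x, 2, 6, 1),
                 tolerance = 1e-9, label = paste("seed", s))
  }
  set.seed(9); x <- rnorm(50)
  expect_equal(dispersion_entropy(x, 3, 4, 2), bf_dispen(x, 3, 4, 2),
               tolerance = 1e-9)
})

test_that("dispersion entropy attains its analytic bound on i.i.d. noise", {
  set.seed(42)
  suppressWarnings({
    val <- dispersion_entropy(rnorm(10000), m = 2, c = 6)
  })
  expect_equal(val, 2 * log(6), tolerance = 0.02)
  # all values inside one class (fixed mapping): a single dispersion pattern
  suppressWarnings(expect_equal(
    dispersion_entropy(rep(c(0.29, 0.31), 50), 2, 2, mu = 0, sigma = 1), 0,
    tolerance = 1e-12))
  expect_error(dispersion_entropy(rep(1, 100)), "variance")
})

test_that("dispersion measures are invariant under affine transforms", {
  set.seed(77)
  x <- rnorm(400)
  expect_equal(dispersion_entropy(3 * x - 7, 2, 6),
               dispersion_entropy(x, 2, 6), tolerance = 1e-12)
  expect_equal(fluctuation_dispersion_entropy(3 * x - 7, 2, 6),
               fluctuation_dispersion_entropy(x, 2, 6), tolerance = 1e-12)
})

test_that("fluctuation dispersion entropy matches enumeration and its bounds", {
  x_spec <- c(9, 8, 1, 12, 5, -3, 1.5, 8.01, 2.99, 4, -1, 10)
  expect_equal(fluctuation_dispersion_entropy(x_spec, 2, 3, 1),
               bf_fdispen(x_spec, 2, 3, 1), tolerance = 1e-12)
  for (s in 1:25) {
    set.seed(300 + s)
    x <- rnorm(sample(30:50, 1))
    got <- fluctuation_dispersion_entropy(x, 3, 5, 1)
    expect_equal(got, bf_fdispen(x, 3, 5, 1), tolerance = 1e-9,
                 label = paste("seed", s))
    expect_lte(got, (3 - 1) * log(2 * 5 - 1))
    expect_gte(got, 0)
  }
  # ramp whose classes increase by exactly one per step: one fluctuation
  # pattern (probit-spaced values make the NCDF mapping uniform)
  ramp <- qnorm((1:20) / 21)
  suppressWarnings(
    expect_equal(fluctuation_dispersion_entropy(ramp, 2, 20,
                                                mu = 0, sigma = 1), 0,
                 tolerance = 1e-12))
})

test_that("Higuchi FD recovers known limits", {
  expect_equal(higuchi_fd(seq_len(2000)), 1, tolerance = 0.01)
  t <- seq(0, 10, length.out = 5000)
  expect_lt(higuchi_fd(sin(2 * pi * t)), 1.3)
  for (s in 1:20) {
    set.seed(400 + s)
    fd <- higuchi_fd(rnorm(5000), kmax = 10)
    expect_gt(fd, 1.9); expect_lt(fd, 2.05)
  }
  expect_error(higuchi_fd(rnorm(50), kmax = 10), "short")
})

test_that("LZ76 phrase counts match an independent definition-level parser", {
  bits <- c(0, 0, 0, 1, 1, 0, 1, 0, 0, 1, 0, 0, 0, 1, 0, 1)
  # feed a numeric series whose median split reproduces these bits
  x <- ifelse(bits == 1, 2, -1)
  got <- lempel_ziv(x)
  expect_equal(attr(got, "count"), bf_lz76(bits))
  for (s in 1:25) {
    set.seed(500 + s)
    x <- rnorm(sample(40:80, 1))
    bits <- as.integer(x > median(x))
    expect_equal(attr(lempel_ziv(x), "count"), bf_lz76(bits),
                 label = paste("seed", s))
  }
})

test_that("LZ76 limits: constant-ish strings are minimal, noise is ~1", {
  x <- c(rep(0, 50), rep(1, 50))  # median split -> 50 zeros then 50 ones
  expect_lte(attr(lempel_ziv(x), "count"), 3)
  set.seed(606)
  z <- as.numeric(lempel_ziv(rnorm(10000)))
  expect_gt(z, 0.85); expect_lt(z, 1.15)
})
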