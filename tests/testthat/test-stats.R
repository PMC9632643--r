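test_that("Mann-Whitney U: fully separated samples give the exact textbook p", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$u_statistic, 0)
  expect_true(res$exact)
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)
  flipped <- mann_whitney_u(c(4, 5, 6), c(1, 2, 3))
  expect_equal(flipped$u_statistic, 9)
  expect_equal(flipped$p_value, 0.1, tolerance = 1e-12)
})

test_that("Mann-Whitney U matches exhaustive enumeration on random inputs", {
  for (s in 1:25) {
    set.seed(s)
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    repeat {
      a <- round(rnorm(n1), 3); b <- round(rnorm(n2), 3)
      if (!anyDuplicated(c(a, b))) break
    }
    got <- mann_whitney_u(a, b)
    want <- bf_mwu_exact(a, b)
    expect_equal(got$u_statistic, want$u, label = paste("U, seed", s))
    if (got$exact) {
      expect_equal(got$p_value, want$p, tolerance = 1e-9,
                   label = paste("p, seed", s))
    }
  }
})

test_that("identical samples give U = n1 n2 / 2 and p = 1", {
  a <- c(1, 2, 3, 4)
  res <- mann_whitney_u(a, a)
  expect_equal(res$u_statistic, 8)
  expect_equal(res$p_value, 1)
})

test_that("normal approximation tracks enumeration closely at n = 8 + 8", {
  errs <- numeric(5)
  for (s in 1:5) {
    set.seed(700 + s)
    a <- rnorm(8); b <- rnorm(8, 0.5)
    res <- mann_whitney_u(a, b)                     # pooled n = 16 > 12
    expect_false(res$exact)
    # the tie/continuity-corrected formula agrees with the reference
    # implementation of the same approximation
    expect_equal(res$p_value,
                 wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
                 tolerance = 1e-9)
    errs[s] <- abs(res$p_value - bf_mwu_exact(a, b)$p)
  }
  expect_lt(mean(errs), 0.01)
  expect_lt(max(errs), 0.02)
})

test_that("Mann-Whitney is invariant under strictly monotone transforms", {
  set.seed(81)
  a <- abs(rnorm(10)) + 0.1; b <- abs(rnorm(12)) + 0.3
  r1 <- mann_whitney_u(a, b)
  r2 <- mann_whitney_u(log(a), log(b))
  r3 <- mann_whitney_u(a^3, b^3)
  expect_equal(r1$u_statistic, r2$u_statistic)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_equal(r1$u_statistic, r3$u_statistic)
  expect_error(mann_whitney_u(numeric(0), b), "non-empty")
})

test_that("Hedges' g reproduces the closed-form hand computation", {
  # mean diff = 1, pooled SD = sqrt(20/3), J = 1 - 3/23
  a <- c(2, 4, 6, 8); b <- c(1, 3, 5, 7)
  expect_equal(hedges_g(a, b), (1 - 3 / 23) * 1 / sqrt(20 / 3),
               tolerance = 1e-12)
  for (s in 1:25) {
    set.seed(s)
    x <- rnorm(sample(5:20, 1)); y <- rnorm(sample(5:20, 1), 0.4)
    expect_equal(hedges_g(x, y), bf_hedges(x, y), tolerance = 1e-9)
  }
})

test_that("Hedges' g is antisymmetric, scale-invariant, and guarded", {
  set.seed(91)
  a <- rnorm(10); b <- rnorm(15, 1)
  expect_equal(hedges_g(a, b), -hedges_g(b, a), tolerance = 1e-12)
  expect_equal(hedges_g(3 * a, 3 * b), hedges_g(a, b), tolerance = 1e-12)
  expect_equal(hedges_g(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(hedges_g(rep(1, 5), rep(1, 5)), "pooled SD")
  expect_error(hedges_g(1, c(1, 2)), ">= 2")
})

test_that("test-retest PCC handles the exact and degenerate cases", {
  s1 <- rnorm(12)
  expect_equal(test_retest_pcc(s1, s1), 1)
  expect_equal(test_retest_pcc(s1, -s1), -1)
  expect_error(test_retest_pcc(s1, rnorm(5)), "paired")
  expect_error(test_retest_pcc(rnorm(2), rnorm(2)), "3")
})

test_that("template score is reliable across simulated repeat sessions", {
  # same subject profile and task, new noise/blink/drift realizations
  cfg <- default_config()
  spec <- filter_spec(cfg$bands$low, 240)
  score_of <- function(profile, schedule_seed, noise_seed) {
    sch <- generate_schedule(seed = schedule_seed)
    rec <- simulate_recording(sch, profile, seed = noise_seed)
    l <- preprocess_channel(rec$left_x, spec, cfg)
    r <- preprocess_channel(rec$right_x, spec, cfg)
    suppressWarnings(mean(c(matched_filter_score(l, fs = 240)$score,
                            matched_filter_score(r, fs = 240)$score)))
  }
  set.seed(123)
  session1 <- numeric(12); session2 <- numeric(12)
  for (i in 1:12) {
    profile <- if (i <= 6) {
      control_profile(primary_gain_mean = runif(1, 0.91, 0.97))
    } else {
      dysmetric_profile(sample(c("hypometric", "hypermetric", "mixed"), 1))
    }
    session1[i] <- score_of(profile, schedule_seed = i, noise_seed = 1000 + i)
    session2[i] <- score_of(profile, schedule_seed = i, noise_seed = 2000 + i)
  }
  expect_gt(test_retest_pcc(session1, session2), 0.5)
})

test_that("compare_groups lays out per-feature statistics", {
  set.seed(7)
  df <- data.frame(label = rep(c("dysmetric", "control"), each = 10),
                   f1 = c(rnorm(10, 2), rnorm(10)),
                   f2 = rnorm(20))
  tab <- compare_groups(df)
  expect_equal(tab$feature, c("f1", "f2"))
  expect_lt(tab$p_value[1], 0.05)
  expect_gt(tab$p_value[2], 0.05)
  expect_gt(tab$hedges_g[1], 1)
  expect_true(all(tab$u_statistic >= 0 & tab$u_statistic <= 100))
  expect_equal(tab$n1, c(10, 10))
})
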