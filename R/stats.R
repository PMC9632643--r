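#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. The U statistic is computed from midrank sums
#' (orientation: U counts pairs where sample `a` precedes sample `b`).
#' When the pooled sample size is at most 12 and there are no ties the
#' two-sided p-value is exact (null distribution of U); otherwise the
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param a,b numeric samples.
#' @return List with `u_statistic`, `p_value`, `exact` (logical), `n1`,
#'   `n2`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
mann_whitney_u <- function(a, b) {
  stop_if_not_numeric(a); stop_if_not_numeric(b)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty", call. = FALSE)
  pooled <- c(a, b)
  rk <- rank(pooled)
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  exact <- (n1 + n2) <= 12 && !ties
  if (exact) {
    p <- 2 * min(stats::pwilcox(u, n1, n2),
                 1 - stats::pwilcox(u - 1, n1, n2))
  } else {
    nn <- n1 + n2
    tie_tab <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - sum(tie_tab^3 - tie_tab) / (nn * (nn - 1)))
    z <- u - n1 * n2 / 2
    z <- z - sign(z) * 0.5 # continuity correction
    p <- if (sigma2 == 0) 1 else 2 * stats::pnorm(-abs(z) / sqrt(sigma2))
  }
  list(u_statistic = u, p_value = min(1, p), exact = exact, n1 = n1, n2 = n2)
}

#' Hedges' g effect size
#'
#' Standardized mean difference `(mean(a) - mean(b)) / s_pooled`, where
#' `s_pooled` is the (n-1)-weighted pooled SD, multiplied by the
#' small-sample bias correction `J = 1 - 3 / (4 (n1 + n2) - 9)`.
#'
#' @param a,b numeric samples with at least 2 observations each.
#' @return Hedges' g.
#' @export
#' @examples
#' hedges_g(c(2, 4, 6, 8), c(1, 3, 5, 7))
hedges_g <- function(a, b) {
  stop_if_not_numeric(a); stop_if_not_numeric(b)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop("both samples need >= 2 observations", call. = FALSE)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  if (sp2 == 0) stop("pooled SD is zero: effect size undefined", call. = FALSE)
  j <- 1 - 3 / (4 * (n1 + n2) - 9)
  j * (mean(a) - mean(b)) / sqrt(sp2)
}

#' Test-retest reliability (Pearson correlation)
#'
#' Pearson correlation across subjects between a feature measured in two
#' recording sessions.
#'
#' @param session1,session2 paired per-subject feature values (equal
#'   length, n >= 3).
#' @return Pearson correlation coefficient.
#' @export
test_retest_pcc <- function(session1, session2) {
  stop_if_not_numeric(session1); stop_if_not_numeric(session2)
  if (length(session1) != length(session2)) {
    stop("sessions must be paired (equal length)", call. = FALSE)
  }
  if (length(session1) < 3) stop("need at least 3 paired subjects", call. = FALSE)
  stats::cor(session1, session2)
}

#' Per-feature two-group comparison table
#'
#' For every feature column, compares the two label groups with the
#' Mann-Whitney U test and Hedges' g (group 1 = `positive` label), the
#' layout used to report per-feature group differences. No
#' multiple-testing correction is applied (none is used in the source
#' analysis); treat the p-values as per-feature.
#'
#' @param features data frame with a `label` column and numeric feature
#'   columns (as from [feature_table()]).
#' @param positive label treated as group 1 (default `"dysmetric"`).
#' @return Data frame with one row per feature: group means/SDs,
#'   `u_statistic`, `p_value`, `hedges_g`, `n1`, `n2`.
#' @export
compare_groups <- function(features, positive = "dysmetric") {
  stopifnot(is.data.frame(features), "label" %in% names(features))
  labs <- features$label
  if (length(unique(labs)) != 2) stop("`features` must contain exactly two groups", call. = FALSE)
  other <- setdiff(unique(labs), positive)
  cols <- names(features)[vapply(features, is.numeric, logical(1))]
  rows <- lapply(cols, function(cn) {
    a <- features[[cn]][labs == positive]
    b <- features[[cn]][labs == other]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    mw <- mann_whitney_u(a, b)
    data.frame(feature = cn,
               mean_pos = mean(a), sd_pos = stats::sd(a),
               mean_neg = mean(b), sd_neg = stats::sd(b),
               u_statistic = mw$u_statistic, p_value = mw$p_value,
               hedges_g = hedges_g(a, b), n1 = mw$n1, n2 = mw$n2)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
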