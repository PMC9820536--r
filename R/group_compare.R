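## Statistical battery for per-animal gait metrics: normality screen,
## between-group tests, pre/post-drug ratio tests, CV comparison.
## The unit of analysis is always the per-animal summary, never pooled steps.

.check_finite <- function(x, what) {
  if (anyNA(x) || !all(is.finite(x)))
    stop("data error: non-finite ", what, call. = FALSE)
}

.test_result <- function(test_name, statistic, p_value, effect_direction = NA,
                         n_a = NA_integer_, n_b = NA_integer_, ...) {
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, effect_direction = effect_direction,
                 n_a = n_a, n_b = n_b, ...),
            class = "gait_test")
}

#' @export
print.gait_test <- function(x, ...) {
  cat(sprintf("<gait_test> %s: statistic=%.4g, p=%.4g (n=%s%s)\n",
              x$test_name, x$statistic, x$p_value, x$n_a,
              if (!is.na(x$n_b)) paste0("/", x$n_b) else ""))
  invisible(x)
}

#' @export
as.data.frame.gait_test <- function(x, ...) {
  data.frame(test_name = x$test_name, statistic = x$statistic,
             p_value = x$p_value, effect_direction = x$effect_direction,
             n_a = x$n_a, n_b = x$n_b)
}

#' D'Agostino-Pearson omnibus normality screen
#'
#' The K-squared omnibus test combining the standard normal transforms of
#' sample skewness (D'Agostino) and kurtosis (Anscombe-Glynn); K2 is referred
#' to a chi-squared distribution with 2 df. The omnibus statistic is not
#' valid for very small samples: below `n = 8` an "untestable" marker (NA
#' p-value) is returned instead of a p.
#'
#' @param values numeric vector.
#' @return a `gait_test` with `statistic` = K2; `p_value` is `NA` and
#'   `untestable = TRUE` when `n < 8`.
#' @export
normality_screen <- function(values) {
  values <- as.numeric(values)
  .check_finite(values, "values")
  n <- length(values)
  if (n < 8L)
    return(.test_result("dagostino_pearson", NA_real_, NA_real_,
                        n_a = n, untestable = TRUE))
  m <- mean(values)
  m2 <- mean((values - m)^2)
  m3 <- mean((values - m)^3)
  m4 <- mean((values - m)^4)
  if (m2 <= 0)
    return(.test_result("dagostino_pearson", NA_real_, NA_real_,
                        n_a = n, untestable = TRUE))
  g1 <- m3 / m2^1.5
  ## skewness transform (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  zs <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  ## kurtosis transform (Anscombe & Glynn 1983)
  k <- m4 / m2^2
  ek <- 3 * (n - 1) / (n + 1)
  vk <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  x1 <- (k - ek) / sqrt(vk)
  beta <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  aa <- 6 + 8 / beta * (2 / beta + sqrt(1 + 4 / beta^2))
  zk <- ((1 - 2 / (9 * aa)) -
           ((1 - 2 / aa) / (1 + x1 * sqrt(2 / (aa - 4))))^(1 / 3)) /
    sqrt(2 / (9 * aa))
  k2 <- zs^2 + zk^2
  .test_result("dagostino_pearson", k2,
               stats::pchisq(k2, df = 2, lower.tail = FALSE),
               n_a = n, z_skew = zs, z_kurt = zk, untestable = FALSE)
}

#' Between-group comparison of per-animal values
#'
#' Unpaired two-tailed tests between two groups of per-animal summaries:
#' pooled-variance Student's t, or Mann-Whitney for bounded quantities such
#' as r-values. The Mann-Whitney p is exact when `min(n) <= 8` — computed by
#' full enumeration of the rank-sum null, which also covers tied data — and
#' otherwise uses the normal approximation with tie/continuity correction.
#' Identical groups short-circuit to `p = 1`.
#'
#' @param a,b numeric vectors of per-animal values (each `n >= 2`).
#' @param test `"student_t"` or `"mann_whitney"`.
#' @return a `gait_test`; `effect_direction` is the sign of
#'   `mean(a) - mean(b)` (t) or of the median difference (Mann-Whitney).
#' @export
compare_groups <- function(a, b, test = c("student_t", "mann_whitney")) {
  test <- match.arg(test)
  a <- as.numeric(a); b <- as.numeric(b)
  .check_finite(c(a, b), "group values")
  if (length(a) < 2L || length(b) < 2L)
    stop("insufficient data: need n >= 2 per group", call. = FALSE)
  na <- length(a); nb <- length(b)
  if (stats::var(c(a, b)) == 0)
    return(.test_result(test, 0, 1, effect_direction = 0, n_a = na, n_b = nb,
                        degenerate = TRUE))
  if (test == "student_t") {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    .test_result("student_t", unname(ht$statistic), ht$p.value,
                 effect_direction = sign(mean(a) - mean(b)),
                 n_a = na, n_b = nb, df = unname(ht$parameter))
  } else {
    if (min(na, nb) <= 8) {
      ## exact null distribution of W by enumeration of every assignment of
      ## the pooled (midranks for ties) ranks; handles tied data, which the
      ## shift-algorithm exact path cannot
      rk <- rank(c(a, b))
      w <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
      ws <- apply(utils::combn(na + nb, na), 2, function(ix)
        sum(rk[ix])) - na * (na + 1) / 2
      p <- min(1, 2 * min(mean(ws <= w + 1e-9), mean(ws >= w - 1e-9)))
      .test_result("mann_whitney", w, p,
                   effect_direction = sign(stats::median(a) - stats::median(b)),
                   n_a = na, n_b = nb, method = "exact")
    } else {
      ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                                correct = TRUE))
      .test_result("mann_whitney", unname(ht$statistic), ht$p.value,
                   effect_direction = sign(stats::median(a) - stats::median(b)),
                   n_a = na, n_b = nb, method = "normal_approx")
    }
  }
}

#' One-sample t-test of post/pre ratios against unity
#'
#' The drug-trial contrast: per-animal post-drug values expressed as ratios
#' to the same animal's pre-drug value, tested two-tailed against 1. Zero
#' variance degenerates to `p = 1` (all ratios exactly 1) or a flagged
#' `p = 0` (all ratios equal but not 1).
#'
#' @param ratios numeric vector of per-animal post/pre ratios (`n >= 2`).
#' @return a `gait_test` with `test_name = "one_sample_t_vs_1"`;
#'   `effect_direction` is the sign of `mean(ratios) - 1`.
#' @export
ratio_vs_unity <- function(ratios) {
  ratios <- as.numeric(ratios)
  .check_finite(ratios, "ratios")
  if (length(ratios) < 2L)
    stop("insufficient data: need n >= 2 ratios", call. = FALSE)
  n <- length(ratios)
  if (stats::var(ratios) == 0) {
    if (isTRUE(all.equal(mean(ratios), 1)))
      return(.test_result("one_sample_t_vs_1", 0, 1, effect_direction = 0,
                          n_a = n, degenerate = TRUE))
    return(.test_result("one_sample_t_vs_1", Inf * sign(mean(ratios) - 1), 0,
                        effect_direction = sign(mean(ratios) - 1), n_a = n,
                        degenerate = TRUE))
  }
  ht <- stats::t.test(ratios, mu = 1)
  .test_result("one_sample_t_vs_1", unname(ht$statistic), ht$p.value,
               effect_direction = sign(mean(ratios) - 1), n_a = n,
               df = unname(ht$parameter))
}

#' Compare per-animal coefficients of variation between groups
#'
#' Unpaired two-tailed Student's t-test on per-animal CVs — the step-to-step
#' consistency contrast between cohorts.
#'
#' @param cv_a,cv_b numeric vectors of per-animal CVs.
#' @return a `gait_test` (pooled-variance Student's t).
#' @export
compare_cv <- function(cv_a, cv_b) compare_groups(cv_a, cv_b, "student_t")
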