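test_that("D'Agostino-Pearson K2 matches an independent reference", {
  # fixture vectors with K2/p frozen from an independent implementation
  x <- c(8.021757, 9.264427, 12.575851, 10.387949, 11.840462, 11.154208,
         8.727073, 11.083904, 9.366809, 9.355222, 10.194335, 6.948139,
         12.384332, 8.657821, 12.000539, 10.272642, 13.064066, 8.680061,
         9.37641, 10.675538, 5.585058, 11.655843, 13.083261, 12.253614,
         11.509539, 9.708044, 12.563804, 12.148061, 10.785242, 10.010229,
         9.276466, 7.539536, 12.452459, 5.655912, 9.259705, 10.32876,
         11.719762, 13.523322, 11.986648, 9.416957)
  r <- normality_screen(x)
  expect_equal(r$statistic, 2.7143146531362117, tolerance = 1e-8)
  expect_equal(r$p_value, 0.25739141771974533, tolerance = 1e-8)
  y <- c(0.766275, 1.080518, -1.418077, -0.280928, 2.260919, 0.065923,
         0.034399, -0.483278, -0.709637, 0.219556, -0.41187, -2.215395,
         -1.341265, 0.319588, 0.380997, -0.809627, 1.135957, 3.335399,
         -3.556567, 0.389915, -0.626364, 1.479523, -0.562652, -0.757111,
         0.458486, 1.904927, 0.844292, 1.910873, -0.163778, 0.674725,
         -0.792603, -0.239261, -0.205073, -0.368434, 1.240917, 2.529376,
         -0.295497, -1.482338, -0.34535, -0.465376)
  r <- normality_screen(y)
  expect_equal(r$statistic, 2.230019944558852, tolerance = 1e-8)
  expect_equal(r$p_value, 0.32791200885310423, tolerance = 1e-8)
  # below the validity floor: untestable marker, not a p-value
  u <- normality_screen(c(1, 2, 3, 4, 5))
  expect_true(u$untestable)
  expect_true(is.na(u$p_value))
})

test_that("normality screen separates normal from heavy-tailed samples", {
  set.seed(61)
  p_norm <- replicate(40, normality_screen(rnorm(500))$p_value)
  p_heavy <- replicate(40, normality_screen(rt(500, df = 2))$p_value)
  expect_gte(mean(p_norm > 0.05), 0.9)
  expect_gte(mean(p_heavy < 0.05), 0.9)
})

test_that("pooled-variance t matches the closed-form hand computation", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  r <- compare_groups(a, b, "student_t")
  sp <- sqrt(((2) * var(a) + (2) * var(b)) / 4)
  t_hand <- (mean(a) - mean(b)) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(r$statistic, t_hand, tolerance = 1e-12)
  expect_equal(r$p_value, 2 * pt(-abs(t_hand), df = 4), tolerance = 1e-12)
  expect_equal(r$effect_direction, -1)
})

test_that("Mann-Whitney exact path equals exhaustive rank enumeration", {
  a <- c(0.9, 0.8, 0.85, 0.95, 0.9)
  b <- c(0.3, 0.4, 0.35, 0.2, 0.5, 0.45, 0.3)
  r <- compare_groups(a, b, "mann_whitney")
  expect_equal(r$p_value, mw_exact_enum(a, b), tolerance = 1e-12)
  set.seed(17)
  for (rep in 1:20) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    a <- round(runif(na), 3); b <- round(runif(nb) + 0.2, 3)
    if (anyDuplicated(c(a, b))) next
    r <- compare_groups(a, b, "mann_whitney")
    expect_equal(r$p_value, mw_exact_enum(a, b), tolerance = 1e-12)
    # independent exact reference for the tie-free case
    expect_equal(r$p_value, wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("degenerate and swapped-label behaviour is sane", {
  a <- c(1, 2, 3)
  expect_equal(compare_groups(a, a, "mann_whitney")$p_value, 1)
  expect_equal(compare_groups(c(2, 2), c(2, 2), "student_t")$p_value, 1)
  # swapping labels preserves p and flips direction
  set.seed(9)
  x <- rnorm(6); y <- rnorm(7, 1)
  r1 <- compare_groups(x, y, "student_t")
  r2 <- compare_groups(y, x, "student_t")
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_equal(r1$effect_direction, -r2$effect_direction)
})

test_that("ratio-vs-unity follows the one-sample t and its degenerate branches", {
  expect_equal(ratio_vs_unity(rep(1, 5))$p_value, 1)
  zv <- ratio_vs_unity(rep(0.7, 4))
  expect_equal(zv$p_value, 0)
  expect_true(zv$degenerate)
  r <- ratio_vs_unity(c(0.5, 0.6, 0.4, 0.5, 0.55))
  v <- c(0.5, 0.6, 0.4, 0.5, 0.55)
  t_hand <- (mean(v) - 1) / (sd(v) / sqrt(5))
  expect_equal(r$statistic, t_hand, tolerance = 1e-12)
  expect_equal(r$p_value, 2 * pt(-abs(t_hand), df = 4), tolerance = 1e-12)
  expect_equal(r$effect_direction, -1)
  expect_error(ratio_vs_unity(0.5), "insufficient")
})

test_that("CV comparison detects a real step-to-step variability difference", {
  # power simulation: per-animal cycle CVs under low vs high jitter
  set.seed(41)
  hits <- 0
  for (rep in 1:20) {
    cv_lo <- replicate(6, sd(rnorm(20, 1, 0.05)) / mean(rnorm(20, 1, 0.05)))
    cv_hi <- replicate(6, sd(rnorm(20, 1, 0.20)) / mean(rnorm(20, 1, 0.20)))
    r <- compare_cv(cv_lo, cv_hi)
    if (r$p_value < 0.05 && r$effect_direction < 0) hits <- hits + 1
  }
  expect_gte(hits, 16)
  # boundary: n = 2 per group computes without error
  expect_s3_class(compare_cv(c(0.1, 0.12), c(0.3, 0.31)), "gait_test")
})

test_that("type-I error of the battery is near nominal under the null", {
  set.seed(77)
  n_rep <- 2000
  p_t <- replicate(n_rep, compare_groups(rnorm(6), rnorm(7), "student_t")$p_value)
  p_r <- replicate(n_rep, ratio_vs_unity(1 + rnorm(5, 0, 0.1))$p_value)
  expect_lt(abs(mean(p_t < 0.05) - 0.05), 0.015)
  expect_lt(abs(mean(p_r < 0.05) - 0.05), 0.015)
})
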