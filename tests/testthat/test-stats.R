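test_that("closed-form CvM statistic equals the empirical-CDF brute force", {
  set.seed(61)
  for (i in 1:100) {
    n <- sample(3:12, 1); m <- sample(3:12, 1)
    x <- rnorm(n); y <- rnorm(m, mean = runif(1, -1, 1))
    expect_equal(cvm_two_sample(x, y)$omega2, cvm_brute_force(x, y),
                 tolerance = 1e-10)
  }
  # identical multisets and a fully separated pair, against the same oracle
  x5 <- c(1, 2, 3, 4, 5)
  expect_equal(cvm_two_sample(x5, x5)$omega2, cvm_brute_force(x5, x5),
               tolerance = 1e-10)
  sep <- cvm_two_sample(c(1, 2, 3), c(101, 102, 103))
  expect_equal(sep$omega2, cvm_brute_force(c(1, 2, 3), c(101, 102, 103)),
               tolerance = 1e-10)
  expect_lt(sep$p_value, 0.1)
})

test_that("the limiting-distribution CDF matches independent reference values", {
  # reference values computed from the Bessel-K series with an independent
  # implementation (scipy.stats 1.17.1), frozen
  ref <- cbind(
    x = c(0.05, 0.1, 0.2, 0.3, 0.46136, 0.7, 1.0, 2.0),
    p = c(0.12371906895864906, 0.4151265615932029, 0.7325295694592229,
          0.8648287311948927, 0.9499996168673471, 0.9872623764021078,
          0.9975395478198642, 0.9999872192637342)
  )
  expect_equal(wavemotif:::cvm_limit_cdf(ref[, "x"]), ref[, "p"],
               tolerance = 1e-8)
})

test_that("a full two-sample case reproduces an independent implementation", {
  x <- c(0.345584, 0.821618, 0.330437, -1.303157, 0.905356, 0.446375,
         -0.536953, 0.581118)
  y <- c(0.864572, 0.794132, 0.528422, 1.046713, -0.236454, 0.33709, 0.017881)
  r <- cvm_two_sample(x, y)
  expect_equal(r$omega2, 0.056746031746031544, tolerance = 1e-10)
  expect_equal(r$p_value, 0.9293947508972933, tolerance = 1e-6)
})

test_that("the statistic is rank-invariant and error cases are caught", {
  set.seed(62)
  x <- rnorm(20); y <- rnorm(15, 0.4)
  s0 <- cvm_two_sample(x, y)$omega2
  expect_equal(cvm_two_sample(exp(x), exp(y))$omega2, s0, tolerance = 1e-12)
  expect_error(cvm_two_sample(1, c(1, 2)), "at least 2")
  # lower bound of the statistic
  expect_gte(s0, -(4 * 20 * 15 - 1) / (6 * 35))
})

test_that("exact enumeration agrees with the asymptotic branch on small samples", {
  set.seed(63)
  x <- rnorm(6); y <- rnorm(6, 1)
  ex <- cvm_two_sample(x, y, method = "exact")
  as <- cvm_two_sample(x, y, method = "asymptotic")
  expect_equal(ex$omega2, as$omega2)
  expect_equal(ex$p_value, as$p_value, tolerance = 0.06)
  expect_error(cvm_two_sample(rnorm(15), rnorm(15), method = "exact"), "<= 20")
})

test_that("type-I error at nominal 0.05 is calibrated under the null", {
  set.seed(64)
  n_sim <- 2000
  rej <- vapply(seq_len(n_sim), function(i) {
    cvm_two_sample(rnorm(100), rnorm(100))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.035)
  expect_lte(mean(rej), 0.065)
})

test_that("pure variance inflation is detected at the Bonferroni threshold", {
  set.seed(65)
  thr <- bonferroni(0.05, 16)
  hits <- vapply(1:100, function(i) {
    cvm_two_sample(rnorm(500), rnorm(500, sd = 2))$p_value < thr
  }, logical(1))
  expect_gt(mean(hits), 0.8)
})

test_that("bootstrap intervals are seeded and bracket the point estimate", {
  set.seed(66)
  x <- rnorm(100); y <- rnorm(100, 0.5)
  ci1 <- bootstrap_ci(x, y, n_boot = 500, seed = 3)
  ci2 <- bootstrap_ci(x, y, n_boot = 500, seed = 3)
  expect_identical(ci1, ci2)
  brackets <- vapply(1:50, function(s) {
    xs <- rnorm(100); ys <- rnorm(100, 0.8)
    est <- cvm_two_sample(xs, ys)$omega2
    ci <- bootstrap_ci(xs, ys, n_boot = 300, seed = s)
    ci$lower <= est && est <= ci$upper
  }, logical(1))
  expect_gte(mean(brackets), 0.99)
})

test_that("null-data bootstrap intervals concentrate on small statistic values", {
  set.seed(67)
  lows <- vapply(1:100, function(i) {
    bootstrap_ci(rnorm(200), rnorm(200), n_boot = 200, seed = i)$lower
  }, numeric(1))
  # under the null, omega^2 is O(1); the interval should reach well below
  # conventional significance thresholds in nearly all simulations
  expect_gt(mean(lows < 0.46), 0.95)
})

test_that("the Bonferroni threshold is alpha over the number of tests", {
  expect_identical(bonferroni(0.05, 16), 0.003125)
  expect_identical(bonferroni(0.05, 1), 0.05)
  expect_identical(bonferroni(0.01, 10), 0.001)
  expect_error(bonferroni(0.05, 0), ">= 1")
})

test_that("tail analysis reports baseline-referenced exceedance proportions", {
  set.seed(68)
  pre <- rnorm(2000)
  ts0 <- tail_shift(pre, pre)
  expect_equal(ts0$prop_below, 0.10, tolerance = 0.01)
  expect_equal(ts0$prop_above, 0.10, tolerance = 0.01)

  infl <- tail_shift(pre, 2 * pre)  # zero-centered scale inflation
  expect_gt(infl$prop_below, 0.10)
  expect_gt(infl$prop_above, 0.10)

  shift <- tail_shift(pre, pre + 10)
  expect_gt(shift$prop_above, 0.9)
  expect_lt(shift$prop_below, 0.01)
  expect_error(tail_shift(rnorm(5), rnorm(50)), "at least 10")
})

test_that("grouped score comparison emits one corrected row per group and component", {
  set.seed(69)
  scores <- tibble::tibble(
    lobe = rep(c("parietal", "occipital"), each = 200),
    time_point = rep(rep(c("pre", "post"), each = 100), 2),
    PC1 = c(rnorm(100), rnorm(100, 1), rnorm(200)),
    PC2 = rnorm(400)
  )
  out <- compare_score_distributions(scores, group_cols = "lobe",
                                     n_boot = 200, seed = 1)
  expect_equal(nrow(out), 4)
  expect_equal(unique(out$bonferroni_threshold), 0.05 / 4)
  shifted <- out[out$lobe == "parietal" & out$component == "PC1", ]
  expect_true(shifted$significant)
  expect_gt(shifted$delta_mean, 0.5)
  null_rows <- out[out$lobe == "occipital", ]
  expect_true(all(!null_rows$significant))
})
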