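test_that("Z'-factor and SSMD match hand arithmetic on printed group stats", {
  g <- group_stats_values(mu_positive = 191.8, sigma_positive = 11.5,
                          mu_negative = 133.7, sigma_negative = 8.4)
  expect_equal(zprime(g), 1 - 3 * (11.5 + 8.4) / 58.1)
  expect_equal(zprime(g), -0.02754, tolerance = 1e-3)
  expect_equal(ssmd(g), 58.1 / sqrt(11.5^2 + 8.4^2))
  expect_equal(ssmd(g), 4.080, tolerance = 1e-3)
})

test_that("Z'-factor and SSMD match the hand formulas on random draws", {
  withr::with_seed(100, {
    for (i in 1:1000) {
      mp <- runif(1, -50, 250); mn <- runif(1, -50, 250)
      sp <- runif(1, 0.01, 30); sn <- runif(1, 0.01, 30)
      if (mp == mn) next
      g <- group_stats_values(mp, sp, mn, sn)
      z_hand <- 1 - 3 * (sp + sn) / abs(mp - mn)
      b_hand <- (mp - mn) / sqrt(sp^2 + sn^2)
      expect_lte(abs(zprime(g) - z_hand) / max(abs(z_hand), 1e-12), 1e-9)
      expect_lte(abs(ssmd(g) - b_hand) / max(abs(b_hand), 1e-12), 1e-9)
    }
  })
})

test_that("Z' limits, scale invariance and SSMD antisymmetry hold", {
  g0 <- group_stats_values(10, 0, 5, 0)
  expect_equal(zprime(g0), 1)
  expect_error(ssmd(g0), class = "octscreen_param_error")
  expect_error(zprime(group_stats_values(5, 1, 5, 1)),
               class = "octscreen_param_error")
  g <- group_stats_values(191.8, 11.5, 133.7, 8.4)
  gc <- group_stats_values(191.8 * 3, 11.5 * 3, 133.7 * 3, 8.4 * 3)
  expect_equal(zprime(g), zprime(gc))
  swapped <- group_stats_values(133.7, 8.4, 191.8, 11.5)
  expect_equal(ssmd(swapped), -ssmd(g))
  expect_equal(zprime(swapped), zprime(g))
  expect_equal(ssmd(group_stats_values(7, 2, 7, 3)), 0)
})

test_that("pooled SD follows the weighted-variance formula", {
  expect_equal(pooled_sd(list(c(2, 2, 2), c(5, 5))), 0)
  expect_equal(pooled_sd(list(c(1, 4, 7, 2))), stats::sd(c(1, 4, 7, 2)))
  expect_equal(pooled_sd(list(c(1, 3), c(10, 14))), sqrt(5))
  expect_error(pooled_sd(list(c(1, 3), 7)), class = "octscreen_param_error")

  # equal-sized sets: pooled SD matches the residual SD up to the weighting
  withr::with_seed(33, {
    sets <- lapply(1:6, function(i) rnorm(5, mean = i * 10))
    resid <- unlist(lapply(sets, function(s) s - mean(s)))
    brute <- sqrt(sum(resid^2) / (length(resid) - length(sets)))
    expect_equal(pooled_sd(sets), brute)
  })
})

test_that("repeatability and reproducibility recover configured noise", {
  d0 <- make_screen_dataset(repeat_sd = 0, seed = 2)
  expect_equal(repeatability(d0), 0)

  d <- make_screen_dataset(n_negative = 10, n_positive = 10,
                           baseline_sd_um = 12.1, repeat_sd = 0.4,
                           n_repeats = 5, seed = 6)
  expect_rel_error(repeatability(d), 0.4, 0.2)
  expect_rel_error(
    reproducibility(d, condition = c(timepoint = "baseline")), 12.1, 0.25)
})

test_that("percent change is the signed relative difference", {
  expect_equal(percent_change(150, 150), 0)
  expect_equal(percent_change(191.8, 133.7), -30.29, tolerance = 1e-3)
  expect_equal(percent_change(100, 130), 30)
  expect_error(percent_change(0, 10), class = "octscreen_param_error")
})

test_that("quality flags follow the conventional thresholds", {
  f <- quality_flag(0.70, 8.8)
  expect_equal(f$flag, c("excellent", "excellent"))
  expect_equal(quality_flag(0.49, 8.8)$flag[1], "below-threshold")
  expect_equal(quality_flag(0.5, 2)$flag, c("excellent", "below-threshold"))
  expect_equal(quality_flag(0.7, -8.8)$flag[2], "excellent")
})

test_that("group comparison is a symmetric two-sided Welch test", {
  a <- c(1, 2, 3, 4); b <- c(1.1, 1.9, 3.2, 3.8)
  expect_equal(group_compare(a, b), group_compare(b, a))
  expect_gt(group_compare(a, a + 1e-12), 0.99)
  expect_error(group_compare(c(1, 1), c(1, 1)),
               class = "octscreen_param_error")

  withr::with_seed(9, {
    x <- rnorm(8, 0, 1); y <- rnorm(8, 5, 1)
    p <- group_compare(x, y)
    expect_lt(p, 0.001)
    # permutation oracle: the Welch p is of the same order as the
    # permutation tail probability of the mean difference
    obs <- abs(mean(x) - mean(y))
    pool <- c(x, y)
    exceed <- vapply(1:2000, function(i) {
      idx <- sample(16, 8)
      abs(mean(pool[idx]) - mean(pool[-idx])) >= obs
    }, logical(1))
    expect_lt(mean(exceed), 0.005)
  })
})

test_that("assay_quality assembles the full QC panel with broom methods", {
  d <- make_screen_dataset(seed = 11)
  q <- assay_quality(d, "thickness_um", timepoint = "day10")
  expect_s3_class(q, "assay_quality")
  expect_lt(q$zprime, 1)
  expect_equal(sign(q$ssmd),
               sign(q$group_stats$mu_positive - q$group_stats$mu_negative))
  td <- tidy(q)
  expect_equal(td$metric,
               c("zprime", "ssmd", "repeatability", "reproducibility",
                 "p_value"))
  gl <- glance(q)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$zprime, q$zprime)
  rep_full <- qc_report(d, timepoint = "day10")
  expect_equal(rep_full$readout, c("thickness_um", "area_mm2", "volume_mm3"))
})
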