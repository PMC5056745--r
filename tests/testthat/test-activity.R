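test_that("von Mises concentration ML inverts A1 and handles extremes", {
  # degenerate: identical angles hit the cap
  expect_equal(vonmises_kappa_ml(rep(1.2, 5)), 500)
  expect_equal(vonmises_kappa_ml(rep(1.2, 5), kappa_max = 50), 50)

  # large uniform sample: concentration near zero
  set.seed(31)
  expect_lt(vonmises_kappa_ml(runif(10000, 0, 2 * pi)), 0.05)

  # Rbar = 0.5: agree with an independent bisection of A1 = I1/I0
  a1 <- function(k) besselI(k, 1) / besselI(k, 0)
  lo <- 0; hi <- 20
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (a1(mid) < 0.5) lo <- mid else hi <- mid
  }
  # build a sample with Rbar exactly 0.5: two angles at +/- acos-spread
  spread <- acos(0.5)
  theta <- c(1 + spread, 1 - spread)
  expect_equal(vonmises_kappa_ml(theta), (lo + hi) / 2, tolerance = 1e-6)
})

test_that("the plug-in bandwidth follows its formula and scalings", {
  # direct evaluation with unscaled Bessel functions as the oracle
  oracle <- function(kappa, n) {
    (3 * n * kappa^2 * besselI(2 * kappa, 2) /
       (4 * sqrt(pi) * besselI(kappa, 1)^2))^(2 / 5)
  }
  expect_equal(plugin_bandwidth(1, 100), oracle(1, 100), tolerance = 1e-10)
  expect_equal(plugin_bandwidth(2.5, 37), oracle(2.5, 37), tolerance = 1e-10)

  # adjust is a divisor: doubling it halves the kernel concentration
  expect_equal(plugin_bandwidth(1, 100, adjust = 2),
               plugin_bandwidth(1, 100) / 2)

  # more data -> sharper kernel
  expect_gt(plugin_bandwidth(1, 500), plugin_bandwidth(1, 50))

  # zero concentration falls back to a positive floor with a warning
  expect_warning(bw0 <- plugin_bandwidth(0, 100), "minimal")
  expect_gt(bw0, 0)
})

test_that("the circular KDE integrates to 1 and matches brute force", {
  set.seed(32)
  x <- rvonmises(60, 2, 3)
  f <- fit_activity(x, units = "radians")
  expect_equal(glance(f)$integral, 1, tolerance = 1e-6)
  expect_true(all(f$grid$density >= 0))

  at <- runif(20, 0, 2 * pi)
  expect_equal(predict(f, at, units = "radians"),
               naive_kde(at, f$sample, f$kappa_kernel), tolerance = 1e-12)

  # n = 1: the density is the single kernel itself
  f1 <- fit_activity(3, units = "radians")
  expect_equal(predict(f1, at, units = "radians"),
               dvonmises(at, 3, f1$kappa_kernel), tolerance = 1e-12)
})

test_that("overlap of identical samples is complete", {
  set.seed(33)
  x <- (rvonmises(100, 5, 2)) * 24 / (2 * pi)
  f <- fit_activity(x)
  o <- overlap_coefficient(f, f)
  expect_equal(o$dhat4, 1)
  expect_equal(o$dhat1, 1, tolerance = 1e-3)
})

test_that("opposed tight activity peaks barely overlap", {
  set.seed(34)
  x <- fit_activity(rvonmises(200, 0, 50), units = "radians")
  y <- fit_activity(rvonmises(200, pi, 50), units = "radians")
  o <- overlap_coefficient(x, y)
  expect_lt(o$dhat1, 0.05)
  expect_lt(o$dhat4, 0.05)
})

test_that("overlap is symmetric and estimator selection follows sample size", {
  set.seed(35)
  a <- fit_activity(rvonmises(60, 1, 2), units = "radians")
  b <- fit_activity(rvonmises(90, 4, 2), units = "radians")
  o1 <- overlap_coefficient(a, b)
  o2 <- overlap_coefficient(b, a)
  expect_equal(o1$dhat1, o2$dhat1, tolerance = 1e-12)
  expect_equal(o1$dhat4, o2$dhat4, tolerance = 1e-12)
  expect_equal(o1$estimator, "Dhat1") # min(n) = 60 < 75

  big_a <- fit_activity(rvonmises(80, 1, 2), units = "radians")
  big_b <- fit_activity(rvonmises(120, 4, 2), units = "radians")
  expect_equal(overlap_coefficient(big_a, big_b)$estimator, "Dhat4")
  expect_equal(overlap_coefficient(big_a, big_b, estimator = "Dhat1")$estimator,
               "Dhat1")
})

test_that("Dhat converges to the analytic min-integral of the true densities", {
  # fine numeric integration of min of two known von Mises densities
  grid <- seq(0, 2 * pi, length.out = 8193)[-8193]
  truth <- mean(pmin(dvonmises(grid, 2, 3), dvonmises(grid, 5, 1.5))) * 2 * pi
  set.seed(36)
  f <- fit_activity(rvonmises(2000, 2, 3), units = "radians")
  g <- fit_activity(rvonmises(2000, 5, 1.5), units = "radians")
  o <- overlap_coefficient(f, g)
  expect_equal(o$dhat1, truth, tolerance = 0.03 / truth)
  expect_equal(o$dhat4, truth, tolerance = 0.03 / truth)
})

test_that("the smoothed bootstrap is reproducible and sane", {
  set.seed(37)
  x <- rvonmises(100, 5.5, 2) * 24 / (2 * pi)
  y <- rvonmises(100, 5.5, 2) * 24 / (2 * pi)
  o1 <- bootstrap_overlap_ci(x, y, n_boot = 150, seed = 99)
  o2 <- bootstrap_overlap_ci(x, y, n_boot = 150, seed = 99)
  expect_equal(o1$ci_low, o2$ci_low)
  expect_equal(o1$ci_high, o2$ci_high)
  expect_true(o1$ci_low <= o1$delta && o1$delta <= o1$ci_high)

  # identical samples: the interval reaches near-complete overlap; its
  # upper percentile sits just below 1 because bootstrap replicates
  # compare two finite redraws (boundary bias of the percentile method,
  # logged as a warning since the point estimate Dhat = 1 exceeds it)
  o_same <- suppressWarnings(bootstrap_overlap_ci(x, x, n_boot = 500, seed = 7))
  expect_gte(o_same$ci_high, 0.94)
  expect_equal(o_same$delta, 1)

  # self-consistency: resampling a fitted density recovers near-complete
  # overlap with the original sample
  fit <- fit_activity(x)
  set.seed(3)
  redrawn <- (sample(fit$sample, fit$n, TRUE) +
                rvonmises(fit$n, 0, fit$kappa_kernel)) %% (2 * pi)
  o_self <- overlap_coefficient(fit, fit_activity(redrawn, units = "radians"))
  expect_gt(o_self$delta, 0.85)
})
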