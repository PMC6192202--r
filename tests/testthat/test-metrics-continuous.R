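# Continuous imbalance metrics.

test_that("t-test imbalance matches the closed-form Welch statistic", {
  x <- c(2.0, 3.5, 1.1, 4.2)
  expect_equal(imb_1pt(two_sample(x, x)), 0, tolerance = 1e-12)
  # A={1,2,3}, B={4,5,6}: t = -3/sqrt(2/3), df = 4 (equal variances)
  expected <- 1 - 2 * pt(-3 / sqrt(2 / 3), df = 4)
  expect_equal(imb_1pt(two_sample(c(1, 2, 3), c(4, 5, 6))), expected,
               tolerance = 1e-12)
  expect_equal(imb_1pt(two_sample(c(4, 5, 6), c(1, 2, 3))), expected,
               tolerance = 1e-12)
  # degenerate limits
  expect_warning(v0 <- imb_1pt(two_sample(c(2, 2), c(2, 2))),
                 class = "ccr_degenerate")
  expect_equal(v0, 0)
  expect_warning(v1 <- imb_1pt(two_sample(c(2, 2), c(3, 3))),
                 class = "ccr_degenerate")
  expect_equal(v1, 1)
})

test_that("U-test imbalance is exact for small untied samples and shift-monotone", {
  expect_equal(imb_1pu(two_sample(c(1, 5, 3), c(1, 5, 3))), 0, tolerance = 1e-12)
  expect_equal(imb_1pu(two_sample(c(1, 2), c(3, 4))), 2 / 3, tolerance = 1e-12)
  a <- c(0.3, 1.9, 2.6, 0.7, 1.1)
  prev <- -Inf
  for (delta in seq(0, 3, by = 0.5)) {
    v <- imb_1pu(two_sample(a, a + delta))
    expect_gte(v + 1e-12, prev)
    prev <- v
  }
})

test_that("KS imbalance is exact for small untied samples and symmetric", {
  expect_equal(imb_1pks(two_sample(c(1, 2, 3), c(1, 2, 3))), 0, tolerance = 1e-12)
  expect_equal(imb_1pks(two_sample(c(1, 2), c(3, 4))),
               1 - perm_pvalue_ks(c(1, 2), c(3, 4)), tolerance = 1e-12)
  a <- c(0.1, 0.7, 2.2); b <- c(1.4, 0.3, 3.1, 2.8)
  expect_equal(imb_1pks(two_sample(a, b)), imb_1pks(two_sample(b, a)))
})

test_that("exact U and KS p-values agree with full permutation enumeration (pooled <= 10)", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    repeat {
      pooled <- round(runif(n + m, 0, 100), 3)
      if (!anyDuplicated(pooled)) break
    }
    a <- pooled[seq_len(n)]; b <- pooled[-seq_len(n)]
    expect_equal(imb_1pks(two_sample(a, b)), 1 - perm_pvalue_ks(a, b),
                 tolerance = 1e-10)
    expect_equal(imb_1pu(two_sample(a, b)), 1 - perm_pvalue_u(a, b),
                 tolerance = 1e-10)
  }
})

test_that("quartiles follow the type-7 interpolation rule", {
  expect_equal(quartiles(c(1, 2, 3)), c(1.5, 2, 2.5))
  expect_equal(quartiles(5), c(5, 5, 5))
  set.seed(41)
  x <- rnorm(11)
  expect_equal(quartiles(3 * x + 2), 3 * quartiles(x) + 2, tolerance = 1e-12)
  q <- quartiles(runif(20))
  expect_true(q[1] <= q[2] && q[2] <= q[3])
})

test_that("maximum relative quartile difference is exact and scale invariant", {
  expect_equal(imb_mrdq(two_sample(c(1, 5, 2), c(1, 5, 2))), 0)
  # quartiles of B = {2,4,6} are exactly twice those of A = {1,2,3}
  expect_equal(imb_mrdq(two_sample(c(1, 2, 3), c(2, 4, 6))), 0.5,
               tolerance = 1e-12)
  a <- c(0.4, 1.8, 2.3, 0.9); b <- c(1.1, 3.0, 0.2, 2.7)
  expect_equal(imb_mrdq(two_sample(7 * a, 7 * b)),
               imb_mrdq(two_sample(a, b)), tolerance = 1e-12)
  # both medians exactly 0: that pair contributes 0 instead of 0/0
  expect_equal(imb_mrdq(two_sample(c(-1, 0, 1), c(-2, 0, 2))), 0.5)
})

test_that("area between ECDFs is computed exactly on the step functions", {
  expect_equal(imb_abcdf(two_sample(c(1, 2), c(1, 2))), 0)
  expect_equal(imb_abcdf(two_sample(c(0, 1), c(2, 3))), 2, tolerance = 1e-12)
  # pure shift of identical samples: area equals the shift
  a <- c(0.2, 1.4, 2.9, 3.3)
  for (delta in c(0.25, 1, 2.5))
    expect_equal(imb_abcdf(two_sample(a, a + delta)), delta, tolerance = 1e-9)
  # quadrature cross-check on a fine step-aligned grid
  set.seed(51)
  x <- round(runif(6), 2); y <- round(runif(5), 2)
  grid <- seq(min(c(x, y)), max(c(x, y)), by = 1e-4)
  riemann <- sum(abs(ecdf(x)(grid[-length(grid)]) -
                     ecdf(y)(grid[-length(grid)]))) * 1e-4
  expect_equal(imb_abcdf(two_sample(x, y)), riemann, tolerance = 1e-6)
})

test_that("density estimates share a grid, integrate to one and respect the floor", {
  set.seed(61)
  a <- rnorm(30); b <- rnorm(25, 1)
  de <- estimate_densities(two_sample(a, b))
  tr <- function(y) sum(diff(de$grid) * (y[-1] + y[-length(y)])) / 2
  expect_equal(tr(de$density_A), 1, tolerance = 1e-3)
  expect_equal(tr(de$density_B), 1, tolerance = 1e-3)
  expect_true(all(de$density_A >= 1e-12) && all(de$density_B >= 1e-12))
  expect_true(all(diff(de$grid) > 0))
  de_same <- estimate_densities(two_sample(a, a))
  expect_equal(de_same$density_A, de_same$density_B)
  expect_warning(estimate_densities(two_sample(rep(2, 3), c(1, 2, 3))),
                 class = "ccr_degenerate")
})

test_that("symmetrised KL of estimated densities is zero on identity, symmetric, and tracks the Gaussian closed form", {
  set.seed(71)
  a <- rnorm(40)
  expect_equal(imb_skl(two_sample(a, a)), 0, tolerance = 1e-9)
  b <- rnorm(35, 0.8)
  expect_equal(imb_skl(two_sample(a, b)), imb_skl(two_sample(b, a)),
               tolerance = 1e-12)
  # unit-variance Gaussians, means 0 and mu: symmetrised KL = mu^2.
  # Noise-free quantile samples isolate the estimator's systematic error
  # (bandwidth attenuation + kernel tails) from Monte-Carlo noise.
  x <- qnorm(ppoints(200))
  prev <- 0
  for (mu in c(0.5, 1, 2)) {
    est <- imb_skl(two_sample(x, x + mu))
    expect_gt(est, prev)
    expect_lt(abs(est - mu^2) / mu^2, 0.3)
    prev <- est
  }
})

test_that("continuous metrics are nonnegative, arm-symmetric and zero on identical samples", {
  set.seed(81)
  for (i in 1:40) {
    a <- rnorm(sample(4:9, 1), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(4:9, 1), mean = runif(1, -1, 1))
    for (nm in names(continuous_metric_fns)) {
      fn <- continuous_metric_fns[[nm]]
      v <- fn(a, b)
      expect_gte(v, 0)
      expect_equal(fn(b, a), v, tolerance = 1e-10)
      expect_equal(fn(a, a), 0, tolerance = 1e-9)
      if (nm %in% c("1-Pt", "1-PU", "1-PKS")) expect_lte(v, 1)
    }
  }
})
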