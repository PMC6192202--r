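# Imbalance metrics for continuous variables: two real-valued samples
# (arm A, arm B) mapped to a nonnegative imbalance, 0 meaning the arms'
# distributions are indistinguishable by the measure.

# product threshold below which exact small-sample p-values are used
EXACT_P_LIMIT <- 400

#' Bundle the two arms' values of a continuous variable
#'
#' @param sample_A,sample_B Nonempty numeric vectors of finite values.
#' @return An object of class `"two_sample"`.
#' @export
two_sample <- function(sample_A, sample_B) {
  sample_A <- as.numeric(sample_A); sample_B <- as.numeric(sample_B)
  if (length(sample_A) == 0L || length(sample_B) == 0L)
    ccr_stop("empty_arm", "both samples must be nonempty")
  if (any(!is.finite(sample_A)) || any(!is.finite(sample_B)))
    ccr_stop("type_error", "samples must be finite")
  structure(list(sample_A = sample_A, sample_B = sample_B),
            class = "two_sample")
}

as_two_sample <- function(x, b = NULL) {
  if (inherits(x, "two_sample")) x else two_sample(x, b)
}

#' t-test p-value imbalance (1-Pt)
#'
#' One minus the two-sided p-value of Welch's two-sample t test. Limit
#' cases: both samples constant and equal gives 0; both constant but
#' unequal gives 1 (the p-value tends to 0 as the means separate at zero
#' variance), each with a classed warning.
#'
#' @param ts A [two_sample()], or arm-A values if `b` is given.
#' @param b Optional arm-B values.
#' @return Imbalance in \[0, 1\].
#' @family continuous imbalance metrics
#' @export
imb_1pt <- function(ts, b = NULL) {
  ts <- as_two_sample(ts, b)
  a <- ts$sample_A; b <- ts$sample_B
  if (stats::var(a) + stats::var(b) == 0 || length(a) < 2L || length(b) < 2L) {
    if (length(unique(c(a, b))) == 1L) {
      ccr_warn("degenerate", "both samples constant and equal: imbalance 0")
      return(0)
    }
    if (length(unique(a)) == 1L && length(unique(b)) == 1L) {
      ccr_warn("degenerate", "both samples constant and unequal: imbalance 1")
      return(1)
    }
    ccr_stop("degenerate", "t test needs >= 2 values per arm with some variance")
  }
  1 - stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' Mann-Whitney U-test p-value imbalance (1-PU)
#'
#' One minus the two-sided p-value of the Mann-Whitney (Wilcoxon rank-sum)
#' test. The exact distribution is used when there are no ties and
#' \eqn{n_A n_B \le 400}; otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @inheritParams imb_1pt
#' @family continuous imbalance metrics
#' @export
imb_1pu <- function(ts, b = NULL) {
  ts <- as_two_sample(ts, b)
  a <- ts$sample_A; b <- ts$sample_B
  pooled <- c(a, b)
  exact <- !anyDuplicated(pooled) && length(a) * length(b) <= EXACT_P_LIMIT
  p <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
  1 - min(1, p)
}

#' Kolmogorov-Smirnov p-value imbalance (1-PKS)
#'
#' One minus the two-sided p-value of the two-sample Kolmogorov-Smirnov
#' test. The statistic D is the maximal distance between the two empirical
#' distribution functions, evaluated on the pooled values (valid under
#' ties). The p-value is exact (conditional permutation distribution, via
#' [stats::psmirnov()]) when there are no ties and \eqn{n_A n_B \le 400},
#' and the asymptotic Kolmogorov distribution otherwise.
#'
#' @inheritParams imb_1pt
#' @family continuous imbalance metrics
#' @export
imb_1pks <- function(ts, b = NULL) {
  ts <- as_two_sample(ts, b)
  a <- ts$sample_A; b <- ts$sample_B
  n <- length(a); m <- length(b)
  D <- ks_statistic(a, b)
  exact <- !anyDuplicated(c(a, b)) && n * m <= EXACT_P_LIMIT
  p <- if (exact) {
    stats::psmirnov(D, sizes = c(n, m), two.sided = TRUE, exact = TRUE,
                    lower.tail = FALSE)
  } else {
    kolmogorov_sf(sqrt(n * m / (n + m)) * D)
  }
  1 - min(1, max(0, p))
}

# max |F_A - F_B| over the pooled support (right-continuous step ECDFs)
ks_statistic <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  Fa <- stats::ecdf(a)(grid)
  Fb <- stats::ecdf(b)(grid)
  max(abs(Fa - Fb))
}

# survival function of the Kolmogorov distribution,
# P(K > t) = 2 * sum_{j>=1} (-1)^(j-1) exp(-2 j^2 t^2)
kolmogorov_sf <- function(t) {
  if (t <= 0) return(1)
  j <- seq_len(101)
  s <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * t^2))
  min(1, max(0, s))
}

#' Sample quartiles (lower quartile, median, upper quartile)
#'
#' Linear-interpolation quantiles of order statistics with
#' \eqn{h = (n-1)p + 1} (the standard "type 7" convention, the default of
#' most statistical environments). Centralised here so the convention can
#' be swapped in one place.
#'
#' @param sample Nonempty numeric vector.
#' @return Numeric vector `c(q25, median, q75)`.
#' @export
quartiles <- function(sample) {
  if (length(sample) == 0L) ccr_stop("empty_arm", "sample must be nonempty")
  unname(stats::quantile(sample, probs = c(0.25, 0.5, 0.75), type = 7))
}

#' Maximum relative difference of quartiles (Mrdq)
#'
#' For the lower quartiles, medians and upper quartiles of the two arms,
#' the maximum over the three pairs of
#' \eqn{|q^A - q^B| / \max(|q^A|, |q^B|)}. A pair with both quartiles
#' exactly 0 (the only case with a zero denominator, where the numerator
#' is also 0) contributes 0, by continuity.
#'
#' @inheritParams imb_1pt
#' @family continuous imbalance metrics
#' @export
imb_mrdq <- function(ts, b = NULL) {
  ts <- as_two_sample(ts, b)
  qa <- quartiles(ts$sample_A); qb <- quartiles(ts$sample_B)
  denom <- pmax(abs(qa), abs(qb))
  terms <- ifelse(denom > 0, abs(qa - qb) / denom, 0)
  max(terms)
}

#' Area between empirical CDFs (AbCDF)
#'
#' \eqn{\int |F_A(x) - F_B(x)|\,dx} over the combined data range, computed
#' exactly as the sum over adjacent pooled sorted values of
#' \eqn{|F_A - F_B|} times the segment length (ECDFs are right-continuous
#' step functions, constant on each segment). For a pure location shift
#' \eqn{\delta} of identical samples the area equals \eqn{\delta}.
#'
#' @inheritParams imb_1pt
#' @family continuous imbalance metrics
#' @export
imb_abcdf <- function(ts, b = NULL) {
  ts <- as_two_sample(ts, b)
  grid <- sort(unique(c(ts$sample_A, ts$sample_B)))
  if (length(grid) == 1L) return(0)
  Fa <- stats::ecdf(ts$sample_A)(grid)
  Fb <- stats::ecdf(ts$sample_B)(grid)
  n <- length(grid)
  sum(abs(Fa[-n] - Fb[-n]) * diff(grid))
}

#' Gaussian kernel density estimates on a shared grid
#'
#' Estimates each arm's density with a Gaussian kernel and Silverman's
#' rule-of-thumb bandwidth, evaluated on a shared grid of `n_grid` equally
#' spaced points spanning the pooled range widened by three times the
#' larger bandwidth. Densities are floored at `eps` (so logarithms are
#' finite) and renormalised to integrate to 1 by the trapezoidal rule. A
#' constant sample gets a fixed fallback bandwidth of 1e-3, with a classed
#' warning.
#'
#' @inheritParams imb_1pt
#' @param n_grid Number of grid points (default 512).
#' @param eps Density floor (default 1e-12).
#' @return An object of class `"density_estimate"` with elements `grid`,
#'   `density_A`, `density_B`, `bandwidths`.
#' @export
estimate_densities <- function(ts, b = NULL, n_grid = 512, eps = 1e-12) {
  ts <- as_two_sample(ts, b)
  bw <- vapply(list(ts$sample_A, ts$sample_B), function(x) {
    if (length(unique(x)) < 2L) {
      ccr_warn("degenerate", "constant sample: fallback KDE bandwidth 1e-3")
      1e-3
    } else stats::bw.nrd0(x)
  }, 0)
  pooled <- c(ts$sample_A, ts$sample_B)
  lo <- min(pooled) - 3 * max(bw)
  hi <- max(pooled) + 3 * max(bw)
  grid <- seq(lo, hi, length.out = n_grid)
  est <- function(x, h) {
    d <- stats::density(x, bw = h, from = lo, to = hi, n = n_grid)$y
    d <- pmax(d, eps)
    d / trapz(grid, d)
  }
  structure(list(grid = grid,
                 density_A = est(ts$sample_A, bw[1]),
                 density_B = est(ts$sample_B, bw[2]),
                 bandwidths = bw),
            class = "density_estimate")
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2

#' Symmetrised Kullback-Leibler divergence of estimated densities (SKL)
#'
#' \eqn{\int p^A \ln(p^A/p^B)\,dx + \int p^B \ln(p^B/p^A)\,dx} with
#' \eqn{p^A, p^B} the kernel density estimates of [estimate_densities()],
#' integrated by the trapezoidal rule on the shared grid and clamped below
#' at 0 (quadrature noise can produce tiny negatives).
#'
#' @inheritParams estimate_densities
#' @family continuous imbalance metrics
#' @export
imb_skl <- function(ts, b = NULL, n_grid = 512, eps = 1e-12) {
  de <- estimate_densities(ts, b, n_grid = n_grid, eps = eps)
  integrand <- de$density_A * log(de$density_A / de$density_B) +
    de$density_B * log(de$density_B / de$density_A)
  max(0, trapz(de$grid, integrand))
}
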