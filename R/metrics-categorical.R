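# Imbalance metrics for binary, categorical and (categorically treated)
# integer variables. All operate on a group summary: per-category counts
# and within-arm proportions for the two arms, with the category universe
# fixed once from the full dataset so summaries are comparable across
# allocation schemes.

#' Summarise a variable's distribution under an allocation scheme
#'
#' Computes per-category counts \eqn{n_x^A, n_x^B} and within-arm
#' proportions \eqn{p_x^A = n_x^A / n^A} (and likewise for B) for one
#' variable under one allocation. Categories are taken from the full
#' dataset (ordered by first appearance), not from the arms, so every
#' category has \eqn{n_x^A + n_x^B \ge 1} and summaries from different
#' schemes share the same category axis.
#'
#' @param values Per-unit variable values.
#' @param labels Per-unit arm labels, `"A"`/`"B"`, aligned with `values`.
#' @param categories Optional fixed category universe; defaults to
#'   `unique(values)` in order of first appearance.
#' @return An object of class `"group_summary"` with elements
#'   `categories`, `n_A`, `n_B`, `p_A`, `p_B`.
#' @export
group_summary <- function(values, labels, categories = NULL) {
  if (length(values) != length(labels))
    ccr_stop("length_mismatch", "values and labels differ in length")
  if (is.null(categories)) categories <- unique(values)
  idx <- match(values, categories)
  if (anyNA(idx))
    ccr_stop("type_error", "values outside the declared category universe")
  k <- length(categories)
  a <- labels == "A"
  n_A <- tabulate(idx[a], nbins = k)
  n_B <- tabulate(idx[!a], nbins = k)
  if (sum(n_A) == 0L || sum(n_B) == 0L)
    ccr_stop("empty_arm", "both arms must be nonempty")
  structure(list(categories = categories, n_A = n_A, n_B = n_B,
                 p_A = n_A / sum(n_A), p_B = n_B / sum(n_B)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  m <- rbind(n_A = x$n_A, n_B = x$n_B,
             p_A = round(x$p_A, 4), p_B = round(x$p_B, 4))
  colnames(m) <- as.character(x$categories)
  cat("<group_summary>\n"); print(m)
  invisible(x)
}

# single-category guard shared by all categorical metrics: a constant
# variable is perfectly balanced by definition, but worth flagging
degenerate_single_category <- function(s) {
  if (length(s$categories) > 1L) return(FALSE)
  ccr_warn("degenerate", "single-category variable: imbalance defined as 0")
  TRUE
}

#' Chi-squared p-value imbalance (1-PX2)
#'
#' One minus the p-value of Pearson's chi-squared test on the 2 x k
#' contingency table of arm-by-category counts (df = k - 1, asymptotic
#' p-value, no continuity correction). Using the p-value rather than the
#' statistic confines the range to \[0, 1\] and makes the measure increase
#' with decreasing balance.
#'
#' @param s A [group_summary()].
#' @return Imbalance in \[0, 1\]; 0 for a single-category variable (with a
#'   warning).
#' @family categorical imbalance metrics
#' @export
imb_1px2 <- function(s) {
  if (degenerate_single_category(s)) return(0)
  counts <- rbind(s$n_A, s$n_B)
  expd <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  stat <- sum((counts - expd)^2 / expd)
  1 - stats::pchisq(stat, df = length(s$categories) - 1L, lower.tail = FALSE)
}

#' Euclidean distance between category proportions (Eucl)
#'
#' \eqn{\sqrt{\sum_x (p_x^A - p_x^B)^2}}; the classical "quadratic
#' imbalance" of minimisation algorithms. Range \[0, sqrt(2)\].
#'
#' @inheritParams imb_1px2
#' @family categorical imbalance metrics
#' @export
imb_euclidean <- function(s) {
  if (degenerate_single_category(s)) return(0)
  sqrt(sum((s$p_A - s$p_B)^2))
}

#' Manhattan distance between category proportions (Manh)
#'
#' \eqn{\sum_x |p_x^A - p_x^B|}; the "average imbalance". Range \[0, 2\].
#'
#' @inheritParams imb_1px2
#' @family categorical imbalance metrics
#' @export
imb_manhattan <- function(s) {
  if (degenerate_single_category(s)) return(0)
  sum(abs(s$p_A - s$p_B))
}

#' Maximum distance between category proportions (Max)
#'
#' \eqn{\max_x |p_x^A - p_x^B|}; akin to the "maximal imbalance". Range
#' \[0, 1\].
#'
#' @inheritParams imb_1px2
#' @family categorical imbalance metrics
#' @export
imb_maximum <- function(s) {
  if (degenerate_single_category(s)) return(0)
  max(abs(s$p_A - s$p_B))
}

#' Chi-squared distance between category proportions (X2d)
#'
#' \eqn{\sqrt{\sum_x (p_x^A - p_x^B)^2 / (p_x^A + p_x^B)}}, a standardised
#' Euclidean distance. Denominators are positive because categories come
#' from the full dataset.
#'
#' @inheritParams imb_1px2
#' @family categorical imbalance metrics
#' @export
imb_chisq_distance <- function(s) {
  if (degenerate_single_category(s)) return(0)
  sqrt(sum((s$p_A - s$p_B)^2 / (s$p_A + s$p_B)))
}

#' Canberra distance between category proportions (Canb)
#'
#' \eqn{\sum_x |p_x^A - p_x^B| / (p_x^A + p_x^B)}; a "standardised range".
#' Range \[0, k\].
#'
#' @inheritParams imb_1px2
#' @family categorical imbalance metrics
#' @export
imb_canberra <- function(s) {
  if (degenerate_single_category(s)) return(0)
  sum(abs(s$p_A - s$p_B) / (s$p_A + s$p_B))
}

#' Hellinger distance between category proportions (Hell)
#'
#' \eqn{\sqrt{1 - \sum_x \sqrt{p_x^A p_x^B}}}. The radicand is clamped at
#' 0 to absorb floating-point drift. Range \[0, 1\].
#'
#' @inheritParams imb_1px2
#' @family categorical imbalance metrics
#' @export
imb_hellinger <- function(s) {
  if (degenerate_single_category(s)) return(0)
  sqrt(max(0, 1 - sum(sqrt(s$p_A * s$p_B))))
}

#' Symmetrised Bayesian Kullback-Leibler divergence (SBKL)
#'
#' Symmetrised KL divergence
#' \eqn{\sum_x \tilde p_x^A \ln(\tilde p_x^A/\tilde p_x^B) +
#'      \sum_x \tilde p_x^B \ln(\tilde p_x^B/\tilde p_x^A)}
#' of smoothed category distributions. The default smoothing is Laplace
#' (add-one): \eqn{\tilde p_x = (n_x + 1)/(n + k)} per arm, which is
#' strictly positive and sums to one — the only reading under which the
#' smoothing actually guarantees non-zero denominators. The alternative
#' `"printed"` form \eqn{\tilde p_x = p_x (n_x + 1)} is available for
#' auditability; note it is zero whenever \eqn{n_x = 0}, in which case the
#' divergence is computed with 0·log(0) := 0 and log-of-zero terms dropped.
#'
#' @inheritParams imb_1px2
#' @param smoothing `"laplace"` (default) or `"printed"`.
#' @family categorical imbalance metrics
#' @export
imb_sbkl <- function(s, smoothing = c("laplace", "printed")) {
  smoothing <- match.arg(smoothing)
  if (degenerate_single_category(s)) return(0)
  sm <- smoothed_proportions(s, smoothing)
  kl_term <- function(p, q) {
    t <- ifelse(p > 0, p * log(p / q), 0)
    sum(t[is.finite(t)])
  }
  kl_term(sm$ptilde_A, sm$ptilde_B) + kl_term(sm$ptilde_B, sm$ptilde_A)
}

#' Smoothed category proportions for SBKL
#'
#' @inheritParams imb_sbkl
#' @return List with `ptilde_A`, `ptilde_B`.
#' @keywords internal
#' @export
smoothed_proportions <- function(s, smoothing = c("laplace", "printed")) {
  smoothing <- match.arg(smoothing)
  k <- length(s$categories)
  if (smoothing == "laplace") {
    list(ptilde_A = (s$n_A + 1) / (sum(s$n_A) + k),
         ptilde_B = (s$n_B + 1) / (sum(s$n_B) + k))
  } else {
    list(ptilde_A = s$p_A * (s$n_A + 1),
         ptilde_B = s$p_B * (s$n_B + 1))
  }
}

#' Kolmogorov-Smirnov p-value imbalance for integer variables (1-PKS)
#'
#' One minus the p-value of the two-sided two-sample Kolmogorov-Smirnov
#' test, the statistic being the maximal distance between the two arms'
#' empirical distribution functions. Shares its engine with the continuous
#' version ([imb_1pks()]); ties (ubiquitous for integers) are handled by
#' evaluating D on the pooled ECDF with an asymptotic p-value.
#'
#' @param values Per-unit integer values.
#' @param labels Per-unit arm labels `"A"`/`"B"`.
#' @return Imbalance in \[0, 1\].
#' @family categorical imbalance metrics
#' @export
imb_1pks_discrete <- function(values, labels) {
  a <- labels == "A"
  if (!any(a) || all(a)) ccr_stop("empty_arm", "both arms must be nonempty")
  imb_1pks(two_sample(values[a], values[!a]))
}
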