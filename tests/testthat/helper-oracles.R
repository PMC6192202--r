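# Independent oracles and small fixtures, all built in code.

# all C(n+m, n) assignments of the pooled values to arm A
all_splits <- function(n_a, n_total) {
  utils::combn(n_total, n_a, simplify = FALSE)
}

# brute-force two-sided KS p-value: proportion of splits whose D is at
# least the observed D (conditional permutation distribution)
perm_pvalue_ks <- function(a, b) {
  pooled <- c(a, b)
  ks_d <- function(x, y) {
    g <- sort(unique(c(x, y)))
    max(abs(ecdf(x)(g) - ecdf(y)(g)))
  }
  d_obs <- ks_d(a, b)
  ds <- vapply(all_splits(length(a), length(pooled)), function(idx)
    ks_d(pooled[idx], pooled[-idx]), 0)
  mean(ds >= d_obs - 1e-12)
}

# brute-force two-sided Mann-Whitney p-value via the permutation
# distribution of |U - n_a n_b / 2|
perm_pvalue_u <- function(a, b) {
  pooled <- c(a, b)
  u_stat <- function(x, y) {
    sum(vapply(x, function(xi) sum(xi > y) + 0.5 * sum(xi == y), 0))
  }
  center <- length(a) * length(b) / 2
  dev_obs <- abs(u_stat(a, b) - center)
  devs <- vapply(all_splits(length(a), length(pooled)), function(idx)
    abs(u_stat(pooled[idx], pooled[-idx]) - center), 0)
  mean(devs >= dev_obs - 1e-12)
}

# group summary built from explicit per-category counts; categories with
# no units at all are dropped, mirroring a universe taken from the data
summary_from_counts <- function(n_A, n_B) {
  keep <- n_A + n_B > 0
  n_A <- n_A[keep]; n_B <- n_B[keep]
  k <- length(n_A)
  cats <- letters[seq_len(k)]
  values <- rep(cats, times = n_A + n_B)
  labels <- unlist(lapply(seq_len(k), function(i)
    rep(c("A", "B"), c(n_A[i], n_B[i]))))
  group_summary(values, labels, categories = cats)
}

# deterministic 8-unit fixture with all four variable types
small_table <- function() {
  unit_table(
    ids = paste0("u", 1:8),
    values = data.frame(
      bin = c("0", "1", "0", "1", "0", "1", "0", "1"),
      cat = c("x", "y", "z", "x", "y", "x", "x", "z"),
      int = c(1, 3, 2, 2, 4, 1, 0, 3),
      con = c(0.5, 1.2, 2.2, 0.9, 1.7, 2.9, 0.1, 1.4),
      stringsAsFactors = FALSE),
    variables = list(variable_spec("bin", "binary"),
                     variable_spec("cat", "categorical"),
                     variable_spec("int", "integer"),
                     variable_spec("con", "continuous")))
}

# every categorical metric, as (identifier, function over a group_summary)
categorical_metric_fns <- list(
  "1-PX2" = imb_1px2, "Eucl" = imb_euclidean, "Manh" = imb_manhattan,
  "Max" = imb_maximum, "X2d" = imb_chisq_distance, "Canb" = imb_canberra,
  "Hell" = imb_hellinger, "SBKL" = imb_sbkl)

# every continuous metric, as (identifier, function over two samples)
continuous_metric_fns <- list(
  "1-Pt" = function(a, b) imb_1pt(two_sample(a, b)),
  "1-PU" = function(a, b) imb_1pu(two_sample(a, b)),
  "1-PKS" = function(a, b) imb_1pks(two_sample(a, b)),
  "Mrdq" = function(a, b) imb_mrdq(two_sample(a, b)),
  "AbCDF" = function(a, b) imb_abcdf(two_sample(a, b)),
  "SKL" = function(a, b) imb_skl(two_sample(a, b)))
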