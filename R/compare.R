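# The metric-comparison study: for one variable, score every scheme with
# all type-matching metrics and compare the metrics pairwise — Spearman
# rank correlations, distinct-value counts, and the subsets of schemes
# each metric considers optimally balanced.

#' Build a comparison report from a contributions matrix
#'
#' Low-level constructor: given a schemes x metrics matrix of imbalance
#' contributions, computes the pairwise Spearman rank correlation matrix
#' (average ranks for ties), each metric's mean correlation with all
#' others, distinct-value counts, optimal (argmin) subsets and their
#' pairwise equality. A metric whose contributions are all identical is
#' flagged degenerate; its correlation entries are reported as NA rather
#' than propagating NaN.
#'
#' @param contrib Numeric matrix, one column per metric (named).
#' @param variable Optional variable name carried along for reporting.
#' @param tol Tolerance for "equal" contribution values when counting
#'   distinct values and forming argmin sets (default 1e-12).
#' @return An object of class `"comparison_report"`.
#' @export
comparison_report <- function(contrib, variable = NA_character_, tol = 1e-12) {
  stopifnot(is.matrix(contrib), !is.null(colnames(contrib)))
  if (nrow(contrib) < 2L)
    ccr_stop("bad_spec", "need at least two schemes to compare metrics")
  metrics <- colnames(contrib)
  m <- length(metrics)
  degenerate <- apply(contrib, 2, function(x) max(x) - min(x) <= tol)

  rho <- matrix(NA_real_, m, m, dimnames = list(metrics, metrics))
  ok <- which(!degenerate)
  if (length(ok) >= 1L)
    rho[ok, ok] <- suppressWarnings(
      stats::cor(contrib[, ok, drop = FALSE], method = "spearman"))
  diag(rho) <- 1

  rho_bar <- vapply(seq_len(m), function(i)
    mean(rho[i, -i], na.rm = TRUE), 0)
  rho_bar[degenerate] <- NA_real_
  names(rho_bar) <- metrics

  n_distinct <- apply(contrib, 2, function(x) {
    sx <- sort(x)
    1L + sum(diff(sx) > tol)
  })
  optimal <- lapply(seq_len(m), function(i) {
    x <- contrib[, i]
    which(x <= min(x) + tol)
  })
  names(optimal) <- metrics
  eq <- outer(seq_len(m), seq_len(m), Vectorize(function(i, j)
    identical(optimal[[i]], optimal[[j]])))
  dimnames(eq) <- list(metrics, metrics)

  structure(list(variable = variable, metrics = metrics, rho = rho,
                 rho_bar = rho_bar, n_distinct = n_distinct,
                 optimal_subset = optimal,
                 optimal_fraction = lengths(optimal) / nrow(contrib),
                 pairwise_optimal_equal = eq,
                 degenerate = degenerate,
                 n_schemes = nrow(contrib)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, digits = 3, ...) {
  cat(sprintf("<comparison_report> variable '%s', %d metrics, %d schemes\n",
              x$variable, length(x$metrics), x$n_schemes))
  cat("  Spearman rho:\n")
  print(round(x$rho, digits))
  tab <- data.frame(rho_bar = round(x$rho_bar, digits),
                    n_distinct = x$n_distinct,
                    optimal_fraction = round(x$optimal_fraction, digits))
  if (any(x$degenerate)) tab$degenerate <- x$degenerate
  print(tab)
  invisible(x)
}

#' Compare imbalance metrics on one variable
#'
#' Scores every scheme in `ss` with each metric in `metric_list` applied
#' to `variable`, then builds a [comparison_report()].
#'
#' @param table A [unit_table()].
#' @param variable Name of the variable to compare metrics on.
#' @param metric_list Metric identifiers, all admissible for the
#'   variable's type; defaults to every admissible metric.
#' @param ss A `scheme_set` (need not be scored).
#' @return A `comparison_report`.
#' @export
compare_metrics <- function(table, variable, metric_list = NULL, ss) {
  stopifnot(inherits(table, "unit_table"), inherits(ss, "scheme_set"))
  spec <- table$variables[[variable]]
  if (is.null(spec)) ccr_stop("undeclared_column",
                              sprintf("unknown variable '%s'", variable))
  if (is.null(metric_list)) metric_list <- METRICS_BY_VTYPE[[spec$vtype]]
  bad <- setdiff(metric_list, METRICS_BY_VTYPE[[spec$vtype]])
  if (length(bad))
    ccr_stop("bad_metric", sprintf(
      "metric(s) %s not admissible for %s variable '%s'",
      paste(bad, collapse = ", "), spec$vtype, variable))
  contrib <- vapply(metric_list, function(mt)
    variable_contributions(table$values[[variable]], spec$vtype, mt, ss$labels),
    numeric(nrow(ss$labels)))
  contrib <- matrix(contrib, nrow = nrow(ss$labels),
                    dimnames = list(NULL, metric_list))
  comparison_report(contrib, variable = variable)
}

#' Radar-chart export: standardised contributions by balance tier
#'
#' Splits a scored scheme set into the `top[1]` best schemes by total
#' imbalance, the next `top[2] - top[1]`, and the rest (the tiers drawn
#' black / dark grey / light grey in the radar display), with each
#' scheme's standardised per-variable contributions as the spoke values.
#'
#' @param ss A `scheme_set` scored with standardising weights (so each
#'   weighted contribution lies in \[0, 1\]; see [standardize_weights()]).
#' @param top Integer vector of two tier boundaries, default `c(10, 100)`.
#' @return Data frame: `scheme_id`, `tier` (`"best"`, `"next"`, `"rest"`),
#'   `total`, and one standardised-contribution column per variable.
#' @export
radar_export <- function(ss, top = c(10, 100)) {
  if (!isTRUE(ss$scored)) ccr_stop("unscored", "score the scheme set first")
  stopifnot(length(top) == 2L, top[1] <= top[2])
  n <- length(ss$totals)
  std <- sweep(ss$contributions, 2, ss$weights_used, `*`)
  rank_pos <- match(seq_len(n), order(ss$totals, ss$scheme_id))
  tier <- rep("rest", n)
  tier[rank_pos <= top[2]] <- "next"
  tier[rank_pos <= top[1]] <- "best"
  out <- data.frame(scheme_id = ss$scheme_id, tier = tier,
                    total = ss$totals, check.names = FALSE)
  for (v in colnames(std)) out[[v]] <- std[, v]
  out[order(rank_pos), , drop = FALSE]
}

#' Run the full metric-comparison study
#'
#' Generates (or enumerates) the allocation schemes for a dataset, scores
#' them with each variable's configured metric, standardises the weights,
#' and produces: one [comparison_report()] per variable covering all
#' type-matching metrics (on standardised contributions), the radar-chart
#' export, the total-imbalance ECDF and coverage statistics.
#'
#' @param table A [unit_table()].
#' @param cfg A [generation_config()]; mode `"auto"` enumerates whenever
#'   the scheme count is within the cap.
#' @param top Radar tier boundaries, default `c(10, 100)`.
#' @return An object of class `"ccr_study"`: list with `reports` (named by
#'   variable), `scheme_set`, `radar`, `ecdf`, `coverage`.
#' @export
run_study <- function(table, cfg = generation_config(mode = "auto"),
                      top = c(10, 100)) {
  ss <- generate_schemes(table, cfg)
  ss <- score_schemes(ss, table)
  w <- standardize_weights(ss)
  ss <- score_schemes(ss, table, weights = w)
  reports <- lapply(names(table$variables), function(vn) {
    rep <- compare_metrics(table, vn, NULL, ss)
    rep
  })
  names(reports) <- names(table$variables)
  structure(list(reports = reports, scheme_set = ss,
                 radar = radar_export(ss, top),
                 ecdf = imbalance_ecdf(ss),
                 coverage = ss$coverage),
            class = "ccr_study")
}

#' @export
print.ccr_study <- function(x, ...) {
  cv <- x$coverage
  cat(sprintf("<ccr_study> %d unique schemes (%.1f%% of %.0f possible)\n",
              cv$n_unique, 100 * cv$fraction, cv$n_possible))
  for (r in x$reports)
    cat(sprintf("  %-12s rho_bar: %s\n", r$variable,
                paste(sprintf("%s=%.2f", r$metrics, r$rho_bar), collapse = " ")))
  invisible(x)
}

#' Serialise a comparison report to JSON
#'
#' Schema: `{variable, metrics[], rho[][], rho_bar[], n_distinct[],
#' optimal_fraction[], pairwise_optimal_equal[][], degenerate[],
#' n_schemes}`. Optimal subsets (scheme indices) are included under
#' `optimal_subset`.
#'
#' @param report A `comparison_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_comparison_report <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  jsonlite::write_json(list(
    variable = report$variable,
    metrics = report$metrics,
    rho = report$rho,
    rho_bar = report$rho_bar,
    n_distinct = report$n_distinct,
    optimal_fraction = report$optimal_fraction,
    optimal_subset = report$optimal_subset,
    pairwise_optimal_equal = report$pairwise_optimal_equal,
    degenerate = report$degenerate,
    n_schemes = report$n_schemes),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read back a comparison report written by [write_comparison_report()]
#'
#' @param path JSON path.
#' @return A `comparison_report`.
#' @export
read_comparison_report <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  metrics <- j$metrics
  named_mat <- function(m) {
    m <- as.matrix(m); dimnames(m) <- list(metrics, metrics); m
  }
  structure(list(
    variable = j$variable, metrics = metrics,
    rho = named_mat(j$rho),
    rho_bar = stats::setNames(as.numeric(j$rho_bar), metrics),
    n_distinct = stats::setNames(as.integer(j$n_distinct), metrics),
    optimal_subset = lapply(j$optimal_subset, as.integer),
    optimal_fraction = stats::setNames(as.numeric(j$optimal_fraction), metrics),
    pairwise_optimal_equal = named_mat(j$pairwise_optimal_equal),
    degenerate = stats::setNames(as.logical(j$degenerate), metrics),
    n_schemes = as.integer(j$n_schemes)),
    class = "comparison_report")
}
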