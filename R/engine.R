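# The allocation engine: enumerate or sample two-arm allocation schemes
# respecting pre-assigned units and the allocation ratio, score each scheme
# by a weighted sum of per-variable imbalance contributions, standardise
# contributions, preselect well-balanced schemes and draw the final one.

#' Generation settings for allocation schemes
#'
#' @param allocation_ratio Relative size of arm A, in (0, 1). The arm-A
#'   size is `round(allocation_ratio * N)`, rounding halves away from zero
#'   (so 15 units at ratio 1/3 give a 5:10 split).
#' @param n_schemes Number of random schemes to draw in `"sample"` mode
#'   (default 10000).
#' @param remove_duplicates Drop duplicate label vectors, keeping first
#'   occurrences (default TRUE).
#' @param seed Integer seed for scheme generation. Kept separate from the
#'   final-choice seed so regenerating schemes never silently changes the
#'   final draw.
#' @param mode `"sample"` (shuffle `n_schemes` times), `"enumerate"` (all
#'   possible schemes, refused above `enumeration_cap`), or `"auto"`
#'   (enumerate when feasible, else sample).
#' @param enumeration_cap Largest scheme count enumerated (default 1e6).
#' @return An object of class `"generation_config"`.
#' @export
generation_config <- function(allocation_ratio = 0.5, n_schemes = 10000,
                              remove_duplicates = TRUE, seed = 1,
                              mode = c("sample", "enumerate", "auto"),
                              enumeration_cap = 1e6) {
  mode <- match.arg(mode)
  if (!is.numeric(allocation_ratio) || allocation_ratio <= 0 || allocation_ratio >= 1)
    ccr_stop("bad_spec", "allocation_ratio must lie strictly between 0 and 1")
  if (!is.numeric(n_schemes) || n_schemes < 1)
    ccr_stop("bad_spec", "n_schemes must be a positive integer")
  structure(list(allocation_ratio = allocation_ratio,
                 n_schemes = as.integer(n_schemes),
                 remove_duplicates = isTRUE(remove_duplicates),
                 seed = as.integer(seed), mode = mode,
                 enumeration_cap = enumeration_cap),
            class = "generation_config")
}

#' Count the possible allocation schemes
#'
#' Exact binomial coefficient \eqn{C(n_{free}, n_{A,free})}: the number of
#' distinct assignments of the free (not pre-assigned) units that put
#' `n_A_free` of them in arm A. Computed by the multiplicative formula in
#' double precision, exact for all values below 2^53.
#'
#' @param n_free Number of free units.
#' @param n_A_free Arm-A places among the free units.
#' @return The scheme count (numeric, integer-valued).
#' @examples
#' count_schemes(14, 7)  # 3432
#' count_schemes(15, 5)  # 3003
#' @export
count_schemes <- function(n_free, n_A_free) {
  if (n_A_free < 0 || n_A_free > n_free)
    ccr_stop("bad_spec", "need 0 <= n_A_free <= n_free")
  k <- min(n_A_free, n_free - n_A_free)
  if (k == 0) return(1)
  # multiplicative formula with exact intermediate integers
  out <- 1
  for (i in seq_len(k)) out <- out * (n_free - k + i) / i
  round(out)
}

# resolve arm sizes net of pre-assigned units; errors if fixed allocations
# exceed an arm's capacity
arm_layout <- function(table, allocation_ratio) {
  N <- length(table$ids)
  n_A <- round_half_up(allocation_ratio * N)
  if (n_A <= 0 || n_A >= N)
    ccr_stop("bad_spec", sprintf(
      "allocation ratio %g leaves an empty arm for %d units", allocation_ratio, N))
  free <- which(table$fixed == "")
  n_A_free <- n_A - sum(table$fixed == "A")
  n_B_free <- (N - n_A) - sum(table$fixed == "B")
  if (n_A_free < 0 || n_B_free < 0)
    ccr_stop("capacity", sprintf(
      "pre-assigned allocations exceed arm capacity (target %d:%d)", n_A, N - n_A))
  list(N = N, n_A = n_A, free = free, n_A_free = n_A_free, n_B_free = n_B_free)
}

#' Generate allocation schemes
#'
#' In `"sample"` mode, draws `cfg$n_schemes` schemes by repeatedly
#' shuffling a vector with the correct numbers of As and Bs over the free
#' units (uniform over feasible schemes); duplicates may then be removed,
#' keeping first occurrences. In `"enumerate"` mode, constructs all
#' possible schemes in lexicographic order of the arm-A positions among
#' the free units. Pre-assigned units keep their labels in every scheme.
#'
#' @param table A [unit_table()].
#' @param cfg A [generation_config()].
#' @return An object of class `"scheme_set"`: unique (or raw) schemes with
#'   their label matrix, coverage statistics, and room for scores (see
#'   [score_schemes()]).
#' @export
generate_schemes <- function(table, cfg) {
  stopifnot(inherits(table, "unit_table"), inherits(cfg, "generation_config"))
  lay <- arm_layout(table, cfg$allocation_ratio)
  n_possible <- count_schemes(length(lay$free), lay$n_A_free)
  mode <- cfg$mode
  if (mode == "auto")
    mode <- if (n_possible <= cfg$enumeration_cap) "enumerate" else "sample"

  base <- rep(c("A", "B"), c(lay$n_A_free, lay$n_B_free))
  if (mode == "enumerate") {
    if (n_possible > cfg$enumeration_cap)
      ccr_stop("cap_exceeded", sprintf(
        "%.0f possible schemes exceed the enumeration cap (%g)",
        n_possible, cfg$enumeration_cap))
    pos <- utils::combn(length(lay$free), lay$n_A_free)
    labels <- matrix("B", nrow = ncol(pos), ncol = lay$N)
    for (i in seq_len(lay$N)[-lay$free]) labels[, i] <- table$fixed[i]
    for (j in seq_len(ncol(pos)))
      labels[j, lay$free[pos[, j]]] <- "A"
    n_generated <- ncol(pos)
  } else {
    set.seed(cfg$seed)
    labels <- matrix(rep(table$fixed, each = cfg$n_schemes),
                     nrow = cfg$n_schemes, ncol = lay$N)
    draws <- replicate(cfg$n_schemes, sample(base))
    labels[, lay$free] <- if (is.matrix(draws)) t(draws) else as.matrix(draws)
    n_generated <- cfg$n_schemes
  }
  colnames(labels) <- table$ids

  if (cfg$remove_duplicates) {
    keys <- apply(labels, 1L, paste, collapse = "")
    labels <- labels[!duplicated(keys), , drop = FALSE]
  }
  n_unique <- nrow(labels)
  structure(list(
    labels = labels,
    scheme_id = seq_len(n_unique),
    mode = mode,
    coverage = list(n_generated = n_generated, n_unique = n_unique,
                    n_possible = n_possible,
                    fraction = n_unique / n_possible),
    contributions = NULL, totals = NULL, weights_used = NULL,
    scored = FALSE),
    class = "scheme_set")
}

#' @export
print.scheme_set <- function(x, ...) {
  cv <- x$coverage
  cat(sprintf("<scheme_set> %d schemes (%s mode), %d units\n",
              nrow(x$labels), x$mode, ncol(x$labels)))
  cat(sprintf("  coverage: %d unique of %.0f possible (%.1f%%), %d generated\n",
              cv$n_unique, cv$n_possible, 100 * cv$fraction, cv$n_generated))
  if (x$scored)
    cat(sprintf("  scored on %d variable(s); total imbalance range [%.4g, %.4g]\n",
                ncol(x$contributions), min(x$totals), max(x$totals)))
  invisible(x)
}

#' @export
summary.scheme_set <- function(object, ...) {
  print(object)
  if (object$scored) {
    cat("  per-variable contribution ranges:\n")
    rng <- apply(object$contributions, 2, range)
    for (v in colnames(object$contributions))
      cat(sprintf("    %-12s [%.4g, %.4g]  weight %g\n",
                  v, rng[1, v], rng[2, v], object$weights_used[[v]]))
  }
  invisible(object)
}

#' Plot the cumulative distribution of total imbalance
#'
#' @param x A scored `scheme_set`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.scheme_set <- function(x, ...) {
  if (!x$scored) ccr_stop("unscored", "score the scheme set first")
  e <- imbalance_ecdf(x)
  graphics::plot(e$total, e$cum_fraction, type = "s",
                 xlab = "total imbalance", ylab = "cumulative fraction", ...)
  invisible(x)
}

# per-scheme contributions of one variable under one metric.
# categorical-type metrics consume group summaries with the category
# universe fixed from the full dataset; sample-based metrics split raw
# values by arm.
variable_contributions <- function(values, vtype, metric, labels) {
  n <- nrow(labels)
  categorical_metric <- switch(metric,
    "1-PX2" = imb_1px2, "Eucl" = imb_euclidean, "Manh" = imb_manhattan,
    "Max" = imb_maximum, "X2d" = imb_chisq_distance, "Canb" = imb_canberra,
    "Hell" = imb_hellinger, "SBKL" = imb_sbkl, NULL)
  if (!is.null(categorical_metric)) {
    categories <- unique(values)
    if (length(categories) == 1L) {
      ccr_warn("degenerate", "single-category variable: all contributions 0")
      return(numeric(n))
    }
    out <- numeric(n)
    for (i in seq_len(n)) {
      s <- group_summary(values, labels[i, ], categories)
      out[i] <- categorical_metric(s)
    }
    return(out)
  }
  fn <- switch(metric,
    "1-PKS" = imb_1pks, "1-Pt" = imb_1pt, "1-PU" = imb_1pu,
    "Mrdq" = imb_mrdq, "AbCDF" = imb_abcdf, "SKL" = imb_skl,
    ccr_stop("bad_metric", sprintf("unknown metric '%s'", metric)))
  vapply(seq_len(n), function(i) {
    a <- labels[i, ] == "A"
    fn(two_sample(values[a], values[!a]))
  }, 0)
}

#' Score allocation schemes
#'
#' Computes each scheme's per-variable imbalance contribution with the
#' metric declared in the table's variable specs, and the total imbalance
#' as the weighted sum of contributions.
#'
#' @param ss A `scheme_set` from [generate_schemes()].
#' @param table The [unit_table()] the schemes were generated for.
#' @param weights Optional named per-variable weights; defaults to the
#'   weights in the variable specs.
#' @return The `scheme_set` with `contributions` (schemes x variables),
#'   `totals` and `weights_used` filled in.
#' @export
score_schemes <- function(ss, table, weights = NULL) {
  stopifnot(inherits(ss, "scheme_set"), inherits(table, "unit_table"))
  vnames <- names(table$variables)
  if (is.null(weights))
    weights <- vapply(table$variables, `[[`, 0, "weight")
  if (is.null(names(weights))) names(weights) <- vnames
  if (!all(vnames %in% names(weights)))
    ccr_stop("bad_weight", "weights must cover every variable")
  if (any(weights < 0)) ccr_stop("bad_weight", "weights must be nonnegative")
  weights <- weights[vnames]

  # contributions do not depend on the weights, so a rescore with new
  # weights (e.g. after standardisation) reuses them
  if (!isTRUE(ss$scored) || !identical(colnames(ss$contributions), vnames)) {
    contrib <- matrix(0, nrow = nrow(ss$labels), ncol = length(vnames),
                      dimnames = list(NULL, vnames))
    for (v in table$variables)
      contrib[, v$name] <- variable_contributions(
        table$values[[v$name]], v$vtype, v$metric, ss$labels)
    ss$contributions <- contrib
  }
  ss$weights_used <- weights
  ss$totals <- as.numeric(ss$contributions %*% weights)
  ss$scored <- TRUE
  ss
}

#' Standardising weights from a unit-weight run
#'
#' Setting each variable's weight to the inverse of its maximum imbalance
#' contribution (as observed over a scored scheme set) standardises the
#' range of its contributions to \[0, 1\]. A constant (degenerate)
#' variable, whose maximum contribution is 0, gets weight 0 with a
#' warning.
#'
#' @param ss A scored `scheme_set`.
#' @return Named numeric vector of weights, usable with [score_schemes()].
#' @export
standardize_weights <- function(ss) {
  if (!isTRUE(ss$scored)) ccr_stop("unscored", "score the scheme set first")
  mx <- apply(ss$contributions, 2, max)
  w <- ifelse(mx > 0, 1 / mx, 0)
  if (any(mx == 0))
    ccr_warn("degenerate", sprintf(
      "variable(s) with zero maximum imbalance get weight 0: %s",
      paste(names(mx)[mx == 0], collapse = ", ")))
  names(w) <- colnames(ss$contributions)
  w
}

#' Preselect well-balanced schemes
#'
#' Selects the schemes with smallest total imbalance, either a fixed
#' `count`, a `proportion` of the set (count = ceiling(proportion x n)),
#' or all schemes with total at most a `max_imbalance` threshold. Ties at
#' the boundary are broken by generation index (stable, seed-independent).
#'
#' @param ss A scored `scheme_set`.
#' @param criterion `"count"`, `"proportion"` or `"max_imbalance"`.
#' @param value Scheme count, proportion in (0, 1\], or imbalance
#'   threshold (must not be below the minimum total).
#' @return An object of class `"preselection"` carrying the selected
#'   scheme indices and the scheme set.
#' @export
preselect <- function(ss, criterion = c("count", "proportion", "max_imbalance"),
                      value) {
  criterion <- match.arg(criterion)
  if (!isTRUE(ss$scored)) ccr_stop("unscored", "score the scheme set first")
  n <- length(ss$totals)
  ord <- order(ss$totals, ss$scheme_id)
  selected <- switch(criterion,
    count = {
      if (value < 1 || value > n)
        ccr_stop("bad_spec", sprintf("count must be in 1..%d", n))
      ord[seq_len(value)]
    },
    proportion = {
      if (value <= 0 || value > 1)
        ccr_stop("bad_spec", "proportion must lie in (0, 1]")
      ord[seq_len(ceiling(value * n))]
    },
    max_imbalance = {
      sel <- which(ss$totals <= value)
      if (length(sel) == 0L)
        ccr_stop("empty_selection", sprintf(
          "no scheme has total imbalance <= %g (minimum is %g)",
          value, min(ss$totals)))
      sel[order(ss$totals[sel], ss$scheme_id[sel])]
    })
  structure(list(criterion = criterion, value = value,
                 selected = ss$scheme_id[selected], scheme_set = ss),
            class = "preselection")
}

#' @export
print.preselection <- function(x, ...) {
  tot <- x$scheme_set$totals[x$selected]
  cat(sprintf("<preselection> %d of %d schemes (%s = %g), totals [%.4g, %.4g]\n",
              length(x$selected), length(x$scheme_set$totals),
              x$criterion, x$value, min(tot), max(tot)))
  invisible(x)
}

#' Draw the final allocation scheme
#'
#' Uniform random draw among the preselected schemes — the step an
#' independent second party would perform. Requires its own seed,
#' distinct from the generation seed, so the draw is auditable and
#' regenerating schemes never silently changes it.
#'
#' @param p A [preselect()] result.
#' @param seed Integer seed for the draw.
#' @return An object of class `"allocation_scheme"` with the identifying
#'   `scheme_id`, per-unit `labels`, and the scheme's total imbalance.
#' @export
choose_final <- function(p, seed) {
  stopifnot(inherits(p, "preselection"))
  if (missing(seed) || is.null(seed))
    ccr_stop("bad_spec", "choose_final requires an explicit seed")
  if (length(p$selected) == 0L) ccr_stop("empty_selection", "empty preselection")
  set.seed(as.integer(seed))
  id <- p$selected[sample.int(length(p$selected), 1L)]
  row <- match(id, p$scheme_set$scheme_id)
  structure(list(scheme_id = id,
                 labels = p$scheme_set$labels[row, ],
                 total = p$scheme_set$totals[row]),
            class = "allocation_scheme")
}

#' @export
print.allocation_scheme <- function(x, ...) {
  cat(sprintf("<allocation_scheme> #%d, total imbalance %.4g\n",
              x$scheme_id, x$total))
  show <- utils::head(x$labels, 6)
  cat(paste(sprintf("%s=%s", names(show), show), collapse = ", "))
  if (length(x$labels) > 6) cat(", ...")
  cat("\n")
  invisible(x)
}

#' Cumulative distribution of total imbalance
#'
#' One row per distinct total imbalance value, with its multiplicity and
#' the cumulative fraction of schemes at or below it. The number of rows
#' is the "distinct values" statistic of the metric-comparison study; the
#' last cumulative fraction is 1.
#'
#' @param ss A scored `scheme_set`.
#' @return Data frame with columns `total`, `count`, `cum_fraction`.
#' @export
imbalance_ecdf <- function(ss) {
  if (!isTRUE(ss$scored)) ccr_stop("unscored", "score the scheme set first")
  tab <- table(ss$totals)
  total <- as.numeric(names(tab))
  ord <- order(total)
  data.frame(total = total[ord],
             count = as.integer(tab)[ord],
             cum_fraction = cumsum(as.integer(tab)[ord]) / length(ss$totals))
}
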