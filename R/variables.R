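# Variable typing and the metric registry.
#
# Every baseline variable is declared with one of four types; each type has
# a fixed set of admissible imbalance metrics, identified by the exact
# strings used throughout (config files, CLI, column names).

VTYPES <- c("binary", "categorical", "integer", "continuous")

# metric identifiers admissible per variable type
METRICS_BY_VTYPE <- list(
  binary      = c("1-PX2", "Eucl"),
  categorical = c("1-PX2", "Eucl", "Manh", "Max", "X2d", "Canb", "Hell", "SBKL"),
  integer     = c("1-PKS", "Eucl"),
  continuous  = c("1-Pt", "1-PU", "1-PKS", "Mrdq", "AbCDF", "SKL")
)

# sensible defaults: the intrinsically standardised / recommended choice per type
DEFAULT_METRIC <- c(
  binary      = "1-PX2",
  categorical = "1-PX2",
  integer     = "1-PKS",
  continuous  = "AbCDF"
)

#' Declare a baseline variable for imbalance scoring
#'
#' A variable specification ties a column name to a variable type, an
#' imbalance metric admissible for that type, and a nonnegative weight used
#' when summing per-variable contributions into a scheme's total imbalance.
#'
#' @param name Column name in the unit table.
#' @param vtype One of `"binary"`, `"categorical"`, `"integer"`,
#'   `"continuous"`.
#' @param metric Metric identifier; must be admissible for `vtype`. Defaults
#'   to `"1-PX2"` for binary/categorical, `"1-PKS"` for integer and
#'   `"AbCDF"` for continuous variables. See [metric_registry()].
#' @param weight Nonnegative weight (default 1).
#' @return An object of class `"variable_spec"`.
#' @examples
#' variable_spec("sex", "binary")
#' variable_spec("age", "continuous", metric = "Mrdq", weight = 0.5)
#' @export
variable_spec <- function(name, vtype, metric = NULL, weight = 1) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    ccr_stop("bad_spec", "variable name must be a nonempty string")
  vtype <- match.arg(vtype, VTYPES)
  if (is.null(metric)) metric <- DEFAULT_METRIC[[vtype]]
  if (!metric %in% METRICS_BY_VTYPE[[vtype]])
    ccr_stop("bad_metric", sprintf(
      "metric '%s' is not admissible for %s variables (allowed: %s)",
      metric, vtype, paste(METRICS_BY_VTYPE[[vtype]], collapse = ", ")))
  if (!is.numeric(weight) || length(weight) != 1L || is.na(weight) || weight < 0)
    ccr_stop("bad_weight", sprintf("weight for '%s' must be a nonnegative number", name))
  structure(list(name = name, vtype = vtype, metric = metric,
                 weight = as.numeric(weight)),
            class = "variable_spec")
}

#' @export
print.variable_spec <- function(x, ...) {
  cat(sprintf("<variable_spec> %s: %s, metric %s, weight %g\n",
              x$name, x$vtype, x$metric, x$weight))
  invisible(x)
}

#' List admissible imbalance metrics
#'
#' @param vtype Optional variable type; if given, only that type's metrics
#'   are returned.
#' @return A named list of metric identifier vectors (or a single vector).
#' @export
metric_registry <- function(vtype = NULL) {
  if (is.null(vtype)) return(METRICS_BY_VTYPE)
  METRICS_BY_VTYPE[[match.arg(vtype, VTYPES)]]
}

# classed errors so callers/tests can distinguish validation failures
ccr_stop <- function(class, msg, call = sys.call(-1)) {
  stop(structure(class = c(paste0("ccr_", class), "ccr_error", "error", "condition"),
                 list(message = msg, call = call)))
}

ccr_warn <- function(class, msg) {
  warning(structure(class = c(paste0("ccr_", class), "ccr_warning",
                              "warning", "condition"),
                    list(message = msg, call = sys.call(-1))))
}

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)
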