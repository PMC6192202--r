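# Synthetic test rosters mirroring the comparison study's two settings:
# a small trial with one variable of each type, allocated either 7:7
# (14 units) or 5:10 (15 units at ratio one third).

SYNTH_PROFILES <- list(
  "tds1-like" = list(n_units = 14, allocation_ratio = 1 / 2),
  "tds2-like" = list(n_units = 15, allocation_ratio = 1 / 3)
)

#' Generate a synthetic unit table
#'
#' Produces a roster with one variable of each of the four types:
#' * binary: Bernoulli(0.4), coded `"0"`/`"1"`;
#' * categorical: three levels `"a"`, `"b"`, `"c"` with probabilities
#'   (0.5, 0.3, 0.2);
#' * integer: Poisson with mean 3;
#' * continuous: lognormal with log-mean 0 and log-sd 0.5.
#'
#' The discrete columns are redrawn (deterministically under the seed,
#' at most 100 times) if they come out constant, so the table is always
#' usable for imbalance scoring at these small sizes. Default metrics per
#' type follow [variable_spec()]; all weights are 1.
#'
#' @param n_units Number of randomisation units (>= 4); defaults to the
#'   profile's size.
#' @param profile `"tds1-like"` (14 units, ratio 1/2) or `"tds2-like"`
#'   (15 units, ratio 1/3). Controls the default `n_units` and the
#'   `allocation_ratio` attached to the table.
#' @param seed Integer seed; the same seed always yields the same table.
#' @return A [unit_table()] with attribute `"allocation_ratio"`.
#' @examples
#' tab <- synth_dataset(profile = "tds1-like", seed = 7)
#' attr(tab, "allocation_ratio")  # 0.5
#' @export
synth_dataset <- function(n_units = NULL, profile = c("tds1-like", "tds2-like"),
                          seed = 1) {
  profile <- match.arg(profile)
  prof <- SYNTH_PROFILES[[profile]]
  if (is.null(n_units)) n_units <- prof$n_units
  if (n_units < 4) ccr_stop("bad_spec", "need at least 4 units")
  set.seed(as.integer(seed))

  draw_nonconstant <- function(gen) {
    for (i in seq_len(100)) {
      x <- gen()
      if (length(unique(x)) > 1L) return(x)
    }
    ccr_stop("degenerate", "could not draw a non-constant column")
  }
  bin <- draw_nonconstant(function() as.character(stats::rbinom(n_units, 1, 0.4)))
  cat_ <- draw_nonconstant(function()
    sample(c("a", "b", "c"), n_units, replace = TRUE, prob = c(0.5, 0.3, 0.2)))
  int_ <- draw_nonconstant(function() stats::rpois(n_units, 3))
  con <- stats::rlnorm(n_units, meanlog = 0, sdlog = 0.5)

  tab <- unit_table(
    ids = sprintf("unit%02d", seq_len(n_units)),
    values = data.frame(bin = bin, cat = cat_, int = int_, con = con,
                        stringsAsFactors = FALSE),
    variables = list(variable_spec("bin", "binary"),
                     variable_spec("cat", "categorical"),
                     variable_spec("int", "integer"),
                     variable_spec("con", "continuous")))
  attr(tab, "allocation_ratio") <- prof$allocation_ratio
  tab
}
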