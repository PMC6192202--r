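# On-disk representation of scored scheme sets: one CSV row per scheme
# with its id, per-unit labels, per-variable contributions and total.
# A leading comment line records metadata (mode, coverage, weights) so a
# written set can be read back losslessly.

#' Write a scored scheme set to CSV
#'
#' Writes one row per scheme: `scheme_id`, one label column per unit
#' (prefixed `u_`), one contribution column per variable (prefixed
#' `imb_`), and `total`. Numbers are written with 17 significant digits,
#' so [read_scheme_set()] recovers the set exactly.
#'
#' @param ss A scored, nonempty `scheme_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scheme_set <- function(ss, path) {
  stopifnot(inherits(ss, "scheme_set"))
  if (!isTRUE(ss$scored)) ccr_stop("unscored", "score the scheme set first")
  if (nrow(ss$labels) == 0L) ccr_stop("empty_selection", "scheme set is empty")
  meta <- jsonlite::toJSON(list(
    mode = ss$mode, coverage = ss$coverage,
    weights_used = as.list(ss$weights_used)), auto_unbox = TRUE, digits = NA)
  out <- data.frame(scheme_id = ss$scheme_id, check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (u in colnames(ss$labels)) out[[paste0("u_", u)]] <- ss$labels[, u]
  for (v in colnames(ss$contributions))
    out[[paste0("imb_", v)]] <- fmt_num(ss$contributions[, v])
  out$total <- fmt_num(ss$totals)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#ccrand ", meta), con)
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a scheme set written by [write_scheme_set()]
#'
#' @param path CSV path.
#' @return A scored `scheme_set`.
#' @export
read_scheme_set <- function(path) {
  if (!file.exists(path)) ccr_stop("io", sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  meta <- if (startsWith(first, "#ccrand "))
    jsonlite::fromJSON(sub("^#ccrand ", "", first)) else NULL
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        colClasses = "character")
  if (!"scheme_id" %in% names(df) || !"total" %in% names(df))
    ccr_stop("io", "not a scheme-set file (missing scheme_id/total columns)")
  ucols <- grep("^u_", names(df), value = TRUE)
  vcols <- grep("^imb_", names(df), value = TRUE)
  labels <- as.matrix(df[ucols])
  colnames(labels) <- sub("^u_", "", ucols)
  rownames(labels) <- NULL
  contrib <- vapply(df[vcols], as.numeric, numeric(nrow(df)))
  contrib <- matrix(contrib, nrow = nrow(df),
                    dimnames = list(NULL, sub("^imb_", "", vcols)))
  weights <- if (!is.null(meta)) unlist(meta$weights_used) else
    stats::setNames(rep(NA_real_, length(vcols)), sub("^imb_", "", vcols))
  coverage <- if (!is.null(meta)) meta$coverage else
    list(n_generated = NA, n_unique = nrow(df), n_possible = NA, fraction = NA)
  structure(list(labels = labels,
                 scheme_id = as.integer(df$scheme_id),
                 mode = if (!is.null(meta)) meta$mode else "unknown",
                 coverage = coverage,
                 contributions = contrib,
                 totals = as.numeric(df$total),
                 weights_used = weights,
                 scored = TRUE),
            class = "scheme_set")
}

#' Restrict a scheme set to a subset of schemes
#'
#' Used by the CLI to persist a preselection as an ordinary scheme-set
#' file.
#'
#' @param ss A scored `scheme_set`.
#' @param ids Scheme ids to keep (order preserved as given).
#' @return A scored `scheme_set` containing only those schemes.
#' @export
subset_schemes <- function(ss, ids) {
  rows <- match(ids, ss$scheme_id)
  if (anyNA(rows)) ccr_stop("bad_spec", "unknown scheme id(s)")
  ss$labels <- ss$labels[rows, , drop = FALSE]
  ss$contributions <- ss$contributions[rows, , drop = FALSE]
  ss$totals <- ss$totals[rows]
  ss$scheme_id <- ss$scheme_id[rows]
  ss$coverage$n_unique <- length(rows)
  ss$coverage$fraction <- length(rows) / ss$coverage$n_possible
  ss
}
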