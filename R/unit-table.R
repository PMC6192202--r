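# Unit tables: the roster of randomisation units with typed baseline
# variables and optional pre-assigned arm labels.

#' Construct a unit table
#'
#' The unit table is the roster of randomisation units (one row per unit,
#' e.g. one cluster in a cluster randomised trial), with typed baseline
#' variables and an optional pre-assigned arm for units randomised in an
#' earlier block. Values are validated strictly against the declared types;
#' missing values are rejected.
#'
#' @param ids Character vector of unique unit identifiers.
#' @param values Data frame of variable values, one column per declared
#'   variable, rows aligned with `ids`.
#' @param variables List of [variable_spec()] objects, one per column of
#'   `values` (same order).
#' @param fixed Per-unit pre-assigned arm: `"A"`, `"B"` or `""`
#'   (unassigned). Default: all unassigned.
#' @return An object of class `"unit_table"` with elements `ids`, `fixed`,
#'   `variables` (named list of specs) and `values` (data frame; binary and
#'   categorical columns stored as character, integer and continuous as
#'   numeric).
#' @seealso [read_unit_table()] to build one from CSV/XLSX + JSON config.
#' @export
unit_table <- function(ids, values, variables, fixed = NULL) {
  ids <- as.character(ids)
  if (length(ids) == 0L) ccr_stop("missing_id", "unit table has no units")
  if (anyNA(ids) || any(!nzchar(ids)))
    ccr_stop("missing_id", "unit IDs must be nonempty and non-missing")
  if (anyDuplicated(ids))
    ccr_stop("duplicate_id", sprintf(
      "duplicate unit IDs: %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (is.null(fixed)) fixed <- rep("", length(ids))
  fixed <- as.character(fixed)
  fixed[is.na(fixed)] <- ""
  if (length(fixed) != length(ids))
    ccr_stop("bad_allocation", "fixed allocation vector length differs from unit count")
  bad <- setdiff(unique(fixed), c("A", "B", ""))
  if (length(bad))
    ccr_stop("bad_allocation", sprintf(
      "pre-assigned allocations must be 'A', 'B' or empty; found: %s",
      paste(bad, collapse = ", ")))

  if (!is.data.frame(values)) values <- as.data.frame(values)
  if (nrow(values) != length(ids))
    ccr_stop("length_mismatch", "values must have one row per unit")
  if (!is.list(variables) || !all(vapply(variables, inherits, TRUE, "variable_spec")))
    ccr_stop("bad_spec", "variables must be a list of variable_spec objects")
  vnames <- vapply(variables, `[[`, "", "name")
  if (anyDuplicated(vnames))
    ccr_stop("bad_spec", "duplicate variable names in specification")
  if (!setequal(vnames, names(values)) || length(vnames) != ncol(values))
    ccr_stop("undeclared_column", sprintf(
      "variable specs (%s) do not match value columns (%s)",
      paste(vnames, collapse = ", "), paste(names(values), collapse = ", ")))
  values <- values[vnames]
  names(variables) <- vnames

  for (v in variables) {
    col <- values[[v$name]]
    if (anyNA(col) || (is.character(col) && any(!nzchar(trimws(col)))))
      ccr_stop("missing_value", sprintf("variable '%s' contains missing values", v$name))
    values[[v$name]] <- coerce_column(col, v)
  }

  structure(list(ids = ids, fixed = fixed, variables = variables,
                 values = values),
            class = "unit_table")
}

# strict typed coercion: declared vtype decides the storage mode, and any
# value inconsistent with the declaration is an error, never a silent NA
coerce_column <- function(col, spec) {
  name <- spec$name
  switch(spec$vtype,
    binary = {
      col <- as.character(col)
      if (length(unique(col)) > 2L)
        ccr_stop("type_error", sprintf(
          "binary variable '%s' has %d distinct values", name, length(unique(col))))
      col
    },
    categorical = as.character(col),
    integer = {
      num <- suppressWarnings(as.numeric(as.character(col)))
      if (anyNA(num))
        ccr_stop("type_error", sprintf(
          "integer variable '%s' has non-numeric entries", name))
      if (any(num != round(num)))
        ccr_stop("type_error", sprintf(
          "integer variable '%s' has non-whole values", name))
      num
    },
    continuous = {
      num <- suppressWarnings(as.numeric(as.character(col)))
      if (anyNA(num) || any(!is.finite(num)))
        ccr_stop("type_error", sprintf(
          "continuous variable '%s' has non-numeric or non-finite entries", name))
      num
    })
}

#' @export
print.unit_table <- function(x, ...) {
  nfix <- sum(x$fixed != "")
  cat(sprintf("<unit_table> %d units, %d variables%s\n",
              length(x$ids), length(x$variables),
              if (nfix) sprintf(" (%d pre-assigned)", nfix) else ""))
  for (v in x$variables)
    cat(sprintf("  %-12s %-11s metric %-5s weight %g\n",
                v$name, v$vtype, v$metric, v$weight))
  invisible(x)
}

#' @export
summary.unit_table <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Read a unit table from CSV or XLSX
#'
#' Reads a roster file with an `ID` column, an optional `Allocation` column
#' (entries `A`, `B` or empty for units already randomised), and one column
#' per baseline variable. Every non-ID, non-Allocation column must be
#' declared in the configuration, which maps column names to
#' `{vtype, metric, weight}`.
#'
#' @param path CSV (UTF-8, header row) or XLSX file. XLSX import requires
#'   the readxl package.
#' @param config Path to a JSON configuration file, or an equivalent named
#'   list. The variable map may sit at the top level or under a
#'   `"variables"` key; other keys (e.g. `allocation_ratio`, `n_schemes`,
#'   `seed`) are retained as attributes for the CLI.
#' @return A validated [unit_table()], column order preserved. The
#'   remaining configuration entries are attached as attribute `"config"`.
#' @examples
#' tab <- synth_dataset(14, "tds1-like", seed = 1)
#' f <- tempfile(fileext = ".csv"); cfg <- tempfile(fileext = ".json")
#' write_unit_table(tab, f, cfg)
#' tab2 <- read_unit_table(f, cfg)
#' @export
read_unit_table <- function(path, config) {
  if (!file.exists(path)) ccr_stop("io", sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      ccr_stop("io", "XLSX import requires the 'readxl' package")
    as.data.frame(readxl::read_excel(path, col_types = "text"))
  } else {
    utils::read.csv(path, colClasses = "character", check.names = FALSE,
                    fileEncoding = "UTF-8")
  }
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) ccr_stop("io", sprintf("config not found: %s", config))
    jsonlite::read_json(config, simplifyVector = FALSE)
  } else if (is.list(config)) config
  else ccr_stop("bad_spec", "config must be a file path or a list")
  varmap <- if (!is.null(cfg$variables)) cfg$variables else
    cfg[setdiff(names(cfg), c("allocation_ratio", "n_schemes", "seed",
                              "choose_seed", "remove_duplicates", "mode"))]

  cols <- names(raw)
  id_col <- which(tolower(cols) == "id")
  if (length(id_col) != 1L)
    ccr_stop("missing_id", "unit table must contain exactly one 'ID' column")
  alloc_col <- which(tolower(cols) == "allocation")
  var_cols <- setdiff(seq_along(cols), c(id_col, alloc_col))
  undeclared <- setdiff(cols[var_cols], names(varmap))
  if (length(undeclared))
    ccr_stop("undeclared_column", sprintf(
      "column(s) not declared in config: %s", paste(undeclared, collapse = ", ")))

  specs <- lapply(cols[var_cols], function(nm) {
    m <- varmap[[nm]]
    if (is.null(m$vtype)) ccr_stop("bad_spec", sprintf("no vtype for column '%s'", nm))
    variable_spec(nm, m$vtype, metric = m$metric,
                  weight = if (is.null(m$weight)) 1 else m$weight)
  })
  fixed <- if (length(alloc_col)) {
    a <- trimws(raw[[alloc_col]]); a[is.na(a)] <- ""; a
  } else NULL
  tab <- unit_table(ids = raw[[id_col]], values = raw[var_cols],
                    variables = specs, fixed = fixed)
  attr(tab, "config") <- cfg[setdiff(names(cfg), "variables")]
  tab
}

#' Write a unit table (and its configuration) to disk
#'
#' Inverse of [read_unit_table()]: writes the roster as CSV with `ID` and
#' `Allocation` columns and, optionally, the variable map as a JSON config.
#'
#' @param table A [unit_table()].
#' @param path Output CSV path.
#' @param config_path Optional JSON config output path.
#' @param extra Named list merged into the JSON config (e.g.
#'   `allocation_ratio`).
#' @return `path`, invisibly.
#' @export
write_unit_table <- function(table, path, config_path = NULL, extra = list()) {
  stopifnot(inherits(table, "unit_table"))
  out <- data.frame(ID = table$ids, Allocation = table$fixed,
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (v in table$variables)
    out[[v$name]] <- fmt_num(table$values[[v$name]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  if (!is.null(config_path)) {
    varmap <- lapply(table$variables, function(v)
      list(vtype = v$vtype, metric = v$metric, weight = v$weight))
    jsonlite::write_json(c(list(variables = varmap), extra), config_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Export the final allocation scheme
#'
#' Writes one row per unit — unit ID and assigned arm — in the unit order
#' of the table.
#'
#' @param scheme An `allocation_scheme` (from [choose_final()]) or a
#'   character vector of `"A"`/`"B"` labels aligned with the table.
#' @param table The [unit_table()] the scheme was built for.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_final_scheme <- function(scheme, table, path) {
  stopifnot(inherits(table, "unit_table"))
  labels <- if (inherits(scheme, "allocation_scheme")) scheme$labels else
    as.character(scheme)
  if (length(labels) != length(table$ids))
    ccr_stop("length_mismatch", sprintf(
      "scheme has %d labels but table has %d units",
      length(labels), length(table$ids)))
  if (!all(labels %in% c("A", "B")))
    ccr_stop("bad_allocation", "scheme labels must all be 'A' or 'B'")
  disagree <- table$fixed != "" & table$fixed != labels
  if (any(disagree))
    ccr_stop("bad_allocation", sprintf(
      "scheme contradicts pre-assigned allocation for unit(s): %s",
      paste(table$ids[disagree], collapse = ", ")))
  utils::write.csv(data.frame(ID = table$ids, Arm = labels),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# full-precision numeric formatting so CSV round trips are exact
fmt_num <- function(x) {
  if (is.numeric(x)) formatC(x, digits = 17, format = "g") else x
}
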