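#' Construct a dimension table
#'
#' A dimension table holds long-format code records for one aspect of care
#' (e.g. diagnoses, prescriptions, laboratory tests): one row per recorded
#' code occurrence, with a patient identifier, the code as text, and
#' optionally the calendar date of the record. When `event_date` is absent
#' the table is treated as already restricted to the covariate assessment
#' window.
#'
#' @param data A data frame with columns `patient_id`, `code` and optionally
#'   `event_date`.
#' @param dimension_label Short label for the dimension, e.g. `"dx"`, `"rx"`,
#'   `"lab"`. Used as the prefix of feature identifiers.
#' @return A tibble of class `hdps_dim` with columns `patient_id` (character),
#'   `code` (character) and, if present, `event_date` (`Date`).
#' @export
dimension_table <- function(data, dimension_label) {
  stopifnot(is.character(dimension_label), length(dimension_label) == 1L,
            nzchar(dimension_label))
  required <- c("patient_id", "code")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("dimension table is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "hdps_schema_error")
  }
  if (nrow(data) == 0) {
    abort("dimension table has no records", class = "hdps_empty_input")
  }
  out <- tibble::as_tibble(data)
  out$patient_id <- as.character(out$patient_id)
  out$code <- as.character(out$code)
  if (any(!nzchar(out$patient_id)) || any(is.na(out$patient_id))) {
    abort("patient_id must be non-empty", class = "hdps_schema_error")
  }
  if (any(!nzchar(out$code)) || any(is.na(out$code))) {
    abort("code must be non-empty", class = "hdps_schema_error")
  }
  if ("event_date" %in% names(out)) {
    out$event_date <- as.Date(out$event_date)
  }
  new_dimension(out, dimension_label)
}

new_dimension <- function(tbl, dimension_label) {
  tbl <- tibble::as_tibble(tbl)
  attr(tbl, "dimension_label") <- dimension_label
  class(tbl) <- unique(c("hdps_dim", class(tbl)))
  tbl
}

#' Dimension label of a dimension table
#' @param dim A dimension table created by [dimension_table()] or
#'   [load_dimension()].
#' @return The dimension label as a string.
#' @export
dimension_label <- function(dim) {
  lbl <- attr(dim, "dimension_label")
  if (is.null(lbl)) abort("not a dimension table: no dimension label set")
  lbl
}

#' Load a dimension table from a delimited or Parquet file
#'
#' Reads a long-format code table and maps its columns onto the roles the
#' pipeline expects. Codes are always read as text so hierarchical codes such
#' as `"250.00"` survive unchanged; row order is preserved.
#'
#' @param path Path to a CSV/TSV or Parquet file.
#' @param column_map Named character vector or list mapping roles to column
#'   names in the file. Roles `patient_id` and `code` are required;
#'   `event_date` is optional.
#' @param dimension_label Label for the dimension (`"dx"`, `"rx"`, ...).
#' @return A validated dimension table (see [dimension_table()]).
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c("pid,icd9code", "p1,434.91", "p1,250.00", "p2,434.11"), path)
#' dx <- load_dimension(path, c(patient_id = "pid", code = "icd9code"), "dx")
#' @export
load_dimension <- function(path, column_map, dimension_label) {
  raw <- read_table_file(path)
  column_map <- unlist(column_map)
  required <- c("patient_id", "code")
  missing_roles <- setdiff(required, names(column_map))
  if (length(missing_roles) > 0) {
    abort(sprintf("column_map must name columns for role(s): %s",
                  paste(missing_roles, collapse = ", ")),
          class = "hdps_schema_error")
  }
  absent <- setdiff(unname(column_map), names(raw))
  if (length(absent) > 0) {
    roles <- names(column_map)[match(absent, column_map)]
    abort(sprintf("file '%s' is missing column(s) %s mapped to role(s) %s",
                  path, paste(absent, collapse = ", "),
                  paste(roles, collapse = ", ")),
          class = "hdps_schema_error")
  }
  keep <- intersect(c("patient_id", "code", "event_date"), names(column_map))
  out <- raw[, unname(column_map[keep]), drop = FALSE]
  names(out) <- keep
  dimension_table(out, dimension_label)
}

read_table_file <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "hdps_io_error")
  }
  if (grepl("\\.parquet$", path, ignore.case = TRUE)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      abort("reading Parquet requires the 'arrow' package")
    }
    tbl <- tibble::as_tibble(arrow::read_parquet(path))
    for (nm in names(tbl)) {
      if (!inherits(tbl[[nm]], "Date") && !is.numeric(tbl[[nm]])) {
        tbl[[nm]] <- as.character(tbl[[nm]])
      }
    }
    return(tbl)
  }
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
}

#' Specify a covariate assessment window
#'
#' The assessment window determines which code records, relative to each
#' patient's index (cohort entry) date, contribute covariate information.
#' Typical choices are the entire prior history for diagnoses, 90 days for
#' prescriptions, and one year for laboratory measurements.
#'
#' @param dimension_label Label of the dimension the window applies to.
#' @param lookback Either the string `"all_history"` or a positive number of
#'   days.
#' @return An object of class `hdps_window`.
#' @export
window_spec <- function(dimension_label, lookback) {
  if (is.character(lookback)) {
    if (!identical(lookback, "all_history")) {
      abort("lookback must be \"all_history\" or a positive number of days",
            class = "hdps_config_error")
    }
  } else {
    lookback <- as.numeric(lookback)
    if (!is.finite(lookback) || lookback <= 0) {
      abort("numeric lookback must be a positive number of days",
            class = "hdps_config_error")
    }
  }
  structure(list(dimension_label = dimension_label, lookback = lookback),
            class = "hdps_window")
}

#' Restrict a dimension table to the covariate assessment window
#'
#' Keeps records dated within the half-open interval
#' `[index_date - lookback, index_date)`: records on the index date itself are
#' never baseline covariates, records exactly `lookback` days before are.
#' With `lookback = "all_history"` every record strictly before the index
#' date is kept. Records for patients absent from the cohort master are
#' dropped, with the count reported via `message()`.
#'
#' @param dim A dimension table with an `event_date` column.
#' @param master A cohort master table (see [validate_master()]) with
#'   `patient_id` and `index_date`.
#' @param spec A [window_spec()] whose label matches `dim`.
#' @return The filtered dimension table; rows are an unmodified subset of the
#'   input rows.
#' @export
apply_window <- function(dim, master, spec) {
  stopifnot(inherits(spec, "hdps_window"))
  lbl <- dimension_label(dim)
  if (!identical(spec$dimension_label, lbl)) {
    abort(sprintf("window is for dimension '%s' but table is '%s'",
                  spec$dimension_label, lbl),
          class = "hdps_config_error")
  }
  if (!"event_date" %in% names(dim)) {
    abort("apply_window needs an event_date column; table without dates is treated as pre-windowed",
          class = "hdps_schema_error")
  }
  idx <- master$index_date[match(dim$patient_id, master$patient_id)]
  unknown <- is.na(idx)
  if (any(unknown)) {
    inform(sprintf("apply_window [%s]: dropped %d record(s) for %d patient(s) not in the cohort master",
                   lbl, sum(unknown), dplyr::n_distinct(dim$patient_id[unknown])))
  }
  delta <- as.numeric(idx - dim$event_date)  # days before index
  keep <- if (identical(spec$lookback, "all_history")) {
    !unknown & delta > 0
  } else {
    !unknown & delta > 0 & delta <= spec$lookback
  }
  out <- dim[keep, , drop = FALSE]
  new_dimension(out, lbl)
}

#' Validate a cohort master table
#'
#' The master table has one row per patient: a unique identifier, binary
#' exposure and outcome, a non-negative follow-up time, the index date, and
#' any investigator-predefined covariate columns.
#'
#' @param master A data frame with columns `patient_id`, `exposure`,
#'   `outcome`, `time_to_event` and (when windowing is used) `index_date`.
#' @param require_index_date Whether `index_date` must be present.
#' @return The master as a validated tibble.
#' @export
validate_master <- function(master, require_index_date = FALSE) {
  required <- c("patient_id", "exposure", "outcome", "time_to_event")
  missing_cols <- setdiff(required, names(master))
  if (length(missing_cols) > 0) {
    abort(sprintf("cohort master is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "hdps_schema_error")
  }
  out <- tibble::as_tibble(master)
  out$patient_id <- as.character(out$patient_id)
  if (anyDuplicated(out$patient_id)) {
    abort("patient_id must be unique in the cohort master",
          class = "hdps_schema_error")
  }
  for (v in c("exposure", "outcome")) {
    vals <- out[[v]]
    if (!all(vals %in% c(0, 1))) {
      abort(sprintf("%s must be binary 0/1", v), class = "hdps_schema_error")
    }
    if (length(unique(vals)) < 2) {
      abort(sprintf("%s takes a single value in the cohort; prioritisation and PS estimation are undefined", v),
            class = "hdps_schema_error")
    }
    out[[v]] <- as.integer(vals)
  }
  if (any(out$time_to_event < 0, na.rm = TRUE) || anyNA(out$time_to_event)) {
    abort("time_to_event must be non-negative and non-missing",
          class = "hdps_schema_error")
  }
  if (require_index_date) {
    if (!"index_date" %in% names(out)) {
      abort("cohort master needs an index_date column for windowing",
            class = "hdps_schema_error")
    }
    out$index_date <- as.Date(out$index_date)
  } else if ("index_date" %in% names(out)) {
    out$index_date <- as.Date(out$index_date)
  }
  out
}

#' Load a cohort master table from file
#'
#' @inheritParams load_dimension
#' @param column_map Named vector mapping roles (`patient_id`, `exposure`,
#'   `outcome`, `time_to_event`, `index_date`) to file columns. Columns not
#'   mentioned are kept under their own names as predefined covariates.
#' @return A validated master tibble.
#' @export
load_master <- function(path, column_map) {
  raw <- read_table_file(path)
  column_map <- unlist(column_map)
  absent <- setdiff(unname(column_map), names(raw))
  if (length(absent) > 0) {
    abort(sprintf("file '%s' is missing column(s): %s", path,
                  paste(absent, collapse = ", ")),
          class = "hdps_schema_error")
  }
  nm <- names(raw)
  nm[match(unname(column_map), nm)] <- names(column_map)
  names(raw) <- nm
  for (v in intersect(c("exposure", "outcome", "time_to_event"), names(raw))) {
    raw[[v]] <- as.numeric(raw[[v]])
  }
  # remaining character columns that look numeric are predefined covariates
  for (v in setdiff(names(raw), c("patient_id", "index_date"))) {
    if (is.character(raw[[v]]) && !anyNA(suppressWarnings(as.numeric(raw[[v]])))) {
      raw[[v]] <- as.numeric(raw[[v]])
    }
  }
  validate_master(raw, require_index_date = "index_date" %in% names(raw))
}
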