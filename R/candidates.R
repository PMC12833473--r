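#' Code-aggregation (granularity) rules
#'
#' Hierarchical coding systems are usually collapsed to a coarser level
#' before candidate features are counted — e.g. ICD-9 diagnosis codes to
#' their 3-digit root, BNF prescription codes to chapter level. Three rules
#' are available: truncation to the first `n` characters, an explicit
#' code-to-group mapping table, and identity (no aggregation).
#'
#' @param n Number of leading characters to keep.
#' @return A granularity rule object for [aggregate_codes()].
#' @name granularity
NULL

#' @rdname granularity
#' @export
granularity_truncate <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1) abort("truncation length must be >= 1",
                               class = "hdps_config_error")
  structure(list(type = "truncate", n = n), class = "hdps_granularity")
}

#' @rdname granularity
#' @param map Named character vector: names are raw codes, values their
#'   aggregated group.
#' @param passthrough If `TRUE`, codes absent from `map` pass through
#'   unchanged; if `FALSE` they are kept unchanged but collected into an
#'   `unmapped_codes` attribute on the result and reported with a warning.
#' @export
granularity_map <- function(map, passthrough = TRUE) {
  map <- unlist(map)
  if (is.null(names(map)) || any(!nzchar(names(map)))) {
    abort("map must be a named vector (raw code -> group)",
          class = "hdps_config_error")
  }
  structure(list(type = "map", map = map, passthrough = isTRUE(passthrough)),
            class = "hdps_granularity")
}

#' @rdname granularity
#' @export
granularity_identity <- function() {
  structure(list(type = "identity"), class = "hdps_granularity")
}

#' Aggregate raw codes to the configured granularity
#'
#' Replaces each code by its aggregate under the rule. Row count and row
#' order are unchanged; only the `code` column is rewritten.
#'
#' @param dim A dimension table.
#' @param rule A rule from [granularity_truncate()], [granularity_map()] or
#'   [granularity_identity()].
#' @return The dimension table with aggregated codes. Under a mapping rule
#'   without passthrough, unmapped codes are listed in the `unmapped_codes`
#'   attribute.
#' @examples
#' dx <- dimension_table(
#'   data.frame(patient_id = "p1", code = "434.91"), "dx")
#' aggregate_codes(dx, granularity_truncate(3))$code  # "434"
#' @export
aggregate_codes <- function(dim, rule) {
  stopifnot(inherits(rule, "hdps_granularity"))
  lbl <- dimension_label(dim)
  out <- dim
  if (rule$type == "truncate") {
    out$code <- substr(out$code, 1L, rule$n)
  } else if (rule$type == "map") {
    mapped <- unname(rule$map[out$code])
    miss <- is.na(mapped)
    if (any(miss) && !rule$passthrough) {
      unmapped <- sort(unique(out$code[miss]))
      warn(sprintf("aggregate_codes [%s]: %d code(s) had no mapping: %s",
                   lbl, length(unmapped),
                   paste(head(unmapped, 10), collapse = ", ")))
      attr(out, "unmapped_codes") <- unmapped
    }
    out$code <- ifelse(miss, out$code, mapped)
  }
  new_dimension(out, lbl)
}

#' Identify candidate features in one dimension
#'
#' Counts, per aggregated code, the number of distinct cohort patients with
#' at least one in-window record, and ranks candidates by that prevalence.
#' Features seen in fewer than `min_patients` patients are dropped, features
#' matching investigator-supplied exclusion patterns (close proxies of the
#' exposure or outcome) are removed, and the list is truncated to the `n`
#' most prevalent. `n = Inf` with `min_patients = 1` disables filtering
#' entirely. Prevalence ties are broken by feature identifier so the ranking
#' is reproducible.
#'
#' @param dim A windowed, aggregated dimension table.
#' @param master The cohort master table; its row count is the cohort size
#'   used for prevalence.
#' @param n Maximum number of candidates to return (default 200).
#' @param min_patients Minimum distinct patients per feature (default 10).
#' @param exclude Character vector of feature identifiers to remove; entries
#'   ending in `"*"` are treated as prefix patterns.
#' @return A tibble with columns `feature_id` (`<label>_<code>`),
#'   `dimension`, `code`, `n_patients`, `prevalence`, sorted by decreasing
#'   prevalence.
#' @export
identify_candidates <- function(dim, master, n = 200, min_patients = 10,
                                exclude = NULL) {
  lbl <- dimension_label(dim)
  cohort_size <- nrow(master)
  in_cohort <- dim$patient_id %in% master$patient_id
  counts <- dim[in_cohort, c("patient_id", "code")] |>
    dplyr::distinct() |>
    dplyr::count(.data$code, name = "n_patients")
  out <- counts |>
    dplyr::mutate(feature_id = paste(lbl, .data$code, sep = "_"),
                  dimension = lbl,
                  prevalence = .data$n_patients / cohort_size) |>
    dplyr::filter(.data$n_patients >= min_patients)
  if (!is.null(exclude) && length(exclude) > 0 && nrow(out) > 0) {
    drop <- matches_exclusion(out$feature_id, exclude)
    out <- out[!drop, , drop = FALSE]
  }
  out <- out |>
    dplyr::arrange(dplyr::desc(.data$prevalence), .data$feature_id) |>
    head(n = if (is.finite(n)) n else nrow(out))
  if (nrow(out) == 0) {
    warn(sprintf("identify_candidates [%s]: no features survive filtering", lbl))
  }
  out[, c("feature_id", "dimension", "code", "n_patients", "prevalence")]
}

matches_exclusion <- function(ids, patterns) {
  hit <- rep(FALSE, length(ids))
  for (p in patterns) {
    if (endsWith(p, "*")) {
      hit <- hit | startsWith(ids, substr(p, 1L, nchar(p) - 1L))
    } else {
      hit <- hit | ids == p
    }
  }
  hit
}
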