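#' Count in-window code occurrences per patient
#'
#' Tallies, for each candidate feature, how many records each cohort patient
#' has in the (already windowed and aggregated) dimension table. Every
#' cohort patient receives a count for every requested feature, zero when
#' the patient has no record of the code.
#'
#' @param dim A windowed, aggregated dimension table.
#' @param master The cohort master table.
#' @param features Character vector of feature identifiers
#'   (`<label>_<code>`); default all codes present in `dim`.
#' @return A tibble `(patient_id, feature_id, count)` with one row per
#'   cohort patient per feature.
#' @export
count_occurrences <- function(dim, master, features = NULL) {
  lbl <- dimension_label(dim)
  prefix <- paste0(lbl, "_")
  if (is.null(features)) {
    features <- paste0(prefix, sort(unique(dim$code)))
  }
  codes <- sub(paste0("^", prefix), "", features)
  absent <- !codes %in% dim$code
  if (any(absent)) {
    warn(sprintf("count_occurrences [%s]: feature(s) absent from dimension, counts all zero: %s",
                 lbl, paste(features[absent], collapse = ", ")))
  }
  m <- occurrence_matrix(dim, master$patient_id, codes)
  colnames(m) <- features
  tibble::tibble(
    patient_id = rep(master$patient_id, times = length(features)),
    feature_id = rep(features, each = nrow(master)),
    count = as.integer(m)
  )
}

# patients x codes integer count matrix, rows aligned to `patients`
occurrence_matrix <- function(dim, patients, codes) {
  ri <- match(dim$patient_id, patients)
  ci <- match(dim$code, codes)
  keep <- !is.na(ri) & !is.na(ci)
  m <- matrix(0L, nrow = length(patients), ncol = length(codes))
  if (any(keep)) {
    tab <- table(factor(ri[keep], levels = seq_along(patients)),
                 factor(ci[keep], levels = seq_along(codes)))
    m[] <- as.integer(tab)
  }
  dimnames(m) <- list(patients, codes)
  m
}

# nearest-rank quantile over positive counts: value at order statistic
# ceiling(p * m); always an observed integer count
nearest_rank <- function(x, p) {
  x <- sort(x)
  x[max(1L, ceiling(p * length(x)))]
}

#' Expand candidate features into recurrence covariates
#'
#' For each feature, derives up to three binary covariates indicating that
#' the code was recorded at least `k` times in-window, with cutoffs `k`
#' equal to 1 (`_once`), the median (`_sporadic`) and the 75th percentile
#' (`_frequent`) of the occurrence counts among patients with at least one
#' occurrence. Cutoffs use the nearest-rank quantile so they are always
#' attainable integer counts. Covariates whose cutoffs coincide are
#' deduplicated, keeping the first name in the order once, sporadic,
#' frequent; features never observed yield no covariates (with a warning).
#'
#' @param counts A per-patient count table from [count_occurrences()], or
#'   any tibble with columns `patient_id`, `feature_id`, `count` covering
#'   all cohort patients (missing rows count as zero).
#' @param master Optional cohort master used to fix the patient set and
#'   order of the covariate matrix; defaults to the patients in `counts`.
#' @return An object of class `hdps_recurrence`: a list with
#'   \describe{
#'     \item{covariates}{tibble `(covariate_id, feature_id, suffix, cutoff)`}
#'     \item{matrix}{tibble with `patient_id` plus one 0/1 column per
#'       covariate}
#'   }
#' @examples
#' counts <- tibble::tibble(
#'   patient_id = paste0("p", 1:4),
#'   feature_id = "dx_434",
#'   count = c(1L, 3L, 5L, 7L))
#' assess_recurrence(counts)$covariates$cutoff  # 1 3 5
#' @export
assess_recurrence <- function(counts, master = NULL) {
  stopifnot(all(c("patient_id", "feature_id", "count") %in% names(counts)))
  patients <- if (is.null(master)) unique(counts$patient_id) else master$patient_id
  features <- unique(counts$feature_id)

  pos <- counts[counts$count >= 1L, , drop = FALSE]
  if (nrow(pos) == 0) {
    warn("assess_recurrence: all counts are zero; no covariates generated")
    return(empty_recurrence(patients))
  }
  cuts <- pos |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(
      once = 1L,
      sporadic = nearest_rank(.data$count, 0.5),
      frequent = nearest_rank(.data$count, 0.75),
      .groups = "drop")
  meta <- cuts |>
    tidyr::pivot_longer(c("once", "sporadic", "frequent"),
                        names_to = "suffix", values_to = "cutoff") |>
    dplyr::mutate(suffix = factor(.data$suffix,
                                  levels = c("once", "sporadic", "frequent"))) |>
    dplyr::arrange(.data$feature_id, .data$suffix) |>
    dplyr::distinct(.data$feature_id, .data$cutoff, .keep_all = TRUE) |>
    dplyr::mutate(suffix = as.character(.data$suffix),
                  covariate_id = paste0(.data$feature_id, "_", .data$suffix),
                  cutoff = as.integer(.data$cutoff)) |>
    dplyr::select("covariate_id", "feature_id", "suffix", "cutoff")

  dropped <- setdiff(features, meta$feature_id)
  if (length(dropped) > 0) {
    warn(sprintf("assess_recurrence: feature(s) with all-zero counts dropped: %s",
                 paste(dropped, collapse = ", ")))
  }

  feat_levels <- unique(meta$feature_id)
  cm <- matrix(0L, nrow = length(patients), ncol = length(feat_levels))
  ri <- match(pos$patient_id, patients)
  ci <- match(pos$feature_id, feat_levels)
  keep <- !is.na(ri) & !is.na(ci)
  cm[cbind(ri[keep], ci[keep])] <- pos$count[keep]

  ind <- matrix(0L, nrow = length(patients), ncol = nrow(meta),
                dimnames = list(NULL, meta$covariate_id))
  fcol <- match(meta$feature_id, feat_levels)
  for (j in seq_len(nrow(meta))) {
    ind[, j] <- as.integer(cm[, fcol[j]] >= meta$cutoff[j])
  }
  mat <- tibble::as_tibble(as.data.frame(ind, check.names = FALSE))
  mat <- dplyr::bind_cols(tibble::tibble(patient_id = patients), mat)
  structure(list(covariates = meta, matrix = mat), class = "hdps_recurrence")
}

empty_recurrence <- function(patients) {
  structure(list(
    covariates = tibble::tibble(covariate_id = character(),
                                feature_id = character(),
                                suffix = character(),
                                cutoff = integer()),
    matrix = tibble::tibble(patient_id = patients)),
    class = "hdps_recurrence")
}

#' @export
print.hdps_recurrence <- function(x, ...) {
  cat(sprintf("<hdps_recurrence> %d covariates from %d features, %d patients\n",
              nrow(x$covariates), dplyr::n_distinct(x$covariates$feature_id),
              nrow(x$matrix)))
  invisible(x)
}

#' @export
tidy.hdps_recurrence <- function(x, ...) x$covariates

#' Build the full recurrence covariate matrix across dimensions
#'
#' Convenience wrapper running [count_occurrences()] and
#' [assess_recurrence()] for each dimension's candidate features and
#' column-binding the results.
#'
#' @param dimensions Named list of windowed, aggregated dimension tables.
#' @param master Cohort master table.
#' @param candidates Candidate table as returned by [identify_candidates()]
#'   (rows for all dimensions combined).
#' @return An `hdps_recurrence` object covering all dimensions.
#' @export
build_recurrence <- function(dimensions, master, candidates) {
  parts <- purrr::map(names(dimensions), function(lbl) {
    feats <- candidates$feature_id[candidates$dimension == lbl]
    if (length(feats) == 0) return(NULL)
    counts <- count_occurrences(dimensions[[lbl]], master, feats)
    assess_recurrence(counts, master)
  })
  parts <- purrr::compact(parts)
  if (length(parts) == 0) return(empty_recurrence(master$patient_id))
  meta <- purrr::map(parts, "covariates") |> dplyr::bind_rows()
  mats <- purrr::map(parts, ~ .x$matrix[, setdiff(names(.x$matrix), "patient_id"),
                                        drop = FALSE])
  mat <- dplyr::bind_cols(tibble::tibble(patient_id = master$patient_id), mats)
  structure(list(covariates = meta, matrix = mat), class = "hdps_recurrence")
}
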