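#' Run the full high-dimensional propensity score analysis in memory
#'
#' Executes the seven-step procedure on loaded tables: (1) restrict each
#' dimension to its assessment window, (2) aggregate codes and identify
#' candidate features, (3) expand candidates into recurrence covariates,
#' (4) prioritise by Bross bias score with optional zero-cell correction,
#' (5) select the top `n_select`, (6) estimate the propensity score from
#' predefined covariates alone and with the selected proxy covariates
#' added, forming stabilised trimmed IPTW for each, and (7) fit weighted
#' Cox outcome models (plus an unweighted reference fit).
#'
#' @param dimensions Named list of dimension tables.
#' @param master Cohort master table (predefined covariate columns
#'   included).
#' @param windows Named list (by dimension label) of [window_spec()]s or
#'   lookback values; `NULL` treats tables as pre-windowed.
#' @param granularity Named list of granularity rules; missing entries
#'   default to [granularity_identity()].
#' @param n_candidates,min_patients,exclude Candidate filtering, see
#'   [identify_candidates()]. Defaults disable the prevalence filter.
#' @param n_select Number of top-ranked covariates for the PS model.
#' @param correction Apply zero-cell correction in prioritisation.
#' @param remove_iv Drop empirically instrument-like covariates before
#'   selection.
#' @param predefined Names of investigator-predefined covariate columns in
#'   `master`.
#' @param trim Weight-trimming percentile (see [stabilised_weights()]).
#' @return An object of class `hdps_result` with components `candidates`,
#'   `recurrence`, `prioritised`, `selected`, `ps` (fits: `predefined`,
#'   `hdps`), `weights` (same names), `models` (`unadjusted`, `ps`,
#'   `hdps`), `effects` (tidy estimate table), and the analysis `data`
#'   (master joined with the covariate matrix).
#' @export
hdps_analysis <- function(dimensions, master,
                          windows = NULL,
                          granularity = NULL,
                          n_candidates = Inf,
                          min_patients = 1,
                          exclude = NULL,
                          n_select = 250,
                          correction = TRUE,
                          remove_iv = FALSE,
                          predefined = character(),
                          trim = 0.99) {
  master <- validate_master(master, require_index_date = !is.null(windows))
  stopifnot(!is.null(names(dimensions)))

  dims <- purrr::imap(dimensions, function(d, lbl) {
    d <- if (inherits(d, "hdps_dim")) d else dimension_table(d, lbl)
    if (!is.null(windows) && !is.null(windows[[lbl]]) &&
        "event_date" %in% names(d)) {
      w <- windows[[lbl]]
      if (!inherits(w, "hdps_window")) w <- window_spec(lbl, w)
      d <- apply_window(d, master, w)
    }
    rule <- granularity[[lbl]] %||% granularity_identity()
    aggregate_codes(d, rule)
  })

  candidates <- purrr::imap(dims, function(d, lbl)
    identify_candidates(d, master, n = n_candidates,
                        min_patients = min_patients, exclude = exclude)) |>
    dplyr::bind_rows()
  recurrence <- build_recurrence(dims, master, candidates)

  tables <- build_association_tables(recurrence$matrix, master)
  prioritised <- prioritise(tables, correction = correction)
  selected <- select_top(prioritised, n_select, remove_iv = remove_iv)

  data <- dplyr::left_join(master, recurrence$matrix, by = "patient_id")
  ps_pre <- fit_ps(data, predefined = predefined)
  ps_hd <- fit_ps(data, predefined = predefined, hdps = selected)
  w_pre <- stabilised_weights(ps_pre$ps, master$exposure, trim = trim)
  w_hd <- stabilised_weights(ps_hd$ps, master$exposure, trim = trim)

  models <- list(
    unadjusted = fit_weighted_cox(master),
    ps = fit_weighted_cox(master, w_pre$weight),
    hdps = fit_weighted_cox(master, w_hd$weight))

  effects <- purrr::imap(models, function(m, nm)
    dplyr::mutate(tidy(m), model = nm, .before = 1)) |>
    dplyr::bind_rows() |>
    dplyr::mutate(n = nrow(master), n_events = sum(master$outcome))

  structure(list(
    candidates = candidates, recurrence = recurrence,
    prioritised = prioritised, selected = selected,
    ps = list(predefined = ps_pre, hdps = ps_hd),
    weights = list(predefined = w_pre, hdps = w_hd),
    models = models, effects = effects, data = data,
    predefined = predefined, trim = trim, n_select = n_select),
    class = "hdps_result")
}

#' @export
print.hdps_result <- function(x, ...) {
  cat(sprintf("<hdps_result> %d candidates -> %d covariates -> top %d selected\n",
              nrow(x$candidates), nrow(x$prioritised), length(x$selected)))
  print(x$effects[, c("model", "estimate", "conf_low", "conf_high")])
  invisible(x)
}

#' @export
tidy.hdps_result <- function(x, ...) x$effects

#' @export
glance.hdps_result <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$data), n_events = sum(x$data$outcome),
    n_candidates = nrow(x$candidates),
    n_covariates = nrow(x$prioritised),
    n_selected = length(x$selected),
    exposure_prevalence = mean(x$data$exposure),
    weight_cap_hdps = attr(x$weights$hdps, "cap"))
}

#' Sensitivity sweep over the number of selected covariates
#'
#' Re-runs covariate selection, PS estimation, weighting and the weighted
#' Cox model for each value of `n_select`, reusing the prioritisation from
#' an existing analysis — the usual robustness check on the size of the
#' adjustment set.
#'
#' @param result An [hdps_analysis()] result.
#' @param grid Integer vector of `n_select` values.
#' @return A tibble with one row per grid value: `n_select`, `hr`,
#'   `conf_low`, `conf_high`, `log_hr`, `se`.
#' @export
hdps_sweep <- function(result, grid = c(50, 100, 150, 200, 250, 500)) {
  stopifnot(inherits(result, "hdps_result"))
  purrr::map(grid, function(k) {
    sel <- select_top(result$prioritised, k)
    fit <- fit_ps(result$data, predefined = result$predefined, hdps = sel)
    w <- stabilised_weights(fit$ps, result$data$exposure, trim = result$trim)
    m <- fit_weighted_cox(result$data, w$weight)
    tibble::tibble(n_select = k, hr = m$hr, conf_low = m$ci_lower,
                   conf_high = m$ci_upper, log_hr = m$log_hr, se = m$se)
  }) |> dplyr::bind_rows()
}

#' Balance diagnostics for an analysis result
#'
#' Builds the three-scheme balance table (unweighted, predefined-only
#' weights, predefined + HDPS weights) over the predefined covariates and
#' the selected proxy covariates, grouped by prioritisation rank.
#'
#' @param result An [hdps_analysis()] result.
#' @param rank_boundary Rank separating the `hdps_rank_1_<b>` group from
#'   later ranks (default 150).
#' @param threshold Balance threshold (default 0.10).
#' @return An `hdps_balance` table (see [balance_table()]).
#' @export
balance_diagnostics <- function(result, rank_boundary = 150, threshold = 0.10) {
  covs <- c(result$predefined, result$selected)
  ranks <- result$prioritised$rank[match(result$selected,
                                         result$prioritised$covariate_id)]
  groups <- c(
    setNames(rep("predefined", length(result$predefined)), result$predefined),
    setNames(ifelse(ranks <= rank_boundary,
                    sprintf("hdps_rank_1_%d", rank_boundary),
                    sprintf("hdps_rank_%d_plus", rank_boundary + 1)),
             result$selected))
  balance_table(result$data, covs,
                schemes = list(unweighted = NULL,
                               predefined = result$weights$predefined$weight,
                               hdps = result$weights$hdps$weight),
                groups = groups, threshold = threshold)
}
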