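#' Cross-tabulate each covariate against exposure and outcome
#'
#' For each binary covariate C, builds the two 2x2 tables the Bross scoring
#' needs: the covariate-exposure table (patients with C=1 among exposed and
#' unexposed) and the covariate-outcome table (outcomes among C=1 and C=0,
#' cohort-wide).
#'
#' @param covariate_matrix Tibble with `patient_id` plus 0/1 covariate
#'   columns (e.g. `$matrix` of an [assess_recurrence()] result).
#' @param master Cohort master table covering the same patients.
#' @return A tibble with one row per covariate: `covariate_id`, exposure
#'   cells `e1`, `e0` and margins `n1`, `n0`, outcome cells `d1`, `d0` and
#'   margins `m1`, `m0`, and logical flags `corrected_exposure`,
#'   `corrected_outcome` (all `FALSE`; set by [zero_cell_correct()]).
#' @export
build_association_tables <- function(covariate_matrix, master) {
  ids <- covariate_matrix$patient_id
  missing_ids <- setdiff(master$patient_id, ids)
  extra_ids <- setdiff(ids, master$patient_id)
  if (length(missing_ids) > 0 || length(extra_ids) > 0) {
    bad <- head(c(missing_ids, extra_ids), 5)
    abort(sprintf("covariate matrix and master cover different patients (e.g. %s)",
                  paste(bad, collapse = ", ")),
          class = "hdps_alignment_error")
  }
  ord <- match(master$patient_id, ids)
  cols <- setdiff(names(covariate_matrix), "patient_id")
  X <- as.matrix(covariate_matrix[ord, cols, drop = FALSE])
  storage.mode(X) <- "double"
  expo <- master$exposure
  outc <- master$outcome
  n1 <- sum(expo == 1); n0 <- sum(expo == 0); n <- n1 + n0
  e1 <- as.numeric(colSums(X[expo == 1, , drop = FALSE]))
  e0 <- as.numeric(colSums(X[expo == 0, , drop = FALSE]))
  m1 <- as.numeric(colSums(X))
  d1 <- as.numeric(colSums(X[outc == 1, , drop = FALSE]))
  d_total <- sum(outc == 1)
  tibble::tibble(
    covariate_id = cols,
    e1 = e1, e0 = e0, n1 = n1, n0 = n0,
    d1 = d1, d0 = d_total - d1, m1 = m1, m0 = n - m1,
    corrected_exposure = FALSE, corrected_outcome = FALSE
  )
}

#' Zero-cell correction for 2x2 association tables
#'
#' When any of the four cells of a 2x2 table is zero, 0.1 is added to all
#' four cells of that table so the derived risk ratios, and hence the Bross
#' score, stay finite and every covariate remains eligible for selection.
#' The exposure and outcome tables are corrected independently; tables with
#' no zero cell are untouched, making the operation idempotent.
#'
#' Cells are stored as `(e1, e0, n1, n0)` and `(d1, d0, m1, m0)` with the
#' margins, so adding 0.1 to the four cells `(a, b, c, d)` adds 0.1 to each
#' positive cell and 0.2 to each margin.
#'
#' @param tables Association table tibble from [build_association_tables()].
#' @return The tibble with corrected cells and `corrected_*` flags set.
#' @export
zero_cell_correct <- function(tables) {
  t <- tables
  # exposure table cells: a=e1, b=e0, c=n1-e1, d=n0-e0
  zero_e <- !t$corrected_exposure &
    (t$e1 == 0 | t$e0 == 0 | (t$n1 - t$e1) == 0 | (t$n0 - t$e0) == 0)
  t$e1[zero_e] <- t$e1[zero_e] + 0.1
  t$e0[zero_e] <- t$e0[zero_e] + 0.1
  t$n1[zero_e] <- t$n1[zero_e] + 0.2
  t$n0[zero_e] <- t$n0[zero_e] + 0.2
  t$corrected_exposure <- t$corrected_exposure | zero_e
  # outcome table cells: a=d1, b=m1-d1, c=d0, d=m0-d0
  zero_d <- !t$corrected_outcome &
    (t$d1 == 0 | t$d0 == 0 | (t$m1 - t$d1) == 0 | (t$m0 - t$d0) == 0)
  t$d1[zero_d] <- t$d1[zero_d] + 0.1
  t$d0[zero_d] <- t$d0[zero_d] + 0.1
  t$m1[zero_d] <- t$m1[zero_d] + 0.2
  t$m0[zero_d] <- t$m0[zero_d] + 0.2
  t$corrected_outcome <- t$corrected_outcome | zero_d
  t
}

#' Bross bias multiplier for a binary confounder
#'
#' Closed-form multiplicative bias that a binary covariate with prevalence
#' `pc1` among the exposed and `pc0` among the unexposed, and risk ratio
#' `rr_cd` for the outcome, would induce on an exposure-outcome risk ratio:
#' \deqn{B = \frac{p_{c1}(RR_{CD} - 1) + 1}{p_{c0}(RR_{CD} - 1) + 1}.}
#' When `rr_cd < 1` its reciprocal is used (the default), so the score
#' reflects the magnitude of potential confounding and protective covariates
#' are not systematically down-ranked.
#'
#' @param pc1,pc0 Covariate prevalence among the exposed / unexposed, in
#'   `[0, 1]`.
#' @param rr_cd Covariate-outcome risk ratio, > 0.
#' @param invert_protective Replace `rr_cd` by `1/rr_cd` when below 1.
#' @return A tibble with columns `bias_m` and `abs_log_bias`.
#' @examples
#' bross_bias(0.5, 0.1, 2)  # bias_m = 1.5/1.1
#' @export
bross_bias <- function(pc1, pc0, rr_cd, invert_protective = TRUE) {
  if (any(rr_cd <= 0)) {
    abort("rr_cd must be positive", class = "hdps_domain_error")
  }
  if (any(pc1 < 0 | pc1 > 1 | pc0 < 0 | pc0 > 1)) {
    abort("prevalences must lie in [0, 1]", class = "hdps_domain_error")
  }
  rr <- if (invert_protective) ifelse(rr_cd < 1, 1 / rr_cd, rr_cd) else rr_cd
  bias_m <- (pc1 * (rr - 1) + 1) / (pc0 * (rr - 1) + 1)
  tibble::tibble(bias_m = bias_m, abs_log_bias = abs(log(bias_m)))
}

#' Prioritise covariates by potential confounding
#'
#' Derives, for every covariate, its prevalence in each exposure arm, the
#' covariate-exposure and covariate-outcome risk ratios, and the Bross bias
#' multiplier, then ranks covariates by the absolute log bias (largest
#' first). Ties are broken by covariate identifier so ranks are
#' reproducible. Covariates that empirically behave like instruments —
#' strongly exposure-associated but outcome-unassociated — are flagged via
#' [flag_iv_like()].
#'
#' @param tables Association tables, typically zero-cell corrected.
#' @param correction Apply [zero_cell_correct()] first (default `TRUE`).
#' @return A tibble sorted by rank with columns `covariate_id`, `pc1`,
#'   `pc0`, `rr_ce`, `rr_cd`, `bias_m`, `abs_log_bias`, `rank`, `iv_like`.
#' @export
prioritise <- function(tables, correction = TRUE) {
  t <- if (correction) zero_cell_correct(tables) else tables
  pc1 <- t$e1 / t$n1
  pc0 <- t$e0 / t$n0
  rr_ce <- pc1 / pc0
  rr_cd <- (t$d1 / t$m1) / (t$d0 / t$m0)
  b <- bross_bias(pc1, pc0, rr_cd)
  out <- tibble::tibble(
    covariate_id = t$covariate_id,
    pc1 = pc1, pc0 = pc0, rr_ce = rr_ce, rr_cd = rr_cd,
    bias_m = b$bias_m, abs_log_bias = b$abs_log_bias,
    iv_like = flag_iv_like(rr_ce, rr_cd)
  ) |>
    dplyr::arrange(dplyr::desc(.data$abs_log_bias), .data$covariate_id) |>
    dplyr::mutate(rank = dplyr::row_number())
  out[, c("covariate_id", "pc1", "pc0", "rr_ce", "rr_cd",
          "bias_m", "abs_log_bias", "rank", "iv_like")]
}

#' Select the top-ranked covariates
#'
#' @param prioritised Output of [prioritise()].
#' @param n_select Number of covariates to take forward into the propensity
#'   score model (clamped to the number available; 0 gives an empty set).
#' @param remove_iv Drop covariates flagged as empirically instrument-like
#'   before taking the top `n_select`.
#' @return Character vector of covariate identifiers in rank order.
#' @export
select_top <- function(prioritised, n_select, remove_iv = FALSE) {
  stopifnot(n_select >= 0)
  p <- dplyr::arrange(prioritised, .data$rank)
  if (remove_iv) p <- p[!p$iv_like, , drop = FALSE]
  head(p$covariate_id, n = if (is.finite(n_select)) n_select else nrow(p))
}

#' Flag empirically instrument-like covariates
#'
#' A covariate is flagged when it is strongly associated with the exposure
#' but essentially unassociated with the outcome:
#' `|log rr_ce| > 1.5` and `|log rr_cd| < 0.5`, both strict. Adjusting for
#' such covariates risks amplifying bias (Z-bias), so they can be removed
#' in sensitivity analyses.
#'
#' @param rr_ce Covariate-exposure risk ratio(s), positive.
#' @param rr_cd Covariate-outcome risk ratio(s), positive.
#' @return Logical vector.
#' @export
flag_iv_like <- function(rr_ce, rr_cd) {
  abs(log(rr_ce)) > 1.5 & abs(log(rr_cd)) < 0.5
}
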