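#' Absolute standardised difference between exposure arms
#'
#' For a binary covariate with arm prevalences `p1`, `p0`:
#' `|p1 - p0| / sqrt((p1 (1 - p1) + p0 (1 - p0)) / 2)`; for a continuous
#' covariate, the arm means and variances replace the prevalence terms.
#' Optional weights give the weighted version used to assess balance after
#' IPTW. Identical arms give 0; unequal means with zero pooled variance
#' give `Inf` (degenerate). A value below 0.10 is conventionally read as
#' well-balanced.
#'
#' @param x Covariate vector.
#' @param exposure Binary arm indicator.
#' @param weights Optional non-negative weights.
#' @return A single non-negative number (possibly `Inf`).
#' @export
asd <- function(x, exposure, weights = NULL) {
  stopifnot(length(x) == length(exposure))
  w <- if (is.null(weights)) rep(1, length(x)) else weights
  binary <- all(x %in% c(0, 1))
  stat <- function(arm) {
    wi <- w[exposure == arm]; xi <- x[exposure == arm]
    m <- sum(wi * xi) / sum(wi)
    v <- if (binary) m * (1 - m) else sum(wi * (xi - m)^2) / sum(wi)
    c(m = m, v = v)
  }
  s1 <- stat(1); s0 <- stat(0)
  num <- abs(s1["m"] - s0["m"])
  den <- sqrt((s1["v"] + s0["v"]) / 2)
  if (den == 0) {
    return(unname(if (num == 0) 0 else Inf))
  }
  unname(num / den)
}

#' Covariate balance across weighting schemes
#'
#' Computes the absolute standardised difference of every covariate under
#' each weighting scheme — typically unweighted, weighted on predefined
#' covariates only, and weighted with the additional high-dimensional proxy
#' covariates — the comparison the balance (Love) plots visualise.
#'
#' @param data Tibble holding the exposure and all covariate columns.
#' @param covariates Character vector of covariate columns to assess.
#' @param schemes Named list of weight vectors (use `NULL` for unweighted).
#' @param exposure Name of the exposure column.
#' @param groups Optional named character vector assigning each covariate a
#'   display group (e.g. `"predefined"`, `"hdps_rank_1_150"`).
#' @param threshold Balance threshold used in the summary (default 0.10).
#' @return An object of class `hdps_balance`: a tibble
#'   `(covariate_id, scheme, asd, group)` with a `summary` attribute
#'   counting covariates at or above `threshold` per scheme.
#' @export
balance_table <- function(data, covariates, schemes, exposure = "exposure",
                          groups = NULL, threshold = 0.10) {
  stopifnot(length(schemes) > 0, !is.null(names(schemes)))
  expo <- data[[exposure]]
  rows <- purrr::imap(schemes, function(w, nm) {
    tibble::tibble(
      covariate_id = covariates,
      scheme = nm,
      asd = purrr::map_dbl(covariates, ~ asd(data[[.x]], expo, w)))
  }) |> dplyr::bind_rows()
  rows$group <- if (is.null(groups)) "covariate" else
    unname(groups[rows$covariate_id]) %||% "covariate"
  rows$scheme <- factor(rows$scheme, levels = names(schemes))
  summary <- rows |>
    dplyr::group_by(.data$scheme) |>
    dplyr::summarise(n_covariates = dplyr::n(),
                     n_imbalanced = sum(.data$asd >= threshold),
                     max_asd = max(.data$asd), .groups = "drop")
  attr(rows, "summary") <- summary
  attr(rows, "threshold") <- threshold
  class(rows) <- c("hdps_balance", class(rows))
  rows
}

#' @export
glance.hdps_balance <- function(x, ...) attr(x, "summary")

#' Propensity score overlap summary
#'
#' Per-arm decile table of the estimated propensity scores plus the common
#' support range `[max of arm minima, min of arm maxima]`, used to compare
#' PS distributions before and after adding the high-dimensional
#' covariates. No plotting is required to compute it; [autoplot()] renders
#' mirrored histograms.
#'
#' @param ps Propensity scores in (0, 1).
#' @param exposure Binary arm indicator.
#' @param scheme Label recorded with the summary.
#' @return An object of class `hdps_ps_overlap`: list with `deciles`
#'   (tibble arm x quantile), `range` (per-arm min/max) and
#'   `common_support` (length-2 numeric).
#' @export
ps_overlap_summary <- function(ps, exposure, scheme = "ps") {
  stopifnot(all(ps > 0 & ps < 1))
  probs <- seq(0, 1, by = 0.1)
  per_arm <- function(arm) {
    q <- quantile(ps[exposure == arm], probs, type = 7)
    tibble::tibble(scheme = scheme, exposure = arm,
                   quantile = probs, ps = unname(q))
  }
  deciles <- dplyr::bind_rows(per_arm(0), per_arm(1))
  min0 <- min(ps[exposure == 0]); max0 <- max(ps[exposure == 0])
  min1 <- min(ps[exposure == 1]); max1 <- max(ps[exposure == 1])
  rng <- tibble::tibble(exposure = c(0, 1),
                        min = c(min0, min1), max = c(max0, max1))
  structure(list(deciles = deciles, range = rng,
                 common_support = c(max(rng$min), min(rng$max)),
                 scheme = scheme, ps = ps, exposure = as.integer(exposure)),
            class = "hdps_ps_overlap")
}

#' @export
print.hdps_ps_overlap <- function(x, ...) {
  cat(sprintf("<hdps_ps_overlap> '%s': common support [%.3f, %.3f]\n",
              x$scheme, x$common_support[1], x$common_support[2]))
  invisible(x)
}

#' Covariate-association map
#'
#' Exports, for each prioritised covariate, the log covariate-exposure and
#' log covariate-outcome associations, the instrument-like flag, and an
#' outlier flag based on a robust z-score (distance from the median in
#' median-absolute-deviation units) on either axis — the scatter used to
#' spot influential covariates.
#'
#' @param prioritised Output of [prioritise()].
#' @param z_threshold Robust z-score above which a covariate is flagged.
#' @return A tibble `(covariate_id, log_rr_ce, log_rr_cd, iv_like, outlier)`
#'   of class `hdps_association_map`.
#' @export
association_map <- function(prioritised, z_threshold = 3) {
  lce <- log(prioritised$rr_ce)
  lcd <- log(prioritised$rr_cd)
  rz <- function(v) {
    s <- mad(v)
    if (s == 0) return(rep(0, length(v)))
    abs(v - median(v)) / s
  }
  out <- tibble::tibble(
    covariate_id = prioritised$covariate_id,
    log_rr_ce = lce, log_rr_cd = lcd,
    iv_like = prioritised$iv_like,
    outlier = rz(lce) > z_threshold | rz(lcd) > z_threshold)
  class(out) <- c("hdps_association_map", class(out))
  out
}
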