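#' @export
autoplot.hdps_balance <- function(object, ...) {
  threshold <- attr(object, "threshold") %||% 0.10
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$asd,
                                   y = stats::reorder(.data$covariate_id, .data$asd),
                                   colour = .data$scheme)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$group), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = "Absolute standardised difference", y = NULL,
                  colour = "Weighting") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 5))
}

#' @export
autoplot.hdps_ps_overlap <- function(object, bins = 40, ...) {
  df <- tibble::tibble(ps = object$ps,
                       arm = factor(object$exposure, c(0, 1),
                                    c("Comparator", "Exposed")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ps, fill = .data$arm)) +
    ggplot2::geom_histogram(data = ~ dplyr::filter(.x, .data$arm == "Exposed"),
                            ggplot2::aes(y = ggplot2::after_stat(count)),
                            bins = bins, alpha = 0.7) +
    ggplot2::geom_histogram(data = ~ dplyr::filter(.x, .data$arm == "Comparator"),
                            ggplot2::aes(y = -ggplot2::after_stat(count)),
                            bins = bins, alpha = 0.7) +
    ggplot2::labs(x = "Propensity score", y = "Count (mirrored)",
                  fill = NULL, title = object$scheme) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.hdps_association_map <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log_rr_ce, y = .data$log_rr_cd,
                                   colour = .data$iv_like,
                                   shape = .data$outlier)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "log RR (covariate-exposure)",
                  y = "log RR (covariate-outcome)",
                  colour = "IV-like", shape = "Outlier") +
    ggplot2::theme_minimal()
}

#' Distribution of Bross bias scores
#'
#' Histogram of the absolute log Bross bias values of the prioritised
#' covariates, optionally restricted to the top `n` ranks.
#'
#' @param prioritised Output of [prioritise()].
#' @param n Restrict to the top `n` ranked covariates (default all).
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_bias_distribution <- function(prioritised, n = Inf, bins = 30) {
  df <- prioritised[prioritised$rank <= n, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$abs_log_bias)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey40") +
    ggplot2::labs(x = "|log Bross bias|", y = "Covariates") +
    ggplot2::theme_minimal()
}
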