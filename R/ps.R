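#' Estimate the propensity score by logistic regression
#'
#' Fits the probability of exposure given the investigator-predefined
#' covariates plus any selected high-dimensional proxy covariates. Constant
#' columns are dropped with a warning. If the maximum-likelihood fit fails
#' to converge or shows complete/quasi-complete separation (fitted
#' probabilities numerically 0 or 1), the model is refitted with a weak
#' ridge penalty — hundreds of sparse binary covariates make separation
#' likely — and the fallback is reported.
#'
#' @param data Tibble holding the exposure column and all covariate columns
#'   (typically the master joined with a recurrence covariate matrix).
#' @param predefined Character vector of predefined covariate columns.
#' @param hdps Character vector of selected proxy covariate columns.
#' @param exposure Name of the binary exposure column.
#' @param ridge_lambda Penalty used by the ridge fallback.
#' @return An object of class `hdps_ps_fit` with elements `ps` (fitted
#'   probabilities, one per row of `data`), `method` (`"glm"` or
#'   `"ridge"`), `coefficients`, `dropped` (constant columns removed) and
#'   `terms` (covariates used).
#' @export
fit_ps <- function(data, predefined = character(), hdps = character(),
                   exposure = "exposure", ridge_lambda = 1e-3) {
  covs <- unique(c(predefined, hdps))
  absent <- setdiff(covs, names(data))
  if (length(absent) > 0) {
    abort(sprintf("covariate column(s) not in data: %s",
                  paste(absent, collapse = ", ")),
          class = "hdps_schema_error")
  }
  y <- data[[exposure]]
  stopifnot(all(y %in% c(0, 1)))
  X <- as.matrix(data[, covs, drop = FALSE])
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) {
    abort("covariates must be finite and non-missing", class = "hdps_domain_error")
  }
  constant <- apply(X, 2, function(col) length(unique(col)) < 2L)
  if (any(constant)) {
    warn(sprintf("fit_ps: dropping constant covariate(s): %s",
                 paste(covs[constant], collapse = ", ")))
    X <- X[, !constant, drop = FALSE]
    covs_used <- covs[!constant]
  } else {
    covs_used <- covs
  }

  if (length(covs_used) == 0) {
    p_bar <- mean(y)
    return(structure(list(
      ps = rep(p_bar, length(y)), method = "intercept_only",
      coefficients = tibble::tibble(term = "(Intercept)", estimate = qlogis(p_bar)),
      dropped = covs[constant], terms = character(), converged = TRUE),
      class = "hdps_ps_fit"))
  }

  fit <- suppressWarnings(glm.fit(cbind(`(Intercept)` = 1, X), y,
                                  family = binomial()))
  # quasi-separation: fitted probabilities numerically at 0/1 (deviance can
  # converge before coefficients do), a boundary fit, or IRLS failure
  eps <- 1e-10
  separation <- !fit$converged || isTRUE(fit$boundary) ||
    any(fit$fitted.values < eps) || any(fit$fitted.values > 1 - eps) ||
    any(abs(fit$coefficients) > 15)
  method <- "glm"
  if ((separation || !fit$converged) && ncol(X) >= 2) {
    inform(sprintf("fit_ps: separation or non-convergence; refitting with ridge penalty (lambda = %g)",
                   ridge_lambda))
    gfit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                           lambda = ridge_lambda, standardize = FALSE)
    ps <- as.numeric(predict(gfit, newx = X, type = "response"))
    coefs <- tibble::tibble(
      term = c("(Intercept)", covs_used),
      estimate = as.numeric(coef(gfit)))
    method <- "ridge"
  } else {
    if (!fit$converged) {
      abort(sprintf("propensity model failed to converge; covariates: %s",
                    paste(covs_used, collapse = ", ")),
            class = "hdps_fit_error")
    }
    ps <- fit$fitted.values
    coefs <- tibble::tibble(term = c("(Intercept)", covs_used),
                            estimate = unname(fit$coefficients))
  }
  structure(list(ps = ps, method = method, coefficients = coefs,
                 dropped = covs[constant], terms = covs_used,
                 converged = TRUE),
            class = "hdps_ps_fit")
}

#' @importFrom stats glm.fit
NULL

#' @export
print.hdps_ps_fit <- function(x, ...) {
  cat(sprintf("<hdps_ps_fit> %d covariates (%s), ps in [%.3f, %.3f]\n",
              length(x$terms), x$method, min(x$ps), max(x$ps)))
  invisible(x)
}

#' @export
tidy.hdps_ps_fit <- function(x, ...) x$coefficients

#' @export
glance.hdps_ps_fit <- function(x, ...) {
  tibble::tibble(n = length(x$ps), n_covariates = length(x$terms),
                 method = x$method, n_dropped = length(x$dropped))
}

#' Stabilised, trimmed inverse probability of treatment weights
#'
#' Exposed patients receive `p_bar / ps`, unexposed `(1 - p_bar) / (1 - ps)`,
#' with `p_bar` the marginal exposure prevalence; stabilisation keeps the
#' mean weight near 1 in each arm. Weights are then trimmed at the 99th
#' percentile (by default) of the pooled weight distribution: values above
#' the cap are set to the cap, which reduces the variance contributed by
#' extreme weights without excluding patients. Propensity scores at 0 or 1
#' are clipped to `[1e-6, 1 - 1e-6]` with a warning.
#'
#' @param ps Vector of propensity scores.
#' @param exposure Binary exposure vector, same length.
#' @param trim Percentile (in (0, 1]) at which weights are capped; `1`
#'   disables trimming.
#' @return An object of class `hdps_weights`: a tibble with columns `ps`,
#'   `exposure`, `weight_raw`, `weight`, carrying attributes `cap` and
#'   `prevalence`.
#' @examples
#' stabilised_weights(c(0.8, 0.8), c(1, 0), trim = 1)$weight  # 0.5, 3 for p_bar = 0.5
#' @export
stabilised_weights <- function(ps, exposure, trim = 0.99) {
  stopifnot(length(ps) == length(exposure), all(exposure %in% c(0, 1)))
  eps <- 1e-6
  if (any(ps <= 0 | ps >= 1)) {
    warn("stabilised_weights: propensity scores at 0 or 1 clipped to [1e-6, 1 - 1e-6]")
    ps <- pmin(pmax(ps, eps), 1 - eps)
  }
  p_bar <- mean(exposure)
  w <- ifelse(exposure == 1, p_bar / ps, (1 - p_bar) / (1 - ps))
  cap <- if (trim < 1) unname(quantile(w, trim, type = 7)) else Inf
  out <- tibble::tibble(ps = ps, exposure = as.integer(exposure),
                        weight_raw = w, weight = pmin(w, cap))
  attr(out, "cap") <- cap
  attr(out, "prevalence") <- p_bar
  attr(out, "trim") <- trim
  class(out) <- c("hdps_weights", class(out))
  out
}

#' Weighted Cox proportional hazards outcome model
#'
#' Fits the outcome on exposure alone by weighted partial likelihood, with a
#' robust (sandwich) variance estimator: IPTW induces within-subject
#' dependence the model-based variance ignores. The 95% confidence interval
#' is `exp(log HR +/- 1.96 * robust SE)`.
#'
#' @param master Cohort master with `exposure`, `outcome`, `time_to_event`.
#' @param weights Per-patient weights (e.g. the `weight` column of
#'   [stabilised_weights()]); `NULL` for an unweighted fit.
#' @return An object of class `hdps_cox` with elements `log_hr`, `hr`,
#'   `se` (robust), `ci_lower`, `ci_upper`, `n`, `n_events` and the
#'   underlying `survival::coxph` fit.
#' @export
fit_weighted_cox <- function(master, weights = NULL) {
  if (any(master$time_to_event <= 0)) {
    abort("time_to_event must be positive for the Cox model",
          class = "hdps_domain_error")
  }
  for (arm in c(0, 1)) {
    if (sum(master$outcome[master$exposure == arm]) == 0) {
      abort(sprintf("no events in the %s arm; hazard ratio is not estimable",
                    if (arm == 1) "exposed" else "unexposed"),
            class = "hdps_fit_error")
    }
  }
  df <- data.frame(time = master$time_to_event, status = master$outcome,
                   exposure = master$exposure,
                   .w = if (is.null(weights)) rep(1, nrow(master)) else weights)
  fit <- survival::coxph(survival::Surv(time, status) ~ exposure, data = df,
                         weights = .w, robust = TRUE)
  log_hr <- unname(coef(fit)[1])
  se <- sqrt(fit$var[1, 1])
  structure(list(
    log_hr = log_hr, hr = exp(log_hr), se = se,
    ci_lower = exp(log_hr - 1.96 * se), ci_upper = exp(log_hr + 1.96 * se),
    n = nrow(df), n_events = sum(df$status), fit = fit),
    class = "hdps_cox")
}

#' @export
print.hdps_cox <- function(x, ...) {
  cat(sprintf("<hdps_cox> HR %.3f (95%% CI %.3f-%.3f), n = %d, events = %d\n",
              x$hr, x$ci_lower, x$ci_upper, x$n, x$n_events))
  invisible(x)
}

#' @export
tidy.hdps_cox <- function(x, ...) {
  tibble::tibble(term = "exposure", estimate = x$hr, log_estimate = x$log_hr,
                 std_error = x$se, conf_low = x$ci_lower, conf_high = x$ci_upper)
}

#' @export
glance.hdps_cox <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, hr = x$hr,
                 conf_low = x$ci_lower, conf_high = x$ci_upper)
}
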