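#' Define a synthetic claims-like cohort scenario
#'
#' Describes a data-generating process that mimics the structure of a
#' longitudinal healthcare database: three code dimensions (hierarchical
#' diagnosis roots with record-level sub-digits, prescription chapter
#' codes, laboratory test codes), a latent binary confounder `U` that
#' drives both treatment choice and the outcome hazard and is *observed
#' only through* a set of proxy codes whose Poisson recording rates differ
#' by `U`, plus two measured covariates (age, sex) with modest effects.
#'
#' Exposure follows `logit P(T=1) = alpha0 + alpha1 U + a_age z_age +
#' a_female female` (with `z_age` standardised age); survival time is
#' exponential with hazard `lambda0 exp(log(true_hr) T + beta_u U +
#' b_age z_age)`, administratively censored at `censor_time` years. With
#' their defaults, age and sex are measured confounders a predefined-only
#' propensity model can remove; setting them and `alpha1`/`beta_u` to zero
#' gives the fully unconfounded limit. Record dates are
#' drawn uniformly within each dimension's assessment window so the
#' windowing logic sees realistic date variation.
#'
#' @param n_patients Cohort size.
#' @param p_u Prevalence of the latent confounder.
#' @param alpha0,alpha1 Intercept and confounder coefficient of the
#'   exposure model (log-odds scale).
#' @param true_hr True conditional hazard ratio of exposure.
#' @param beta_u Log hazard ratio of the latent confounder.
#' @param baseline_hazard Baseline event rate per year.
#' @param censor_time Administrative censoring time in years.
#' @param n_dx_codes,n_rx_codes,n_lab_codes Codes per dimension.
#' @param n_proxy_codes Number of codes (split across dimensions in
#'   proportion to their size) whose rates depend on `U`.
#' @param proxy_base_rate Poisson rate of a proxy code when `U = 0`.
#' @param proxy_rate_ratio Multiplier of that rate when `U = 1`.
#' @param noise_rate_range Range of (U-independent) rates for the
#'   remaining codes.
#' @param a_age,a_female Exposure-model coefficients of standardised age
#'   and female sex.
#' @param b_age Log hazard ratio per standard deviation of age.
#' @param history_days Length of the diagnosis history horizon in days
#'   (dates for the "all history" window are drawn within it).
#' @param rx_window,lab_window Assessment windows (days) for the
#'   prescription and laboratory dimensions.
#' @param seed Default seed used by [simulate_hdps()].
#' @return An object of class `hdps_scenario`.
#' @export
hdps_scenario <- function(n_patients = 20000,
                          p_u = 0.3,
                          alpha0 = -0.7,
                          alpha1 = 1.0,
                          true_hr = 1.0,
                          beta_u = 0.7,
                          baseline_hazard = 0.02,
                          censor_time = 10,
                          n_dx_codes = 40,
                          n_rx_codes = 20,
                          n_lab_codes = 15,
                          n_proxy_codes = 30,
                          proxy_base_rate = 0.3,
                          proxy_rate_ratio = 4,
                          noise_rate_range = c(0.05, 0.6),
                          a_age = 0.3,
                          a_female = -0.2,
                          b_age = 0.3,
                          history_days = 3650,
                          rx_window = 90,
                          lab_window = 365,
                          seed = 1L) {
  stopifnot(p_u > 0, p_u < 1, baseline_hazard > 0, censor_time > 0,
            proxy_base_rate > 0, proxy_rate_ratio > 0,
            all(noise_rate_range > 0),
            n_proxy_codes <= n_dx_codes + n_rx_codes + n_lab_codes)
  structure(list(
    n_patients = n_patients, p_u = p_u, alpha0 = alpha0, alpha1 = alpha1,
    true_hr = true_hr, beta_u = beta_u, baseline_hazard = baseline_hazard,
    censor_time = censor_time, n_dx_codes = n_dx_codes,
    n_rx_codes = n_rx_codes, n_lab_codes = n_lab_codes,
    n_proxy_codes = n_proxy_codes, proxy_base_rate = proxy_base_rate,
    proxy_rate_ratio = proxy_rate_ratio, noise_rate_range = noise_rate_range,
    a_age = a_age, a_female = a_female, b_age = b_age,
    history_days = history_days, rx_window = rx_window,
    lab_window = lab_window, seed = as.integer(seed)),
    class = "hdps_scenario")
}

#' Assessment windows implied by a scenario
#' @param scenario An [hdps_scenario()].
#' @return Named list of [window_spec()] objects for `dx`, `rx`, `lab`.
#' @export
scenario_windows <- function(scenario) {
  list(dx = window_spec("dx", "all_history"),
       rx = window_spec("rx", scenario$rx_window),
       lab = window_spec("lab", scenario$lab_window))
}

# deterministic code books; proxies are the leading codes of each dimension
scenario_codebook <- function(s) {
  dx_roots <- sprintf("%03d", seq(101, by = 7,
                                  length.out = s$n_dx_codes) %% 900 + 100)
  dx_roots <- make.unique(dx_roots, sep = "x")
  rx_codes <- sprintf("%02d.%d", rep(1:15, length.out = s$n_rx_codes),
                      seq_len(s$n_rx_codes) %% 9 + 1)
  rx_codes <- make.unique(rx_codes, sep = "x")
  lab_codes <- sprintf("L%03d", seq_len(s$n_lab_codes) * 3 + 100)
  sizes <- c(dx = s$n_dx_codes, rx = s$n_rx_codes, lab = s$n_lab_codes)
  n_proxy <- pmin(round(s$n_proxy_codes * sizes / sum(sizes)), sizes)
  # distribute rounding remainder deterministically
  while (sum(n_proxy) < s$n_proxy_codes) {
    i <- which.max(sizes - n_proxy); n_proxy[i] <- n_proxy[i] + 1
  }
  while (sum(n_proxy) > s$n_proxy_codes) {
    i <- which.max(n_proxy); n_proxy[i] <- n_proxy[i] - 1
  }
  tibble::tibble(
    dimension = rep(names(sizes), times = sizes),
    code = c(dx_roots, rx_codes, lab_codes),
    proxy = unlist(lapply(names(sizes), function(d)
      seq_len(sizes[[d]]) <= n_proxy[[d]]), use.names = FALSE))
}

#' Simulate a cohort with dimension tables and known ground truth
#'
#' Draws the latent confounder, measured covariates, exposure, survival
#' outcome, and per-code Poisson occurrence counts, then expands counts
#' into long-format dimension tables with record dates uniform within each
#' dimension's assessment window. Fully reproducible given the seed.
#'
#' @param scenario An [hdps_scenario()].
#' @param seed Overrides the scenario's seed.
#' @return An object of class `hdps_sim`: list with `dimensions` (named
#'   list of dimension tables `dx`, `rx`, `lab`), `master` (cohort master
#'   with predefined covariates `age`, `female`), `latent` (tibble with the
#'   latent confounder and uncensored event times, for validation only),
#'   `codebook`, and the `scenario`.
#' @export
simulate_hdps <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "hdps_scenario"))
  s <- scenario
  set.seed(seed %||% s$seed)
  n <- s$n_patients
  patient_id <- sprintf("p%06d", seq_len(n))

  u <- rbinom(n, 1, s$p_u)
  age <- rnorm(n, 62, 12)
  z_age <- (age - 62) / 12
  female <- rbinom(n, 1, 0.5)

  p_expo <- plogis(s$alpha0 + s$alpha1 * u + s$a_age * z_age +
                     s$a_female * female)
  exposure <- rbinom(n, 1, p_expo)
  prev <- mean(exposure)
  if (prev <= 0.05 || prev >= 0.95) {
    abort(sprintf("degenerate scenario: exposure prevalence %.3f outside (0.05, 0.95)",
                  prev), class = "hdps_scenario_error")
  }

  hazard <- s$baseline_hazard *
    exp(log(s$true_hr) * exposure + s$beta_u * u + s$b_age * z_age)
  event_time <- rexp(n, hazard)
  outcome <- as.integer(event_time <= s$censor_time)
  time_to_event <- pmin(event_time, s$censor_time)
  if (sum(outcome) == 0) {
    abort("degenerate scenario: no events before censoring",
          class = "hdps_scenario_error")
  }

  index_date <- as.Date("2018-01-01") + sample.int(365, n, replace = TRUE) - 1L

  cb <- scenario_codebook(s)
  base <- ifelse(cb$proxy, s$proxy_base_rate,
                 runif(nrow(cb), s$noise_rate_range[1], s$noise_rate_range[2]))
  ratio <- ifelse(cb$proxy, s$proxy_rate_ratio, 1)
  # n x K rate matrix: proxy-code rates scale by ratio^U, counts ~ Poisson
  mult <- matrix(rep(ratio, each = n), nrow = n)^u
  rates <- matrix(base, nrow = n, ncol = nrow(cb), byrow = TRUE) * mult
  counts <- matrix(rpois(n * nrow(cb), rates), nrow = n)

  windows <- c(dx = s$history_days, rx = s$rx_window, lab = s$lab_window)
  dims <- lapply(c("dx", "rx", "lab"), function(d) {
    jj <- which(cb$dimension == d)
    sub <- counts[, jj, drop = FALSE]
    nz <- which(sub > 0, arr.ind = TRUE)
    if (nrow(nz) == 0) {
      abort(sprintf("degenerate scenario: no records in dimension %s", d),
            class = "hdps_scenario_error")
    }
    k <- sub[nz]
    pid <- rep(patient_id[nz[, 1]], k)
    code <- rep(cb$code[jj][nz[, 2]], k)
    m <- length(pid)
    if (d == "dx") code <- paste0(code, ".", sample(0:9, m, replace = TRUE))
    days_back <- sample.int(windows[[d]], m, replace = TRUE)
    tbl <- tibble::tibble(
      patient_id = pid, code = code,
      event_date = rep(index_date[nz[, 1]], k) - days_back)
    dimension_table(tbl[order(tbl$patient_id, tbl$event_date), ], d)
  })
  names(dims) <- c("dx", "rx", "lab")

  master <- tibble::tibble(
    patient_id = patient_id, exposure = exposure, outcome = outcome,
    time_to_event = time_to_event, index_date = index_date,
    age = age, female = female)

  structure(list(
    dimensions = dims,
    master = validate_master(master, require_index_date = TRUE),
    latent = tibble::tibble(patient_id = patient_id, u = u,
                            event_time = event_time, p_exposure = p_expo),
    codebook = cb, scenario = s),
    class = "hdps_sim")
}

#' @export
print.hdps_sim <- function(x, ...) {
  cat(sprintf("<hdps_sim> %d patients, %d/%d/%d dx/rx/lab records, %.1f%% exposed, %.1f%% events\n",
              nrow(x$master), nrow(x$dimensions$dx), nrow(x$dimensions$rx),
              nrow(x$dimensions$lab), 100 * mean(x$master$exposure),
              100 * mean(x$master$outcome)))
  invisible(x)
}

#' Packaged example cohorts
#'
#' Three fixed-seed synthetic cohorts: `tiny` (40 patients, hand-checkable
#' 2x2 tables), `small` (2000 patients), `medium` (20 000 patients, the
#' size used in the package's end-to-end validation). Ground truth (latent
#' confounder, uncensored event times, scenario parameters) travels with
#' the object.
#'
#' @param size One of `"tiny"`, `"small"`, `"medium"`.
#' @return An `hdps_sim` object (see [simulate_hdps()]).
#' @export
make_fixture <- function(size = c("tiny", "small", "medium")) {
  size <- match.arg(size)
  scenario <- switch(size,
    tiny = hdps_scenario(n_patients = 40, n_dx_codes = 6, n_rx_codes = 4,
                         n_lab_codes = 3, n_proxy_codes = 5,
                         baseline_hazard = 0.05, seed = 101L),
    small = hdps_scenario(n_patients = 2000, seed = 102L),
    medium = hdps_scenario(n_patients = 20000, seed = 103L))
  simulate_hdps(scenario)
}

#' Write a simulated cohort to disk
#'
#' Writes `dx.csv`, `rx.csv`, `lab.csv`, `master.csv` and a `truth.json`
#' with the scenario parameters to a directory, the on-disk layout the
#' pipeline configuration consumes.
#'
#' @param sim An `hdps_sim` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (lbl in names(sim$dimensions)) {
    readr::write_csv(tibble::as_tibble(sim$dimensions[[lbl]]),
                     file.path(dir, paste0(lbl, ".csv")))
  }
  readr::write_csv(sim$master, file.path(dir, "master.csv"))
  jsonlite::write_json(sim$scenario[setdiff(names(sim$scenario), NULL)],
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
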