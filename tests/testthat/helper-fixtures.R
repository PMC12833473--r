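# Shared fixture builders and independent oracles used across test files.

# small hand-constructed cohort master
toy_master <- function(n = 6) {
  tibble::tibble(
    patient_id = paste0("p", seq_len(n)),
    exposure = rep(c(1L, 0L), length.out = n),
    outcome = rep(c(1L, 0L, 0L), length.out = n),
    time_to_event = seq_len(n) / 2,
    index_date = as.Date("2020-06-01"))
}

# random tiny cohort: master + one pre-windowed dimension with known rows
random_tiny_cohort <- function(seed, n_patients = 30, n_codes = 5,
                               max_count = 6) {
  set.seed(seed)
  pid <- paste0("p", seq_len(n_patients))
  codes <- paste0("c", seq_len(n_codes))
  counts <- matrix(rpois(n_patients * n_codes, runif(n_codes, 0.3, 2)),
                   nrow = n_patients)
  counts <- pmin(counts, max_count)
  rows <- which(counts > 0, arr.ind = TRUE)
  dim_tbl <- tibble::tibble(
    patient_id = rep(pid[rows[, 1]], counts[rows]),
    code = rep(codes[rows[, 2]], counts[rows]))
  master <- tibble::tibble(
    patient_id = pid,
    exposure = rep(c(1L, 0L), length.out = n_patients),
    outcome = sample(c(0L, 1L), n_patients, replace = TRUE, prob = c(0.7, 0.3)),
    time_to_event = runif(n_patients, 0.1, 5))
  # guarantee both exposure/outcome levels present
  master$outcome[1:2] <- c(0L, 1L)
  list(master = master,
       dim = dimension_table(dim_tbl[sample(nrow(dim_tbl)), ], "dx"),
       counts = counts, pid = pid, codes = codes)
}

# independent nearest-rank quantile: value at order statistic ceiling(p*m)
oracle_nearest_rank <- function(x, p) {
  xs <- sort(x)
  xs[max(1, ceiling(p * length(xs)))]
}

# independent Bross evaluation, written out term by term
oracle_bross <- function(pc1, pc0, rr_cd) {
  rr <- rr_cd
  if (rr < 1) rr <- 1 / rr
  num <- pc1 * (rr - 1) + 1
  den <- pc0 * (rr - 1) + 1
  num / den
}

# brute-force per-patient occurrence tally
oracle_counts <- function(dim_tbl, pid, codes) {
  m <- matrix(0L, length(pid), length(codes), dimnames = list(pid, codes))
  for (i in seq_len(nrow(dim_tbl))) {
    m[dim_tbl$patient_id[i], dim_tbl$code[i]] <-
      m[dim_tbl$patient_id[i], dim_tbl$code[i]] + 1L
  }
  m
}

# default study-condition scenario and the analysis settings used with it
confounded_run <- function(seed, true_hr = 1, n_patients = 20000,
                           n_select = 50) {
  sim <- simulate_hdps(hdps_scenario(true_hr = true_hr,
                                     n_patients = n_patients), seed = seed)
  res <- suppressMessages(suppressWarnings(hdps_analysis(
    sim$dimensions, sim$master,
    windows = scenario_windows(sim$scenario),
    granularity = list(dx = granularity_truncate(3)),
    n_select = n_select, predefined = c("age", "female"))))
  list(sim = sim, res = res)
}
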