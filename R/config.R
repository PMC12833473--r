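#' Read a pipeline configuration
#'
#' A YAML (or JSON) file declaring, for each dimension, the input file,
#' column roles, assessment window and granularity rule, plus the master
#' file and the analysis settings (candidate filter, zero-cell correction,
#' number of covariates selected, instrument-like covariate removal,
#' predefined covariates, weight trimming, time unit, seed, output
#' directory).
#'
#' @param path Path to a YAML or JSON config file.
#' @return A validated config list of class `hdps_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path),
                                class = "hdps_config_error")
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as_pipeline_config(cfg, base_dir = dirname(path))
}

as_pipeline_config <- function(cfg, base_dir = ".") {
  defaults <- list(
    candidates = list(n = Inf, min_patients = 1, exclude = NULL),
    prioritise = list(correction = TRUE),
    select = list(n_select = 250, remove_iv = FALSE),
    weights = list(trim = 0.99),
    predefined = character(), time_unit = "years", seed = 1L)
  for (nm in names(defaults)) {
    cfg[[nm]] <- if (is.list(defaults[[nm]])) {
      modifyList(defaults[[nm]], cfg[[nm]] %||% list())
    } else cfg[[nm]] %||% defaults[[nm]]
  }
  # YAML 1.1 reads an unquoted key `n` as boolean FALSE
  if (!is.null(cfg$candidates[["FALSE"]])) {
    cfg$candidates$n <- cfg$candidates[["FALSE"]]
    cfg$candidates[["FALSE"]] <- NULL
  }
  if (is.null(cfg$out_dir)) abort("config needs an out_dir",
                                  class = "hdps_config_error")
  if (is.null(cfg$master$path)) abort("config needs master: path",
                                      class = "hdps_config_error")
  if (is.null(cfg$dimensions) || length(cfg$dimensions) == 0) {
    abort("config needs at least one dimension", class = "hdps_config_error")
  }
  for (lbl in names(cfg$dimensions)) {
    if (is.null(cfg$dimensions[[lbl]]$window)) {
      abort(sprintf("dimension '%s' has no window", lbl),
            class = "hdps_config_error")
    }
  }
  if (cfg$select$n_select < 0) abort("n_select must be >= 0",
                                     class = "hdps_config_error")
  resolve <- function(p) if (file.exists(p)) p else file.path(base_dir, p)
  cfg$master$path <- resolve(cfg$master$path)
  for (lbl in names(cfg$dimensions)) {
    cfg$dimensions[[lbl]]$path <- resolve(cfg$dimensions[[lbl]]$path)
  }
  structure(cfg, class = "hdps_config")
}

config_granularity <- function(g) {
  if (is.null(g) || identical(g$rule, "identity")) return(granularity_identity())
  # YAML 1.1 reads an unquoted key `n` as boolean FALSE; accept either
  n_chars <- g[["n"]] %||% g[["FALSE"]]
  switch(g$rule,
         truncate = granularity_truncate(n_chars),
         map = granularity_map(unlist(g$map), passthrough = g$passthrough %||% TRUE),
         abort(sprintf("unknown granularity rule '%s'", g$rule),
               class = "hdps_config_error"))
}

config_window <- function(lbl, w) {
  window_spec(lbl, if (identical(w, "all_history")) w else as.numeric(w))
}

pipeline_stages <- c("window", "candidates", "recurrence", "prioritise",
                     "ps", "outcome", "diagnostics")

#' Run the pipeline from a configuration file
#'
#' Loads the dimension and master tables named in the config, executes the
#' analysis stages in order, and writes one artifact per stage to the
#' output directory (windowed dimensions, candidate list, recurrence
#' matrix, prioritisation report, propensity scores and weights, effect
#' estimates, balance and association diagnostics), plus a `manifest.json`
#' recording the config hash, seed, and per-stage row counts. A subset of
#' stages can be re-run; inputs they need are read back from the artifacts
#' of earlier stages.
#'
#' @param config An `hdps_config` (or path to one).
#' @param stages Character vector of stages to run, a contiguous ordered
#'   subset of `r toString(pipeline_stages)`; default all.
#' @return The output directory, invisibly. The full [hdps_analysis()]
#'   result is attached as the `"result"` attribute when the `outcome`
#'   stage ran.
#' @export
run_pipeline <- function(config, stages = pipeline_stages) {
  cfg <- if (inherits(config, "hdps_config")) config else read_pipeline_config(config)
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  manifest <- list(config_hash = rlang::hash(unclass(cfg)), seed = cfg$seed,
                   stages = list())
  log_stage <- function(name, rows) {
    manifest$stages[[name]] <<- list(rows = rows, completed = TRUE)
    inform(sprintf("stage %s: %s", name,
                   paste(sprintf("%s=%d", names(rows), unlist(rows)),
                         collapse = ", ")))
  }

  master <- load_master(cfg$master$path, cfg$master$columns)

  read_dim <- function(lbl) {
    f <- file.path(out, sprintf("windowed_%s.csv", lbl))
    if (!file.exists(f)) abort(sprintf("missing artifact %s; run the 'window' stage first", f))
    d <- readr::read_csv(f, col_types = readr::cols(
      patient_id = readr::col_character(), code = readr::col_character(),
      .default = readr::col_guess()), progress = FALSE)
    new_dimension(d, lbl)
  }

  dims <- NULL
  if ("window" %in% stages) {
    dims <- purrr::imap(cfg$dimensions, function(dc, lbl) {
      d <- load_dimension(dc$path, dc$columns, lbl)
      n_in <- nrow(d)
      if ("event_date" %in% names(d)) {
        d <- apply_window(d, master, config_window(lbl, dc$window))
      }
      # aggregation applied here so downstream artifacts carry analysis codes
      d <- aggregate_codes(d, config_granularity(dc$granularity))
      readr::write_csv(tibble::as_tibble(d),
                       file.path(out, sprintf("windowed_%s.csv", lbl)))
      inform(sprintf("stage window [%s]: records_in=%d, records_out=%d",
                     lbl, n_in, nrow(d)))
      d
    })
    manifest$stages[["window"]] <- list(rows = purrr::map(dims, nrow),
                                        completed = TRUE)
  }

  get_dims <- function() {
    if (is.null(dims)) dims <<- purrr::imap(cfg$dimensions,
                                            function(dc, lbl) read_dim(lbl))
    dims
  }

  candidates <- NULL
  if ("candidates" %in% stages) {
    candidates <- purrr::imap(get_dims(), function(d, lbl)
      identify_candidates(d, master, n = cfg$candidates$n %||% Inf,
                          min_patients = cfg$candidates$min_patients,
                          exclude = cfg$candidates$exclude)) |>
      dplyr::bind_rows()
    readr::write_csv(candidates, file.path(out, "candidates.csv"))
    log_stage("candidates", list(features = nrow(candidates)))
  }
  get_candidates <- function() {
    if (is.null(candidates)) {
      candidates <<- readr::read_csv(file.path(out, "candidates.csv"),
                                     col_types = readr::cols(
                                       code = readr::col_character(),
                                       .default = readr::col_guess()),
                                     progress = FALSE)
    }
    candidates
  }

  recurrence <- NULL
  if ("recurrence" %in% stages) {
    recurrence <- build_recurrence(get_dims(), master, get_candidates())
    readr::write_csv(recurrence$matrix, file.path(out, "recurrence.csv"))
    readr::write_csv(recurrence$covariates,
                     file.path(out, "recurrence_covariates.csv"))
    log_stage("recurrence", list(covariates = nrow(recurrence$covariates)))
  }
  get_recurrence <- function() {
    if (is.null(recurrence)) {
      mat <- readr::read_csv(file.path(out, "recurrence.csv"),
                             col_types = readr::cols(
                               patient_id = readr::col_character(),
                               .default = readr::col_integer()),
                             progress = FALSE)
      meta <- readr::read_csv(file.path(out, "recurrence_covariates.csv"),
                              col_types = "ccci", progress = FALSE)
      recurrence <<- structure(list(covariates = meta, matrix = mat),
                               class = "hdps_recurrence")
    }
    recurrence
  }

  prioritised <- NULL
  if ("prioritise" %in% stages) {
    tables <- build_association_tables(get_recurrence()$matrix, master)
    prioritised <- prioritise(tables, correction = cfg$prioritise$correction)
    readr::write_csv(prioritised, file.path(out, "prioritisation.csv"))
    log_stage("prioritise", list(covariates = nrow(prioritised)))
  }
  get_prioritised <- function() {
    if (is.null(prioritised)) {
      prioritised <<- readr::read_csv(file.path(out, "prioritisation.csv"),
                                      col_types = readr::cols(
                                        covariate_id = readr::col_character(),
                                        iv_like = readr::col_logical(),
                                        .default = readr::col_double()),
                                      progress = FALSE)
    }
    prioritised
  }

  data <- NULL
  get_data <- function() {
    if (is.null(data)) {
      data <<- dplyr::left_join(master, get_recurrence()$matrix,
                                by = "patient_id")
    }
    data
  }

  fits <- NULL
  if ("ps" %in% stages) {
    selected <- select_top(get_prioritised(), cfg$select$n_select,
                           remove_iv = cfg$select$remove_iv)
    ps_pre <- fit_ps(get_data(), predefined = cfg$predefined)
    ps_hd <- fit_ps(get_data(), predefined = cfg$predefined, hdps = selected)
    w_pre <- stabilised_weights(ps_pre$ps, master$exposure,
                                trim = cfg$weights$trim)
    w_hd <- stabilised_weights(ps_hd$ps, master$exposure,
                               trim = cfg$weights$trim)
    weights_tbl <- tibble::tibble(
      patient_id = master$patient_id,
      ps_predefined = ps_pre$ps, ps_hdps = ps_hd$ps,
      weight_predefined = w_pre$weight, weight_hdps = w_hd$weight)
    readr::write_csv(weights_tbl, file.path(out, "weights.csv"))
    fits <- list(selected = selected, ps_pre = ps_pre, ps_hd = ps_hd,
                 w_pre = w_pre, w_hd = w_hd)
    log_stage("ps", list(patients = nrow(weights_tbl),
                         selected = length(selected)))
  }
  get_fits <- function() {
    if (is.null(fits)) {
      w <- readr::read_csv(file.path(out, "weights.csv"),
                           col_types = readr::cols(
                             patient_id = readr::col_character(),
                             .default = readr::col_double()),
                           progress = FALSE)
      w <- w[match(master$patient_id, w$patient_id), ]
      fits <<- list(selected = select_top(get_prioritised(),
                                          cfg$select$n_select,
                                          remove_iv = cfg$select$remove_iv),
                    ps_pre = list(ps = w$ps_predefined),
                    ps_hd = list(ps = w$ps_hdps),
                    w_pre = list(weight = w$weight_predefined),
                    w_hd = list(weight = w$weight_hdps))
    }
    fits
  }

  if ("outcome" %in% stages) {
    f <- get_fits()
    models <- list(unadjusted = fit_weighted_cox(master),
                   ps = fit_weighted_cox(master, f$w_pre$weight),
                   hdps = fit_weighted_cox(master, f$w_hd$weight))
    effects <- purrr::imap(models, function(m, nm)
      dplyr::mutate(tidy(m), model = nm, .before = 1)) |>
      dplyr::bind_rows() |>
      dplyr::mutate(n = nrow(master), n_events = sum(master$outcome))
    readr::write_csv(effects, file.path(out, "effects.csv"))
    log_stage("outcome", list(models = length(models)))
  }

  if ("diagnostics" %in% stages) {
    f <- get_fits()
    covs <- c(cfg$predefined, f$selected)
    bal <- balance_table(get_data(), covs,
                         schemes = list(unweighted = NULL,
                                        predefined = f$w_pre$weight,
                                        hdps = f$w_hd$weight))
    readr::write_csv(tibble::as_tibble(bal), file.path(out, "balance.csv"))
    readr::write_csv(glance(bal), file.path(out, "balance_summary.csv"))
    ov <- dplyr::bind_rows(
      ps_overlap_summary(f$ps_pre$ps, master$exposure, "predefined")$deciles,
      ps_overlap_summary(f$ps_hd$ps, master$exposure, "hdps")$deciles)
    readr::write_csv(ov, file.path(out, "ps_summary.csv"))
    readr::write_csv(tibble::as_tibble(association_map(get_prioritised())),
                     file.path(out, "association_map.csv"))
    log_stage("diagnostics", list(balance_rows = nrow(bal)))
  }

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Run the covariate-count sensitivity sweep from a configuration
#'
#' Requires the `prioritise` stage artifacts; writes `sweep.csv` with one
#' effect-estimate row per grid value.
#'
#' @param config An `hdps_config` or path.
#' @param grid Values of `n_select` to evaluate.
#' @return The sweep tibble, invisibly.
#' @export
run_sweep <- function(config, grid = c(50, 100, 150, 200, 250, 500)) {
  cfg <- if (inherits(config, "hdps_config")) config else read_pipeline_config(config)
  out <- cfg$out_dir
  master <- load_master(cfg$master$path, cfg$master$columns)
  mat <- readr::read_csv(file.path(out, "recurrence.csv"),
                         col_types = readr::cols(
                           patient_id = readr::col_character(),
                           .default = readr::col_integer()),
                         progress = FALSE)
  prioritised <- readr::read_csv(file.path(out, "prioritisation.csv"),
                                 col_types = readr::cols(
                                   covariate_id = readr::col_character(),
                                   iv_like = readr::col_logical(),
                                   .default = readr::col_double()),
                                 progress = FALSE)
  data <- dplyr::left_join(master, mat, by = "patient_id")
  rows <- purrr::map(grid, function(k) {
    sel <- select_top(prioritised, k, remove_iv = cfg$select$remove_iv)
    fit <- fit_ps(data, predefined = cfg$predefined, hdps = sel)
    w <- stabilised_weights(fit$ps, master$exposure, trim = cfg$weights$trim)
    m <- fit_weighted_cox(master, w$weight)
    tibble::tibble(n_select = k, hr = m$hr, conf_low = m$ci_lower,
                   conf_high = m$ci_upper, log_hr = m$log_hr, se = m$se)
  }) |> dplyr::bind_rows()
  readr::write_csv(rows, file.path(out, "sweep.csv"))
  invisible(rows)
}
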