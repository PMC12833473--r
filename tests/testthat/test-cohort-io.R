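test_that("load_dimension maps columns, preserves row order, keeps codes as text", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pid,icd9code", "p1,434.91", "p1,250.00", "p2,003"), path)
  dx <- load_dimension(path, c(patient_id = "pid", code = "icd9code"), "dx")
  expect_s3_class(dx, "hdps_dim")
  expect_equal(nrow(dx), 3)
  expect_identical(dx$code, c("434.91", "250.00", "003"))
  expect_identical(dimension_label(dx), "dx")

  # round-trip: writing and re-reading preserves the code strings exactly
  out <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::as_tibble(dx), out)
  back <- load_dimension(out, c(patient_id = "patient_id", code = "code"), "dx")
  expect_identical(back$code, dx$code)
})

test_that("load_dimension errors name the missing role and reject empty input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,code", "p1,100"), path)
  expect_error(
    load_dimension(path, c(patient_id = "pid", code = "code"), "dx"),
    class = "hdps_schema_error")
  err <- tryCatch(
    load_dimension(path, c(patient_id = "pid", code = "code"), "dx"),
    error = identity)
  expect_match(conditionMessage(err), "patient_id")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("pid,code", empty)
  expect_error(
    load_dimension(empty, c(patient_id = "pid", code = "code"), "dx"),
    class = "hdps_empty_input")
})

test_that("apply_window keeps [index - L, index) and drops index-date records", {
  master <- toy_master(2)
  dx <- dimension_table(tibble::tibble(
    patient_id = "p1",
    code = c("a", "b", "c", "d"),
    event_date = master$index_date[1] - c(0, 1, 90, 91)), "dx")
  out <- apply_window(dx, master, window_spec("dx", 90))
  # on index date: out; 1 day before: in; exactly L days before: in; L+1: out
  expect_identical(out$code, c("b", "c"))
})

test_that("all_history keeps everything strictly before index", {
  master <- toy_master(2)
  dx <- dimension_table(tibble::tibble(
    patient_id = "p1", code = c("a", "b", "c"),
    event_date = master$index_date[1] - c(0, 1, 4000)), "dx")
  out <- apply_window(dx, master, window_spec("dx", "all_history"))
  expect_identical(out$code, c("b", "c"))
})

test_that("windowed records match a per-record date-arithmetic oracle", {
  master <- toy_master(4)
  set.seed(7)
  days_back <- sample(1:400, 60, replace = TRUE)
  pid <- sample(master$patient_id, 60, replace = TRUE)
  dx <- dimension_table(tibble::tibble(
    patient_id = pid, code = sprintf("c%02d", seq_len(60)),
    event_date = master$index_date[match(pid, master$patient_id)] - days_back),
    "dx")
  out <- apply_window(dx, master, window_spec("dx", 365))
  keep_oracle <- vapply(seq_len(60), function(i) {
    idx <- master$index_date[match(dx$patient_id[i], master$patient_id)]
    dx$event_date[i] < idx && dx$event_date[i] >= idx - 365
  }, logical(1))
  expect_identical(out$code, dx$code[keep_oracle])
})

test_that("patients absent from the master are dropped with a logged tally", {
  master <- toy_master(2)
  dx <- dimension_table(tibble::tibble(
    patient_id = c("p1", "ghost", "ghost2"),
    code = c("a", "b", "c"),
    event_date = master$index_date[1] - 5), "dx")
  expect_message(out <- apply_window(dx, master, window_spec("dx", 90)),
                 "2 record")
  expect_identical(out$patient_id, "p1")
})

test_that("apply_window is idempotent and returns a pure row subset", {
  master <- toy_master(5)
  set.seed(11)
  dx <- dimension_table(tibble::tibble(
    patient_id = sample(master$patient_id, 40, replace = TRUE),
    code = sample(letters, 40, replace = TRUE),
    event_date = as.Date("2020-06-01") - sample(0:500, 40, replace = TRUE)),
    "dx")
  w <- window_spec("dx", 180)
  once <- apply_window(dx, master, w)
  twice <- apply_window(once, master, w)
  expect_identical(tibble::as_tibble(once), tibble::as_tibble(twice))
  # subset: every output row appears in the input unchanged
  key_in <- paste(dx$patient_id, dx$code, dx$event_date)
  key_out <- paste(once$patient_id, once$code, once$event_date)
  expect_true(all(key_out %in% key_in))
  # all_history then L equals direct L
  via_all <- apply_window(apply_window(dx, master,
                                       window_spec("dx", "all_history")),
                          master, w)
  expect_identical(tibble::as_tibble(via_all), tibble::as_tibble(once))
})

test_that("window spec label mismatch and invalid lookback are rejected", {
  master <- toy_master(2)
  dx <- dimension_table(tibble::tibble(
    patient_id = "p1", code = "a",
    event_date = as.Date("2020-01-01")), "dx")
  expect_error(apply_window(dx, master, window_spec("rx", 90)),
               class = "hdps_config_error")
  expect_error(window_spec("dx", -3), class = "hdps_config_error")
  expect_error(window_spec("dx", "forever"), class = "hdps_config_error")
})

test_that("master validation enforces uniqueness, binary arms and nonnegative time", {
  m <- toy_master(4)
  expect_silent(validate_master(m))
  expect_error(validate_master(dplyr::mutate(m, patient_id = "p1")),
               class = "hdps_schema_error")
  expect_error(validate_master(dplyr::mutate(m, exposure = 1L)),
               class = "hdps_schema_error")
  expect_error(validate_master(dplyr::mutate(m, time_to_event = -1)),
               class = "hdps_schema_error")
})

test_that("parquet round-trip matches the CSV path", {
  skip_if_not_installed("arrow")
  df <- tibble::tibble(pid = c("p1", "p2"), code = c("250.00", "434"))
  pq <- withr::local_tempfile(fileext = ".parquet")
  arrow::write_parquet(df, pq)
  dim_pq <- load_dimension(pq, c(patient_id = "pid", code = "code"), "dx")
  expect_identical(dim_pq$code, df$code)
})
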