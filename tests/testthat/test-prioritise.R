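test_that("association cells match hand cross-tabulation", {
  master <- validate_master(tibble::tibble(
    patient_id = paste0("p", 1:4),
    exposure = c(1L, 0L, 1L, 0L),
    outcome = c(1L, 1L, 0L, 0L),
    time_to_event = rep(1, 4)))
  mat <- tibble::tibble(patient_id = paste0("p", 1:4),
                        C = c(1L, 1L, 0L, 0L),
                        Z = c(0L, 0L, 0L, 0L))
  t <- build_association_tables(mat, master)
  c_row <- t[t$covariate_id == "C", ]
  expect_equal(c_row$e1, 1); expect_equal(c_row$e0, 1)
  expect_equal(c_row$n1, 2); expect_equal(c_row$n0, 2)
  expect_equal(c_row$d1, 2); expect_equal(c_row$d0, 0)
  expect_equal(c_row$m1, 2); expect_equal(c_row$m0, 2)
  # all-zero covariate is degenerate but representable
  z_row <- t[t$covariate_id == "Z", ]
  expect_equal(z_row$e1, 0); expect_equal(z_row$e0, 0); expect_equal(z_row$m1, 0)
})

test_that("association cells equal a nested-loop count on simulated patients", {
  set.seed(42)
  n <- 200
  master <- validate_master(tibble::tibble(
    patient_id = paste0("p", 1:n),
    exposure = rbinom(n, 1, 0.4),
    outcome = rbinom(n, 1, 0.3),
    time_to_event = runif(n, 0.1, 5)))
  mat <- tibble::tibble(patient_id = master$patient_id,
                        a = rbinom(n, 1, 0.2), b = rbinom(n, 1, 0.6))
  t <- build_association_tables(mat, master)
  for (cv in c("a", "b")) {
    e1 <- 0; e0 <- 0; d1 <- 0; d0 <- 0; m1 <- 0
    for (i in seq_len(n)) {
      ci <- mat[[cv]][i]
      if (ci == 1 && master$exposure[i] == 1) e1 <- e1 + 1
      if (ci == 1 && master$exposure[i] == 0) e0 <- e0 + 1
      if (ci == 1) m1 <- m1 + 1
      if (ci == 1 && master$outcome[i] == 1) d1 <- d1 + 1
      if (ci == 0 && master$outcome[i] == 1) d0 <- d0 + 1
    }
    row <- t[t$covariate_id == cv, ]
    expect_equal(unlist(row[, c("e1", "e0", "d1", "d0", "m1")],
                        use.names = FALSE), c(e1, e0, d1, d0, m1))
    expect_equal(row$n1, sum(master$exposure))
    expect_equal(row$m0, n - m1)
  }
})

test_that("misaligned patient sets raise an alignment error naming ids", {
  master <- validate_master(toy_master(4))
  mat <- tibble::tibble(patient_id = c("p1", "p2", "p3", "px"), C = 0L)
  expect_error(build_association_tables(mat, master),
               class = "hdps_alignment_error")
  err <- tryCatch(build_association_tables(mat, master), error = identity)
  expect_match(conditionMessage(err), "p4|px")
})

test_that("zero-cell correction adds 0.1 to all four cells only when a zero occurs", {
  t <- tibble::tibble(covariate_id = c("z", "ok"),
                      e1 = c(5, 3), e0 = c(4, 7), n1 = c(10, 10), n0 = c(10, 10),
                      d1 = c(0, 2), d0 = c(10, 8), m1 = c(9, 5), m0 = c(11, 15),
                      corrected_exposure = FALSE, corrected_outcome = FALSE)
  out <- zero_cell_correct(t)
  # outcome table (0,9,10,1) has a zero: cells (d1, m1-d1, d0, m0-d0) all +0.1
  expect_equal(out$d1[1], 0.1)
  expect_equal(out$m1[1] - out$d1[1], 9.1)
  expect_equal(out$d0[1], 10.1)
  expect_equal(out$m0[1] - out$d0[1], 1.1)
  expect_true(out$corrected_outcome[1])
  # exposure table of 'z' has no zero: untouched
  expect_equal(out$e1[1], 5); expect_equal(out$n1[1], 10)
  expect_false(out$corrected_exposure[1])
  # 'ok' has no zero anywhere: full identity
  expect_equal(out[2, 2:9], t[2, 2:9])
})

test_that("zero-cell correction is idempotent and keeps all RRs finite and positive", {
  set.seed(5)
  for (i in 1:50) {
    e1 <- sample(0:5, 1); e0 <- sample(0:5, 1)
    n1 <- e1 + sample(0:10, 1); n0 <- e0 + sample(0:10, 1)
    d1 <- sample(0:3, 1); d0 <- sample(0:3, 1)
    m1 <- d1 + sample(0:10, 1); m0 <- d0 + sample(0:10, 1)
    t <- tibble::tibble(covariate_id = "c", e1 = e1, e0 = e0,
                        n1 = max(n1, 1), n0 = max(n0, 1),
                        d1 = d1, d0 = d0, m1 = max(m1, 1), m0 = max(m0, 1),
                        corrected_exposure = FALSE, corrected_outcome = FALSE)
    once <- zero_cell_correct(t)
    twice <- zero_cell_correct(once)
    expect_equal(once, twice)
    p <- prioritise(once, correction = FALSE)
    expect_true(is.finite(p$rr_ce) && p$rr_ce > 0)
    expect_true(is.finite(p$rr_cd) && p$rr_cd > 0)
    expect_true(is.finite(p$abs_log_bias))
  }
})

test_that("bross_bias reproduces the closed-form expression", {
  expect_equal(bross_bias(0.2, 0.2, 3)$bias_m, 1)
  expect_equal(bross_bias(0.2, 0.2, 3)$abs_log_bias, 0)
  expect_equal(bross_bias(0.7, 0.3, 1)$bias_m, 1)
  b <- bross_bias(0.5, 0.1, 2)
  expect_equal(b$bias_m, 1.5 / 1.1)
  expect_equal(b$abs_log_bias, log(15 / 11))
  # protective association inverted so magnitude drives the score
  expect_equal(bross_bias(0.5, 0.1, 0.5)$bias_m, bross_bias(0.5, 0.1, 2)$bias_m)
  expect_error(bross_bias(0.5, 0.1, 0), class = "hdps_domain_error")
  expect_error(bross_bias(1.2, 0.1, 2), class = "hdps_domain_error")
})

test_that("bross_bias matches the independent oracle on random triples", {
  set.seed(99)
  for (i in 1:200) {
    pc1 <- runif(1); pc0 <- runif(1); rr <- exp(rnorm(1))
    got <- bross_bias(pc1, pc0, rr)
    expect_equal(got$bias_m, oracle_bross(pc1, pc0, rr), tolerance = 1e-14)
  }
})

test_that("bias multiplier is antisymmetric in prevalences and monotone in pc1", {
  set.seed(12)
  for (i in 1:30) {
    pc1 <- runif(1); pc0 <- runif(1); rr <- exp(abs(rnorm(1))) # rr >= 1
    expect_equal(bross_bias(pc1, pc0, rr)$bias_m *
                   bross_bias(pc0, pc1, rr)$bias_m, 1, tolerance = 1e-12)
  }
  pcs <- seq(0.05, 0.95, by = 0.1)
  biases <- bross_bias(pcs, 0.2, 2)$bias_m
  expect_true(all(diff(biases) > 0))
})

test_that("prioritisation ranks by descending score with lexicographic ties", {
  t <- tibble::tibble(
    covariate_id = c("b", "a", "c"),
    e1 = c(30, 10, 10), e0 = c(10, 10, 10),
    n1 = 100, n0 = 100,
    d1 = c(20, 5, 5), d0 = c(10, 20, 20), m1 = c(40, 20, 20),
    m0 = c(160, 180, 180),
    corrected_exposure = FALSE, corrected_outcome = FALSE)
  p <- prioritise(t)
  # a and c have identical tables -> tied score, a ranked before c
  expect_equal(p$rank, 1:3)
  ia <- which(p$covariate_id == "a"); ic <- which(p$covariate_id == "c")
  expect_lt(ia, ic)
  expect_true(all(diff(p$abs_log_bias) <= 0))
})

test_that("ranking is invariant to input order and matches a recompute-and-sort oracle", {
  set.seed(31)
  n <- 50
  t <- tibble::tibble(
    covariate_id = sprintf("c%02d", 1:n),
    e1 = sample(0:40, n, TRUE), e0 = sample(0:40, n, TRUE),
    n1 = 100, n0 = 120,
    d1 = sample(0:20, n, TRUE), d0 = sample(0:20, n, TRUE),
    m1 = sample(40:80, n, TRUE), m0 = sample(40:80, n, TRUE),
    corrected_exposure = FALSE, corrected_outcome = FALSE)
  t$m1 <- pmax(t$m1, t$d1); t$m0 <- pmax(t$m0, t$d0)
  t$n1 <- pmax(t$n1, t$e1); t$n0 <- pmax(t$n0, t$e0)
  p1 <- prioritise(t)
  p2 <- prioritise(t[sample(n), ])
  expect_equal(p1, p2)
  # independent recomputation of scores, then sort
  tc <- zero_cell_correct(t)
  scores <- vapply(seq_len(n), function(i) {
    pc1 <- tc$e1[i] / tc$n1[i]; pc0 <- tc$e0[i] / tc$n0[i]
    rr_cd <- (tc$d1[i] / tc$m1[i]) / (tc$d0[i] / tc$m0[i])
    abs(log(oracle_bross(pc1, pc0, rr_cd)))
  }, numeric(1))
  oracle_order <- tc$covariate_id[order(-scores, tc$covariate_id)]
  expect_identical(p1$covariate_id, oracle_order)
})

test_that("with correction enabled every covariate receives a finite score", {
  master <- validate_master(toy_master(6))
  mat <- tibble::tibble(patient_id = master$patient_id,
                        allzero = 0L, allone = 1L,
                        mixed = c(1L, 0L, 1L, 0L, 1L, 0L))
  p <- prioritise(build_association_tables(mat, master))
  expect_equal(nrow(p), 3)
  expect_true(all(is.finite(p$abs_log_bias)))
})

test_that("select_top clamps, honours rank order and supports the sensitivity grid", {
  p <- tibble::tibble(covariate_id = letters[1:5],
                      rank = 1:5, iv_like = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(select_top(p, 3), c("a", "b", "c"))
  expect_identical(select_top(p, 0), character(0))
  expect_identical(select_top(p, 10), letters[1:5])
  expect_identical(select_top(p, 3, remove_iv = TRUE), c("a", "c", "d"))
  for (k in c(10, 50, 100, 150, 200, 250, 500)) {
    expect_length(select_top(p, k), 5)
  }
})

test_that("instrument-like flag matches direct evaluation with strict boundaries", {
  expect_true(flag_iv_like(exp(1.6), exp(0.4)))
  expect_false(flag_iv_like(exp(1.5), exp(0.4)))   # boundary strict
  expect_false(flag_iv_like(exp(1.6), exp(0.5)))   # boundary strict
  expect_true(flag_iv_like(exp(-1.6), exp(-0.4)))  # magnitudes, either sign
  grid <- expand.grid(lce = seq(-2.5, 2.5, by = 0.25),
                      lcd = seq(-1, 1, by = 0.1))
  got <- flag_iv_like(exp(grid$lce), exp(grid$lcd))
  oracle <- abs(grid$lce) > 1.5 & abs(grid$lcd) < 0.5
  expect_identical(got, oracle)
})
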