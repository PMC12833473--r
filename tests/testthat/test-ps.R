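test_that("empty covariate list gives the marginal prevalence and unit weights", {
  master <- validate_master(toy_master(10))
  data <- master
  fit <- fit_ps(data)
  expect_equal(fit$ps, rep(mean(master$exposure), 10))
  w <- stabilised_weights(fit$ps, master$exposure, trim = 1)
  expect_equal(w$weight, rep(1, 10))
})

test_that("a covariate independent of exposure leaves ps near the marginal prevalence", {
  set.seed(2)
  n <- 5000
  data <- tibble::tibble(exposure = rbinom(n, 1, 0.4), x = rnorm(n))
  fit <- fit_ps(data, predefined = "x")
  expect_lt(diff(range(fit$ps)), 0.12)
  expect_equal(mean(fit$ps), mean(data$exposure), tolerance = 1e-6)
})

test_that("logistic coefficients are recovered within 3 SE on simulated data", {
  set.seed(77)
  n <- 5000
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.3)
  truth <- c(`(Intercept)` = -0.5, x1 = 0.8, x2 = -0.6)
  y <- rbinom(n, 1, plogis(truth[1] + truth[2] * x1 + truth[3] * x2))
  fit <- fit_ps(tibble::tibble(exposure = y, x1 = x1, x2 = x2),
                predefined = c("x1", "x2"))
  ref <- glm(y ~ x1 + x2, family = binomial())
  se <- sqrt(diag(vcov(ref)))
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_true(all(abs(est[names(truth)] - truth) < 3 * se))
  # and the fit agrees with stats::glm itself
  expect_equal(unname(est[names(truth)]), unname(coef(ref)), tolerance = 1e-8)
})

test_that("constant covariates are dropped with a warning", {
  master <- validate_master(toy_master(10))
  data <- dplyr::mutate(master, flat = 1, ok = rep(c(0, 1), 5))
  expect_warning(fit <- fit_ps(data, predefined = c("flat", "ok")), "constant")
  expect_identical(fit$terms, "ok")
})

test_that("separation triggers the ridge fallback and finite scores", {
  set.seed(4)
  n <- 60
  expo <- rep(c(1L, 0L), each = n / 2)
  data <- tibble::tibble(exposure = expo,
                         sep = expo,          # perfect separator
                         x = rnorm(n))
  expect_message(fit <- fit_ps(data, predefined = c("sep", "x")), "ridge")
  expect_identical(fit$method, "ridge")
  expect_true(all(fit$ps > 0 & fit$ps < 1))
})

test_that("stabilised weights follow the closed form and trim at the pooled percentile", {
  # p_bar = 0.4: exposed with ps 0.8 -> 0.5; unexposed with ps 0.8 -> 3.0
  ps <- c(0.8, 0.8, 0.5, 0.5, 0.5)
  expo <- c(1, 0, 0, 1, 0)           # p_bar = 0.4
  w <- stabilised_weights(ps, expo, trim = 1)
  expect_equal(w$weight[1], 0.4 / 0.8)          # 0.5
  expect_equal(w$weight[2], (1 - 0.4) / (1 - 0.8))  # 3.0
  set.seed(10)
  ps2 <- runif(1000, 0.05, 0.95)
  expo2 <- rbinom(1000, 1, ps2)
  w2 <- stabilised_weights(ps2, expo2, trim = 0.99)
  raw <- ifelse(expo2 == 1, mean(expo2) / ps2, (1 - mean(expo2)) / (1 - ps2))
  cap_oracle <- unname(quantile(raw, 0.99))
  expect_equal(attr(w2, "cap"), cap_oracle)
  expect_true(all(w2$weight <= cap_oracle + 1e-12))
  # trimming is monotone: capped below, untouched under the cap
  expect_true(all(w2$weight <= w2$weight_raw))
  under <- w2$weight_raw < cap_oracle
  expect_equal(w2$weight[under], w2$weight_raw[under])
})

test_that("mean stabilised weight is near 1 in each arm before trimming", {
  set.seed(20)
  n <- 20000
  x <- rnorm(n)
  ps_true <- plogis(-0.4 + 0.8 * x)
  expo <- rbinom(n, 1, ps_true)
  fit <- fit_ps(tibble::tibble(exposure = expo, x = x), predefined = "x")
  w <- stabilised_weights(fit$ps, expo, trim = 1)
  expect_equal(mean(w$weight_raw[expo == 1]), 1, tolerance = 0.05)
  expect_equal(mean(w$weight_raw[expo == 0]), 1, tolerance = 0.05)
})

test_that("degenerate propensity scores are clipped with a warning", {
  expect_warning(w <- stabilised_weights(c(0, 1, 0.5), c(0, 1, 1), trim = 1),
                 "clipped")
  expect_true(all(is.finite(w$weight)))
})

test_that("unit weights reproduce the unweighted Cox fit bit-exactly", {
  master <- validate_master(tibble::tibble(
    patient_id = paste0("p", 1:40),
    exposure = rep(c(1L, 0L), 20),
    outcome = rep(c(1L, 1L, 0L, 0L), 10),
    time_to_event = seq(0.5, 20, by = 0.5)))
  weighted <- fit_weighted_cox(master, rep(1, 40))
  ref <- survival::coxph(
    survival::Surv(master$time_to_event, master$outcome) ~ master$exposure)
  expect_identical(weighted$log_hr, unname(coef(ref)[1]))
})

test_that("two identical arms give a hazard ratio of 1", {
  times <- c(1, 2, 3, 4, 5)
  status <- c(1, 1, 0, 1, 0)
  master <- validate_master(tibble::tibble(
    patient_id = paste0("p", 1:10),
    exposure = rep(c(0L, 1L), each = 5),
    outcome = rep(status, 2),
    time_to_event = rep(times, 2)))
  fit <- fit_weighted_cox(master, rep(1, 10))
  expect_equal(fit$hr, 1, tolerance = 1e-8)
})

test_that("an arm without events raises an estimation error naming the arm", {
  master <- validate_master(tibble::tibble(
    patient_id = paste0("p", 1:10),
    exposure = rep(c(0L, 1L), each = 5),
    outcome = c(1L, 1L, 0L, 1L, 0L, rep(0L, 5)),
    time_to_event = rep(1:5, 2)))
  err <- tryCatch(fit_weighted_cox(master, rep(1, 10)), error = identity)
  expect_s3_class(err, "hdps_fit_error")
  expect_match(conditionMessage(err), "exposed")
})

test_that("the weighted Cox recovers a known hazard ratio without confounding", {
  hrs <- vapply(1:3, function(seed) {
    set.seed(seed)
    n <- 20000
    expo <- rbinom(n, 1, 0.5)
    t_event <- rexp(n, 0.05 * 0.8^expo)
    master <- validate_master(tibble::tibble(
      patient_id = paste0("p", 1:n), exposure = expo,
      outcome = as.integer(t_event <= 10),
      time_to_event = pmin(t_event, 10)))
    fit_weighted_cox(master, rep(1, n))$hr
  }, numeric(1))
  expect_true(mean(hrs) > 0.75 && mean(hrs) < 0.85)
})

test_that("adding a null covariate barely moves the weighted estimate", {
  run <- confounded_run(314, true_hr = 1, n_patients = 8000, n_select = 50)
  res <- run$res
  set.seed(314)
  data2 <- dplyr::mutate(res$data, null_cov = rbinom(nrow(res$data), 1, 0.3))
  fit1 <- fit_ps(res$data, predefined = c("age", "female"),
                 hdps = res$selected)
  fit2 <- fit_ps(data2, predefined = c("age", "female"),
                 hdps = c(res$selected, "null_cov"))
  w1 <- stabilised_weights(fit1$ps, res$data$exposure)
  w2 <- stabilised_weights(fit2$ps, res$data$exposure)
  m1 <- fit_weighted_cox(res$data, w1$weight)
  m2 <- fit_weighted_cox(data2, w2$weight)
  expect_lt(abs(m1$log_hr - m2$log_hr), 0.02)
})
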