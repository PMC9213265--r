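test_that("generation is seed-deterministic and stable under n changes", {
  a <- generate_bundle(simulation_config(n_patients = 20, seed = 1))
  b <- generate_bundle(simulation_config(n_patients = 20, seed = 1))
  c <- generate_bundle(simulation_config(n_patients = 20, seed = 2))
  expect_identical(a$bundle$prescriptions, b$bundle$prescriptions)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$bundle$prescriptions, c$bundle$prescriptions))
  # per-patient streams: the first 10 patients are unchanged when n grows
  big <- generate_bundle(simulation_config(n_patients = 30, seed = 1))
  expect_identical(a$truth[1:10, ], big$truth[1:10, ])
})

test_that("zero-gap generation tiles each episode contiguously", {
  g <- generate_bundle(simulation_config(n_patients = 40, seed = 3,
                                         gap_prob = 0,
                                         post_episode_rx_prob = 0))
  drugs <- g$bundle$drugs
  op <- drugs$drug_code[drugs$role %in% c("base_opioid", "rescue_opioid")]
  for (pid in g$truth$patient_id) {
    tr <- g$truth[g$truth$patient_id == pid, ]
    rx <- g$bundle$prescriptions
    rx <- rx[rx$patient_id == pid & rx$drug_code %in% op, ]
    covered <- sort(unique(unlist(Map(
      function(s, d) s + seq_len(d) - 1,
      as.integer(rx$start_date - tr$index_date) + 1, rx$days_supplied))))
    expect_equal(covered, seq_len(tr$duration_days))
  }
})

test_that("empty and tiny configurations behave", {
  g0 <- generate_bundle(simulation_config(n_patients = 0))
  expect_equal(nrow(g0$bundle$patients), 0)
  d1 <- generate_regression_dataset(1, c(x1 = 1), c(-1, -2), seed = 1)
  expect_equal(nrow(d1$x), 1)
  expect_true(d1$y %in% 0:2)
})

test_that("planted covariate prevalences are recovered", {
  g <- generate_bundle(simulation_config(n_patients = 600, seed = 21))
  covs <- default_sim_covariates()
  for (j in seq_len(nrow(covs))) {
    p_hat <- mean(g$truth[[covs$name[j]]])
    se <- sqrt(covs$prevalence[j] * (1 - covs$prevalence[j]) / 600)
    expect_lt(abs(p_hat - covs$prevalence[j]), 4 * se + 1e-9)
  }
})

test_that("the regression generator follows the cumulative-logit model", {
  # no covariate effect: marginals equal the intercept logits
  d <- generate_regression_dataset(20000, c(x1 = 0),
                                   c(stats::qlogis(0.2), stats::qlogis(0.05)),
                                   seed = 4)
  expect_lt(abs(mean(d$y >= 1) - 0.2), 4 * sqrt(0.2 * 0.8 / 20000))
  expect_lt(abs(mean(d$y >= 2) - 0.05), 4 * sqrt(0.05 * 0.95 / 20000))
  # one binary covariate with beta = log 2: empirical cumulative odds ratio
  d2 <- generate_regression_dataset(50000, c(x1 = log(2)), c(-1, -2),
                                    seed = 8)
  x <- d2$x$x1
  or_hat <- (mean(d2$y[x == 1] >= 1) / (1 - mean(d2$y[x == 1] >= 1))) /
    (mean(d2$y[x == 0] >= 1) / (1 - mean(d2$y[x == 0] >= 1)))
  expect_lt(abs(log(or_hat) - log(2)), 0.08)
  expect_error(generate_regression_dataset(10, c(x1 = 1), c(-2, -1)),
               "decreasing")
})

test_that("infeasible calendars are rejected", {
  expect_error(
    generate_bundle(simulation_config(
      n_patients = 5, seed = 1,
      calendar_start = as.Date("2008-04-01"),
      calendar_end = as.Date("2009-04-01"))),
    "infeasible|invalid|negative", ignore.case = TRUE)
})
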