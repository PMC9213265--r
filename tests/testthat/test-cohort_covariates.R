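test_that("classification follows the duration and dose cut-offs", {
  # control is defined by duration alone, whatever the dose
  expect_equal(as.character(classify_episode(100, 300, TRUE)), "control")
  expect_equal(as.character(classify_episode(200, 130, TRUE)), "case_I")
  expect_equal(as.character(classify_episode(800, 130, TRUE)), "case_II")
  expect_equal(as.character(classify_episode(200, 50, TRUE)),
               "excluded_long_low_dose")
  expect_equal(as.character(classify_episode(200, NA, FALSE)),
               "excluded_dose_not_calculable")
  # boundaries: 183 days and 120 mg/day are inclusive for the case side,
  # 730 days separates case I from case II
  expect_equal(as.character(classify_episode(182, 500, TRUE)), "control")
  expect_equal(as.character(classify_episode(183, 120, TRUE)), "case_I")
  expect_equal(as.character(classify_episode(730, 120, TRUE)), "case_II")
  expect_equal(as.character(classify_episode(729, 120, TRUE)), "case_I")
})

test_that("classification partitions patients and is threshold-monotone", {
  set.seed(88)
  dur <- sample(1:1200, 500, replace = TRUE)
  dose <- stats::rlnorm(500, log(60), 1)
  calc <- stats::runif(500) > 0.02
  g <- classify_episode(dur, dose, calc)
  expect_false(any(is.na(g)))
  expect_equal(sum(table(g)), 500)
  # raising the dose cut never moves a patient from control to case
  g_hi <- classify_episode(dur, dose, calc,
                           cohort_thresholds(high_dose_mg = 200))
  was_case <- g %in% c("case_I", "case_II")
  is_case <- g_hi %in% c("case_I", "case_II")
  expect_true(all(is_case <= was_case))
  expect_true(all(g[g == "control"] == g_hi[g == "control"]))
})

test_that("covariate flags respect the pre-index and on-episode windows", {
  idx <- as.Date("2015-06-01")
  rx <- dplyr::bind_rows(
    toy_rx("P1", "MOR-SR", idx, 100),
    toy_rx("P1", "GABA-1", idx - 10, 7),          # pre-index only
    toy_rx("P1", "SNRI-1", idx + 20, 7),          # on-episode only
    toy_rx("P1", "NSAID", idx - 30, 7),
    toy_rx("P1", "NSAID", idx + 5, 7))            # both windows
  extra <- toy_dx(rep("P1", 3), c("M54.1", "CHEM", "RADI"),
                  c(idx - 100, idx, idx + 200))
  b <- one_patient_bundle(rx, dx_date = "2015-01-01", extra_dx = extra)
  cov <- extract_covariates(b, build_episodes(b))
  expect_true(cov$pre_gabapentinoid)
  expect_false(cov$during_gabapentinoid)
  expect_false(cov$pre_SNRI)
  expect_true(cov$during_SNRI)
  expect_true(cov$pre_non_opioid_analgesic && cov$during_non_opioid_analgesic)
  expect_true(cov$back_pain)
  # chemotherapy record on the index date counts as on-episode
  expect_true(cov$during_chemotherapy)
  expect_false(cov$pre_chemotherapy)
  # radiotherapy dated after the episode end (day 100) is outside the window
  expect_false(cov$during_radiotherapy)
  expect_equal(cov$days_dx_to_index, 151L)
  expect_equal(cov$age_at_index, 65L)
})

test_that("descriptive table summarises groups and tests against control", {
  set.seed(31)
  n <- c(control = 60, case_I = 20, case_II = 30)
  df <- tibble::tibble(
    group = factor(rep(names(n), n), levels = cohort_levels()),
    flag = c(stats::rbinom(60, 1, 0.2), stats::rbinom(20, 1, 0.7),
             stats::rbinom(30, 1, 0.7)) == 1,
    age = stats::rnorm(110, 65, 10) + 5 * rep(c(0, 1, 1), n))
  tab <- descriptive_table(df, exclude = "group")
  expect_equal(nrow(tab), 2)
  flag_row <- tab[tab$variable == "flag", ]
  expect_equal(flag_row$type, "categorical")
  expect_equal(flag_row$n_control, sum(df$flag[df$group == "control"]))
  expect_equal(flag_row$stat_control,
               pct(flag_row$n_control, 60))
  expect_lt(flag_row$p_case_II, 0.05)
  age_row <- tab[tab$variable == "age", ]
  expect_equal(age_row$type, "continuous")
  expect_equal(age_row$stat_control, mean(df$age[df$group == "control"]))
  expect_true(all(!is.na(c(age_row$p_case_I, age_row$p_case_II))))
})

test_that("single-group input yields descriptive columns without tests", {
  df <- tibble::tibble(group = factor(rep("control", 10),
                                      levels = cohort_levels()),
                       flag = rep(c(TRUE, FALSE), 5))
  tab <- descriptive_table(df, exclude = "group")
  expect_equal(tab$n_control, 5)
  expect_true(is.na(tab$p_case_I) && is.na(tab$p_case_II))
})

test_that("percentages round half-up to one decimal", {
  expect_equal(round_half_up(2.25, 1), 2.3)
  expect_equal(round_half_up(2.249, 1), 2.2)
  expect_equal(pct(1, 8), 12.5)
  expect_equal(pct(0, 10), 0)
})
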