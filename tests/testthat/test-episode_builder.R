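test_that("eligibility needs cancer, a post-diagnosis opioid, and 730 days", {
  idx <- as.Date("2014-06-01")
  # opioid before the first cancer diagnosis only: not eligible
  b <- one_patient_bundle(toy_rx("P1", "MOR-SR", "2013-06-01", 14),
                          dx_date = "2014-01-01")
  expect_equal(nrow(select_eligible(b)), 0)
  # end_of_data exactly 729 days after index: excluded at the boundary
  b <- one_patient_bundle(toy_rx("P1", "MOR-SR", idx, 14),
                          eod = idx + 729)
  expect_equal(nrow(select_eligible(b)), 0)
  expect_equal(nrow(select_eligible(b, min_followup_days = 729)), 1)
  # opioid on the diagnosis day with long follow-up: eligible, index = dx day
  b <- one_patient_bundle(toy_rx("P1", "MOR-SR", "2014-01-01", 14),
                          dx_date = "2014-01-01", eod = "2016-06-01")
  el <- select_eligible(b)
  expect_equal(el$index_date, as.Date("2014-01-01"))
  expect_equal(el$followup_days, 882L)
  # injectable-only opioid history never qualifies
  b <- one_patient_bundle(toy_rx("P1", "FEN-INJ", "2014-06-01", 14))
  expect_equal(nrow(select_eligible(b)), 0)
})

test_that("a 29-day uncovered run continues the episode; 30 days ends it", {
  idx <- as.Date("2015-01-01")
  # A covers days 1-14, B starts day 44: uncovered days 15-43 = 29 days
  rx <- rx_tibble(c(1, 44), c(14, 10))
  ep <- build_episode(rx, idx)
  expect_equal(ep$duration_days, 53L)
  # B starts day 45: uncovered days 15-44 = 30 days -> episode ends day 14
  rx <- rx_tibble(c(1, 45), c(14, 10))
  ep <- build_episode(rx, idx)
  expect_equal(ep$duration_days, 14L)
  expect_equal(nrow(ep$episode_rx), 1)
})

test_that("opioid switches and overlaps continue a single episode", {
  idx <- as.Date("2015-01-01")
  rx <- dplyr::bind_rows(
    rx_tibble(1, 30, drug_code = "OXY-SR", daily_dose_mg = 20),
    rx_tibble(20, 41, drug_code = "FEN-TTS", daily_dose_mg = 0.6))
  ep <- build_episode(rx, idx)
  expect_equal(ep$end_date, idx + 59)
  expect_equal(ep$duration_days, 60L)
})

test_that("episode construction ignores row order and requires an index rx", {
  idx <- as.Date("2015-01-01")
  rx <- rx_tibble(c(1, 10, 50), c(14, 25, 7))
  shuffled <- rx[c(3, 1, 2), ]
  expect_equal(build_episode(rx, idx)$end_date,
               build_episode(shuffled, idx)$end_date)
  expect_error(build_episode(rx_tibble(5, 10), idx), "index date")
})

test_that("OME sums convert by factor and skip non-convertible drugs", {
  drugs <- default_drug_dictionary()
  # morphine oral, factor exactly 1: 30 mg/day x 10 days
  rx <- rx_tibble(1, 10, daily_dose_mg = 30)
  o <- episode_ome(rx, drugs, 10)
  expect_equal(o$total_ome_mg, 300)
  expect_equal(o$mean_daily_ome, 30)
  # oxycodone factor 1.5: 40 mg/day x 15 days over a 30-day episode whose
  # tail is covered by a zero-dose prescription
  rx <- dplyr::bind_rows(
    rx_tibble(1, 15, drug_code = "OXY-SR", daily_dose_mg = 40),
    rx_tibble(16, 15, drug_code = "OXY-SR", daily_dose_mg = 0))
  o <- episode_ome(rx, drugs, 30)
  expect_equal(o$total_ome_mg, 900)
  expect_equal(o$mean_daily_ome, 30)
  # fentanyl buccal only: dose not calculable
  rx <- rx_tibble(1, 10, drug_code = "FEN-BUC", daily_dose_mg = 0.4)
  o <- episode_ome(rx, drugs, 10)
  expect_false(o$dose_calculable)
  expect_equal(o$total_ome_mg, 0)
  # mixed: buccal contributes zero without poisoning the sum
  rx <- dplyr::bind_rows(rx_tibble(1, 10, daily_dose_mg = 30),
                         rx_tibble(1, 10, drug_code = "FEN-BUC",
                                   daily_dose_mg = 0.4))
  o <- episode_ome(rx, drugs, 10)
  expect_true(o$dose_calculable)
  expect_equal(o$total_ome_mg, 300)
})

test_that("episode building is idempotent, monotone, and shift-invariant", {
  idx <- as.Date("2015-01-01")
  set.seed(4021)
  for (i in 1:200) {
    rxs <- random_rx_set()
    rx <- rx_tibble(rxs$start_day, rxs$days_supplied)
    ep <- build_episode(rx, idx)
    # idempotence on the episode's own prescriptions
    ep2 <- build_episode(ep$episode_rx, idx)
    expect_identical(ep2$end_date, ep$end_date)
    # adding an rx within 29 uncovered days of the end never shortens it
    add <- rx_tibble(as.integer(ep$end_date - idx) + 1 + sample(1:29, 1),
                     sample(1:20, 1))
    ep3 <- build_episode(dplyr::bind_rows(rx, add), idx)
    expect_gte(ep3$duration_days, ep$duration_days)
    # translation invariance
    k <- sample(-300:300, 1)
    rx_k <- rx
    rx_k$start_date <- rx_k$start_date + k
    ep_k <- build_episode(rx_k, idx + k)
    expect_equal(as.integer(ep_k$end_date - (idx + k)),
                 as.integer(ep$end_date - idx))
  }
})

test_that("interval merge agrees with the day-grid oracle", {
  idx <- as.Date("2015-01-01")
  set.seed(551)
  for (i in 1:500) {
    rxs <- random_rx_set()
    ep <- build_episode(rx_tibble(rxs$start_day, rxs$days_supplied), idx)
    oracle_end <- day_grid_episode_end(rxs$start_day, rxs$days_supplied)
    expect_equal(as.integer(ep$end_date - idx) + 1L, oracle_end)
  }
})
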