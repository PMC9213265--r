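test_that("prescription status reflects base and rescue roles", {
  drugs <- default_drug_dictionary()
  only_sol <- rx_tibble(1, 10, drug_code = "MOR-SOL")
  expect_equal(prescription_status(only_sol, drugs), "rescue_only")
  both <- dplyr::bind_rows(rx_tibble(1, 30, drug_code = "FEN-TTS"),
                           rx_tibble(5, 3, drug_code = "OXY-IR"))
  expect_equal(prescription_status(both, drugs), "base_and_rescue")
  patch <- rx_tibble(1, 30, drug_code = "FEN-TTS")
  expect_equal(prescription_status(patch, drugs), "base_only")
  non_opioid <- rx_tibble(1, 10, drug_code = "NSAID")
  expect_error(prescription_status(non_opioid, drugs), "no opioid")
})

test_that("rescue intensity counts units and converts only convertible mg", {
  drugs <- default_drug_dictionary()
  # 10 rescue units carrying 300 mg OME over a 10-day episode
  rx <- rx_tibble(1, 10, drug_code = "MOR-IR", daily_dose_mg = 30,
                  n_units = 10)
  ri <- rescue_intensity(rx, drugs, 10)
  expect_equal(ri$mean_daily_uses, 1)
  expect_equal(ri$mean_daily_rescue_ome, 30)
  # 5 fentanyl buccal units (not convertible) + 5 morphine IR units of
  # 10 mg each over 10 days: frequency counts all units, dose only morphine
  rx <- dplyr::bind_rows(
    rx_tibble(1, 5, drug_code = "FEN-BUC", daily_dose_mg = 0.1, n_units = 5),
    rx_tibble(6, 5, drug_code = "MOR-IR", daily_dose_mg = 10, n_units = 5))
  ri <- rescue_intensity(rx, drugs, 10)
  expect_equal(ri$mean_daily_uses, 1)
  expect_equal(ri$mean_daily_rescue_ome, 5)
  # contract: no rescue prescriptions present
  expect_error(rescue_intensity(rx_tibble(1, 10, drug_code = "MOR-SR"),
                                drugs, 10),
               "without rescue")
})

test_that("rescue summary partitions each group and bounds rescue dose", {
  g <- generate_bundle(simulation_config(n_patients = 250, seed = 17))
  run_ep <- build_episodes(g$bundle)
  rs <- rescue_summary(g$bundle, run_ep)
  # the three statuses partition every group
  grp_n <- table(rs$per_patient$group[rs$per_patient$group %in%
                                        c("control", "case_I", "case_II")])
  expect_equal(rs$status$n_control[1] + rs$status$n_control[2] +
                 rs$status$n_control[3], unname(grp_n[["control"]]))
  expect_equal(sum(rs$status$n_case_II), unname(grp_n[["case_II"]]))
  # planted statuses are recovered exactly
  m <- merge(rs$per_patient, g$truth, by = "patient_id")
  expect_equal(m$status, m$rescue_status)
  # rescue OME never exceeds the whole-episode mean when all rescue drugs
  # convert
  ep <- run_ep[match(rs$per_patient$patient_id, run_ep$patient_id), ]
  ok <- !is.na(rs$per_patient$mean_daily_rescue_ome) & ep$dose_calculable
  expect_true(all(rs$per_patient$mean_daily_rescue_ome[ok] <=
                    ep$mean_daily_ome[ok] + 1e-9))
})
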