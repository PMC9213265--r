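# Small hand-built bundles for unit tests.

toy_patients <- function(ids, eod = "2021-12-31", sex = "male",
                         birth_year = 1950) {
  tibble::tibble(patient_id = ids, sex = sex, birth_year = birth_year,
                 end_of_data = as.Date(eod))
}

toy_dx <- function(ids, codes, dates) {
  tibble::tibble(patient_id = ids, icd10_code = codes,
                 date = as.Date(dates))
}

toy_rx <- function(ids, drug, start, days, dose = 30, units = NULL) {
  tibble::tibble(patient_id = ids, drug_code = drug,
                 start_date = as.Date(start),
                 days_supplied = as.integer(days),
                 daily_dose_mg = dose,
                 n_units = as.integer(if (is.null(units)) days else units))
}

# one cancer patient with a configurable prescription history
one_patient_bundle <- function(rx, dx_date = "2014-01-01",
                               eod = "2021-12-31", extra_dx = NULL) {
  dx <- toy_dx("P1", "C50.9", dx_date)
  if (!is.null(extra_dx)) dx <- dplyr::bind_rows(dx, extra_dx)
  claims_bundle(toy_patients("P1", eod = eod), dx, rx)
}
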