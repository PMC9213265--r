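# Brute-force day-grid episode oracle: mark every covered calendar day and
# find the first uncovered run of >= gap_days after day 1. Independent of the
# interval-merge implementation.
day_grid_episode_end <- function(start_day, days_supplied, gap_days = 30) {
  stopifnot(any(start_day == 1))
  last <- max(start_day + days_supplied - 1)
  covered <- rep(FALSE, last)
  for (i in seq_along(start_day))
    covered[start_day[i]:(start_day[i] + days_supplied[i] - 1)] <- TRUE
  run <- 0L
  for (d in seq_len(last)) {
    if (covered[d]) {
      run <- 0L
    } else {
      run <- run + 1L
      if (run >= gap_days) {
        prior <- which(covered[seq_len(d)])
        return(max(prior))
      }
    }
  }
  max(which(covered))
}

# random prescription set anchored at day 1, mixing overlaps, contiguous
# refills, sub-30 gaps and occasional >= 30 breaks (including exact-boundary
# gaps of 29 and 30 days)
random_rx_set <- function(max_rx = 8) {
  n <- sample(1:max_rx, 1)
  start <- c(1L, 1L + cumsum(sample(c(0:35, 29L, 30L), n - 1,
                                    replace = TRUE)))
  len <- sample(1:30, n, replace = TRUE)
  data.frame(start_day = start, days_supplied = len)
}

rx_tibble <- function(start_day, days_supplied, index = as.Date("2015-01-01"),
                      drug_code = "MOR-SR", daily_dose_mg = 30,
                      n_units = days_supplied) {
  tibble::tibble(patient_id = "P1", drug_code = drug_code,
                 start_date = index + start_day - 1L,
                 days_supplied = as.integer(days_supplied),
                 daily_dose_mg = daily_dose_mg,
                 n_units = as.integer(n_units))
}
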