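# Eligibility selection, continuous-prescription-episode construction under a
# persistence gap, and oral morphine equivalent (OME) dosing.
#
# Conventions: prescription coverage is the closed interval
# [start_date, start_date + days_supplied - 1]; episode duration is an
# inclusive day count (end - index + 1); the follow-up requirement is a plain
# date difference (end_of_data - index_date >= 730).

#' Select eligible patients
#'
#' A patient is eligible iff (i) they have a cancer diagnosis (a record whose
#' code matches `cancer_codes`), (ii) they have at least one oral/transdermal
#' opioid prescription (dictionary role `base_opioid` or `rescue_opioid`) on
#' or after the first cancer diagnosis, and (iii) they can be followed for at
#' least `min_followup_days` days from the index date. The index date is the
#' first qualifying opioid prescription on/after the first cancer diagnosis.
#' Injectable and otherwise non-listed preparations (role `other`) never
#' qualify.
#'
#' @param bundle A `claims_bundle`.
#' @param cancer_codes ICD-10 prefixes defining a cancer diagnosis; default
#'   taken from the bundle's code map.
#' @param min_followup_days Minimum days from index date to end of data
#'   (difference of dates); default 730.
#' @return Tibble: `patient_id`, `first_cancer_dx_date`, `index_date`,
#'   `followup_days` — one row per eligible patient.
#' @export
select_eligible <- function(bundle, cancer_codes = NULL,
                            min_followup_days = 730) {
  stopifnot(inherits(bundle, "claims_bundle"))
  if (is.null(cancer_codes)) cancer_codes <- bundle$code_map$cancer_codes
  if (!length(cancer_codes)) stop("cancer_codes must be non-empty")

  dx <- bundle$diagnoses[matches_prefix(bundle$diagnoses$icd10_code,
                                        cancer_codes), ]
  if (!nrow(dx)) return(empty_eligible())
  first_dx <- dx |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(first_cancer_dx_date = min(.data$date), .groups = "drop")

  opioids <- bundle$drugs$drug_code[bundle$drugs$role %in% opioid_roles()]
  rx <- bundle$prescriptions[bundle$prescriptions$drug_code %in% opioids, ]
  if (!nrow(rx)) return(empty_eligible())

  el <- dplyr::inner_join(rx, first_dx, by = "patient_id") |>
    dplyr::filter(.data$start_date >= .data$first_cancer_dx_date)
  if (!nrow(el)) return(empty_eligible())
  el <- el |>
    dplyr::arrange(.data$patient_id, .data$start_date) |>
    dplyr::distinct(.data$patient_id, .keep_all = TRUE) |>
    dplyr::transmute(.data$patient_id, .data$first_cancer_dx_date,
                     index_date = .data$start_date) |>
    dplyr::inner_join(bundle$patients[, c("patient_id", "end_of_data")],
                      by = "patient_id")
  el$followup_days <- as.integer(el$end_of_data - el$index_date)
  el <- el[el$followup_days >= min_followup_days,
           c("patient_id", "first_cancer_dx_date", "index_date",
             "followup_days")]
  dplyr::arrange(el, .data$patient_id)
}

empty_eligible <- function() {
  tibble::tibble(patient_id = character(),
                 first_cancer_dx_date = as.Date(character()),
                 index_date = as.Date(character()),
                 followup_days = integer())
}

#' Build one patient's prescription episode
#'
#' Scans the coverage intervals of all opioid prescriptions (base and rescue,
#' any drug) from the index date forward. The episode continues across
#' uncovered runs shorter than `gap_days` (opioid switches and additions
#' included) and ends at the last covered day before the first uncovered run
#' of `gap_days` or more — or at the last covered day of the final
#' prescription. The result is independent of input row order.
#'
#' @param rx Tibble of one patient's opioid prescriptions (`start_date`,
#'   `days_supplied`); rows starting before `index_date` are ignored.
#' @param index_date The episode anchor; at least one prescription must start
#'   exactly on it.
#' @param gap_days Persistence gap: an uncovered run of this many days or
#'   more terminates the episode. Default 30.
#' @param end_of_data Optional censoring date (death or last record); the
#'   episode end is capped at it.
#' @return List with `index_date`, `end_date`, `duration_days`, and
#'   `episode_rx` (the prescriptions starting within the episode).
#' @export
build_episode <- function(rx, index_date, gap_days = 30, end_of_data = NULL) {
  rx <- rx[rx$start_date >= index_date, ]
  if (!nrow(rx) || !any(rx$start_date == index_date))
    stop("no prescription at the index date", call. = FALSE)

  start <- as.integer(rx$start_date - index_date) + 1L  # day 1 = index date
  end <- start + as.integer(rx$days_supplied) - 1L
  o <- order(start, end)
  start <- start[o]; end <- end[o]

  cur_end <- end[1L]
  for (i in seq_along(start)[-1L]) {
    uncovered <- start[i] - cur_end - 1L
    if (uncovered >= gap_days) break
    cur_end <- max(cur_end, end[i])
  }
  end_date <- index_date + (cur_end - 1L)
  if (!is.null(end_of_data)) end_date <- min(end_date, end_of_data)
  episode_rx <- rx[rx$start_date <= end_date, ]
  list(index_date = index_date, end_date = end_date,
       duration_days = as.integer(end_date - index_date) + 1L,
       episode_rx = episode_rx)
}

#' Oral morphine equivalent dose of an episode
#'
#' Sums `daily_dose_mg * ome_factor * days_supplied` over the episode's
#' convertible opioid prescriptions. Drugs flagged not-convertible (blank
#' `ome_factor`: fentanyl sublingual/buccal tablets, methadone by default)
#' contribute zero milligrams without poisoning the sum; the dose is marked
#' non-calculable only when the episode contains no convertible opioid at
#' all. The denominator of the mean is the full episode duration, covered
#' gaps included.
#'
#' @param episode_rx Prescriptions of the episode (opioid or not; non-opioid
#'   roles are ignored).
#' @param drugs Drug dictionary.
#' @param duration_days Episode duration in days.
#' @return List `total_ome_mg`, `mean_daily_ome`, `dose_calculable`.
#' @export
episode_ome <- function(episode_rx, drugs, duration_days) {
  stopifnot(duration_days >= 1)
  dict <- drugs[match(episode_rx$drug_code, drugs$drug_code), ]
  is_op <- dict$role %in% opioid_roles()
  if (any(is_op & episode_rx$daily_dose_mg < 0))
    stop("negative daily_dose_mg", call. = FALSE)
  conv <- is_op & !is.na(dict$ome_factor)
  total <- sum(episode_rx$daily_dose_mg[conv] * dict$ome_factor[conv] *
                 episode_rx$days_supplied[conv])
  calculable <- any(conv)
  list(total_ome_mg = total,
       mean_daily_ome = if (calculable) total / duration_days else NA_real_,
       dose_calculable = calculable)
}

#' Build episodes for all eligible patients
#'
#' @param bundle A `claims_bundle`.
#' @param eligible Output of [select_eligible()]; computed if `NULL`.
#' @param gap_days Persistence gap (default 30).
#' @return Tibble with one row per eligible patient: `patient_id`,
#'   `index_date`, `end_date`, `duration_days`, `total_ome_mg`,
#'   `mean_daily_ome`, `dose_calculable`.
#' @export
build_episodes <- function(bundle, eligible = NULL, gap_days = 30) {
  stopifnot(inherits(bundle, "claims_bundle"))
  if (is.null(eligible)) eligible <- select_eligible(bundle)
  if (!nrow(eligible)) {
    return(tibble::tibble(patient_id = character(),
                          index_date = as.Date(character()),
                          end_date = as.Date(character()),
                          duration_days = integer(),
                          total_ome_mg = numeric(),
                          mean_daily_ome = numeric(),
                          dose_calculable = logical()))
  }
  opioids <- bundle$drugs$drug_code[bundle$drugs$role %in% opioid_roles()]
  rx <- bundle$prescriptions[bundle$prescriptions$drug_code %in% opioids, ]
  rx_by_pat <- split(rx, factor(rx$patient_id, levels = eligible$patient_id))
  eod <- bundle$patients$end_of_data[match(eligible$patient_id,
                                           bundle$patients$patient_id)]

  rows <- vector("list", nrow(eligible))
  for (i in seq_len(nrow(eligible))) {
    ep <- build_episode(rx_by_pat[[i]], eligible$index_date[i],
                        gap_days = gap_days, end_of_data = eod[i])
    ome <- episode_ome(ep$episode_rx, bundle$drugs, ep$duration_days)
    rows[[i]] <- tibble::tibble(
      patient_id = eligible$patient_id[i],
      index_date = ep$index_date, end_date = ep$end_date,
      duration_days = ep$duration_days,
      total_ome_mg = ome$total_ome_mg,
      mean_daily_ome = ome$mean_daily_ome,
      dose_calculable = ome$dose_calculable)
  }
  dplyr::bind_rows(rows)
}
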