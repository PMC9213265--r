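# Rescue-medication status and intensity during the prescription episode.

#' Rescue/base prescription status of one episode
#'
#' Status from the presence of rescue-role vs base-role opioid prescriptions
#' within the episode.
#'
#' @param episode_rx Prescriptions of the episode.
#' @param drugs Drug dictionary.
#' @return One of `"rescue_only"`, `"base_only"`, `"base_and_rescue"`.
#' @export
prescription_status <- function(episode_rx, drugs) {
  role <- drugs$role[match(episode_rx$drug_code, drugs$drug_code)]
  has_rescue <- any(role == "rescue_opioid", na.rm = TRUE)
  has_base <- any(role == "base_opioid", na.rm = TRUE)
  if (!has_rescue && !has_base)
    stop("episode contains no opioid prescription", call. = FALSE)
  if (has_rescue && has_base) "base_and_rescue"
  else if (has_rescue) "rescue_only" else "base_only"
}

#' Rescue-medication intensity of one episode
#'
#' The mean daily number of rescue uses is the total dispensed rescue dose
#' units divided by the episode duration; the mean daily rescue dose is the
#' total rescue OME divided by the episode duration. Units of
#' non-convertible rescue drugs (fentanyl sublingual/buccal tablets) count
#' toward the frequency but contribute no milligrams.
#'
#' @param episode_rx Prescriptions of the episode (must contain at least one
#'   rescue prescription).
#' @param drugs Drug dictionary.
#' @param duration_days Episode duration.
#' @return List `mean_daily_uses`, `mean_daily_rescue_ome`.
#' @export
rescue_intensity <- function(episode_rx, drugs, duration_days) {
  stopifnot(duration_days >= 1)
  dict <- drugs[match(episode_rx$drug_code, drugs$drug_code), ]
  is_rescue <- dict$role == "rescue_opioid"
  if (!any(is_rescue))
    stop("rescue_intensity called on an episode without rescue prescriptions",
         call. = FALSE)
  uses <- sum(episode_rx$n_units[is_rescue])
  conv <- is_rescue & !is.na(dict$ome_factor)
  ome <- sum(episode_rx$daily_dose_mg[conv] * dict$ome_factor[conv] *
               episode_rx$days_supplied[conv])
  list(mean_daily_uses = uses / duration_days,
       mean_daily_rescue_ome = ome / duration_days)
}

#' Rescue-medication summary by cohort group
#'
#' Per analysis group: patient counts and percentages in each prescription
#' status (`rescue_only` / `base_only` / `base_and_rescue`), compared with
#' the control by the Steel test on the binary receipt of any rescue
#' medication; and, among rescue recipients, mean (SD) daily number of
#' rescue uses and mean (SD) daily rescue OME, compared by the Dunnett test.
#'
#' @param bundle A `claims_bundle`.
#' @param episodes Output of [build_episodes()].
#' @param thresholds See [cohort_thresholds()].
#' @return List: `status` (tibble of counts/percentages with Steel p-values),
#'   `intensity` (tibble of means/SDs with Dunnett p-values), `per_patient`
#'   (patient-level status and intensities).
#' @export
rescue_summary <- function(bundle, episodes,
                           thresholds = cohort_thresholds()) {
  stopifnot(inherits(bundle, "claims_bundle"))
  group <- classify_episode(episodes$duration_days, episodes$mean_daily_ome,
                            episodes$dose_calculable, thresholds)
  opioids <- bundle$drugs$drug_code[bundle$drugs$role %in% opioid_roles()]
  rx <- bundle$prescriptions[bundle$prescriptions$drug_code %in% opioids, ]
  rx_by_pat <- split(rx, factor(rx$patient_id, levels = episodes$patient_id))

  n <- nrow(episodes)
  status <- character(n)
  uses <- rep(NA_real_, n)
  ome <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    erx <- rx_by_pat[[i]]
    erx <- erx[erx$start_date >= episodes$index_date[i] &
                 erx$start_date <= episodes$end_date[i], ]
    status[i] <- prescription_status(erx, bundle$drugs)
    if (status[i] != "base_only") {
      ri <- rescue_intensity(erx, bundle$drugs, episodes$duration_days[i])
      uses[i] <- ri$mean_daily_uses
      ome[i] <- ri$mean_daily_rescue_ome
    }
  }
  per_patient <- tibble::tibble(patient_id = episodes$patient_id,
                                group = group, status = status,
                                mean_daily_uses = uses,
                                mean_daily_rescue_ome = ome)

  cc <- per_patient[per_patient$group %in%
                      c("control", "case_I", "case_II"), ]
  cc$group <- factor(as.character(cc$group),
                     levels = c("control", "case_I", "case_II"))
  n_g <- table(cc$group)
  testable <- all(n_g >= 2)

  any_rescue <- cc$status != "base_only"
  p_steel <- c(NA_real_, NA_real_)
  if (testable && stats::var(as.numeric(any_rescue)) > 0) {
    st <- steel_test(as.numeric(any_rescue), cc$group)
    p_steel <- st$p_adjusted[match(c("case_I", "case_II"), st$comparison)]
  }
  status_tbl <- dplyr::bind_rows(lapply(
    c("rescue_only", "base_only", "base_and_rescue"), function(s) {
      cnt <- unname(vapply(levels(cc$group),
                           function(g) sum(cc$status == s & cc$group == g),
                           numeric(1)))
      tibble::tibble(status = s,
                     n_control = cnt[1], n_case_I = cnt[2],
                     n_case_II = cnt[3],
                     pct_control = pct(cnt[1], n_g[[1]]),
                     pct_case_I = pct(cnt[2], n_g[[2]]),
                     pct_case_II = pct(cnt[3], n_g[[3]]))
    }))
  status_tbl$p_case_I <- c(p_steel[1], NA, NA)
  status_tbl$p_case_II <- c(p_steel[2], NA, NA)

  rec <- cc[any_rescue, ]
  one_metric <- function(v, label) {
    mu <- tapply(rec[[v]], rec$group, mean)
    sdv <- tapply(rec[[v]], rec$group, stats::sd)
    p <- c(NA_real_, NA_real_)
    if (all(table(rec$group) >= 2)) {
      dt <- dunnett_test(rec[[v]], rec$group)
      p <- dt$p_adjusted[match(c("case_I", "case_II"), dt$comparison)]
    }
    tibble::tibble(metric = label,
                   mean_control = mu[[1]], mean_case_I = mu[[2]],
                   mean_case_II = mu[[3]],
                   sd_control = sdv[[1]], sd_case_I = sdv[[2]],
                   sd_case_II = sdv[[3]],
                   p_case_I = p[1], p_case_II = p[2])
  }
  intensity <- dplyr::bind_rows(
    one_metric("mean_daily_uses", "mean_daily_rescue_uses"),
    one_metric("mean_daily_rescue_ome", "mean_daily_rescue_ome_mg"))
  list(status = status_tbl, intensity = intensity, per_patient = per_patient)
}
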