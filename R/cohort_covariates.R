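# Ordered cohort allocation (control < case I < case II) and the
# analysis-ready covariate table.

#' Cohort thresholds
#'
#' The three cut-offs of the cohort definition plus the persistence gap:
#' long-term is an episode of `long_term_days` (default 183, i.e. more than
#' 6 months) or more; high-dose is a mean daily dose of `high_dose_mg`
#' (default 120 mg/day oral morphine equivalent) or more; very-long splits
#' the case group at `very_long_days` (default 730).
#'
#' @param long_term_days,high_dose_mg,very_long_days,gap_days Positive
#'   thresholds.
#' @return Named list of thresholds.
#' @export
cohort_thresholds <- function(long_term_days = 183, high_dose_mg = 120,
                              very_long_days = 730, gap_days = 30) {
  stopifnot(long_term_days > 0, high_dose_mg >= 0, very_long_days > 0,
            gap_days > 0)
  list(long_term_days = long_term_days, high_dose_mg = high_dose_mg,
       very_long_days = very_long_days, gap_days = gap_days)
}

#' Cohort group levels
#'
#' The three analysis groups in increasing order, followed by the two
#' exclusion categories.
#' @return Character vector of labels.
#' @export
cohort_levels <- function() {
  c("control", "case_I", "case_II",
    "excluded_long_low_dose", "excluded_dose_not_calculable")
}

#' Classify episodes into the ordered cohort
#'
#' Deterministic mapping: duration below the long-term cut-off makes a
#' patient a control regardless of dose; long-term episodes at a mean dose
#' at or above the high-dose cut-off are cases, split into case I
#' (duration below the very-long cut-off) and case II (at or above it);
#' long-term episodes below the dose cut-off are excluded (`long_low_dose`),
#' and episodes whose dose cannot be calculated are excluded
#' (`dose_not_calculable`).
#'
#' @param duration_days,mean_daily_ome,dose_calculable Vectors describing
#'   episodes (recycled to a common length).
#' @param thresholds See [cohort_thresholds()].
#' @return Factor with levels [cohort_levels()].
#' @export
classify_episode <- function(duration_days, mean_daily_ome, dose_calculable,
                             thresholds = cohort_thresholds()) {
  n <- max(length(duration_days), length(mean_daily_ome),
           length(dose_calculable))
  duration_days <- rep_len(duration_days, n)
  mean_daily_ome <- rep_len(mean_daily_ome, n)
  dose_calculable <- rep_len(dose_calculable, n)
  out <- character(n)
  long <- duration_days >= thresholds$long_term_days
  out[!dose_calculable] <- "excluded_dose_not_calculable"
  ok <- dose_calculable
  out[ok & !long] <- "control"
  high <- ok & long & mean_daily_ome >= thresholds$high_dose_mg
  out[ok & long & !high] <- "excluded_long_low_dose"
  out[high & duration_days < thresholds$very_long_days] <- "case_I"
  out[high & duration_days >= thresholds$very_long_days] <- "case_II"
  factor(out, levels = cohort_levels())
}

flag_by_window <- function(dates, lo = NULL, hi = NULL) {
  ok <- rep(TRUE, length(dates))
  if (!is.null(lo)) ok <- ok & dates >= lo
  if (!is.null(hi)) ok <- ok & dates <= hi
  any(ok)
}

#' Build the analysis covariate table
#'
#' One row per classified patient: demographics, cancer-site and metastasis
#' flags, comorbidity flags (any record up to the episode end), episode dose,
#' days from first cancer diagnosis to index, and pre-index / on-episode
#' flags for the non-opioid analgesic classes and cancer treatments. The
#' pre-index window is any record strictly before the index date; the
#' on-episode ("during") window is the closed interval from index date to
#' episode end.
#'
#' Diagnosis codes with no entry in the code map are ignored.
#'
#' @param bundle A `claims_bundle`.
#' @param episodes Output of [build_episodes()].
#' @param thresholds See [cohort_thresholds()].
#' @param eligible Output of [select_eligible()]; computed if `NULL`
#'   (needed for `days_dx_to_index`).
#' @return Tibble with one row per episode, including a `group` factor.
#' @export
extract_covariates <- function(bundle, episodes,
                               thresholds = cohort_thresholds(),
                               eligible = NULL) {
  stopifnot(inherits(bundle, "claims_bundle"))
  if (is.null(eligible)) eligible <- select_eligible(bundle)
  cm <- bundle$code_map
  n <- nrow(episodes)

  group <- classify_episode(episodes$duration_days, episodes$mean_daily_ome,
                            episodes$dose_calculable, thresholds)

  pat <- bundle$patients[match(episodes$patient_id,
                               bundle$patients$patient_id), ]
  elig <- eligible[match(episodes$patient_id, eligible$patient_id), ]
  age_at_index <- as.integer(format(episodes$index_date, "%Y")) -
    pat$birth_year
  days_dx_to_index <- as.integer(episodes$index_date -
                                   elig$first_cancer_dx_date)

  dx_by_pat <- split(bundle$diagnoses,
                     factor(bundle$diagnoses$patient_id,
                            levels = episodes$patient_id))
  rx <- dplyr::left_join(bundle$prescriptions,
                         bundle$drugs[, c("drug_code", "role")],
                         by = "drug_code")
  rx_by_pat <- split(rx, factor(rx$patient_id, levels = episodes$patient_id))

  dx_groups <- c(cm$cancer_sites, cm$metastasis, cm$comorbidities)
  tx_tokens <- cm$treatments

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    dx <- dx_by_pat[[i]]
    prx <- rx_by_pat[[i]]
    idx <- episodes$index_date[i]
    endd <- episodes$end_date[i]

    row <- list(patient_id = episodes$patient_id[i], group = group[i],
                sex = pat$sex[i], male = pat$sex[i] == "male",
                age_at_index = age_at_index[i],
                days_dx_to_index = days_dx_to_index[i],
                mean_daily_ome = episodes$mean_daily_ome[i],
                duration_days = episodes$duration_days[i])
    # diagnosis-driven flags: any matching record up to the episode end
    for (nm in names(dx_groups)) {
      m <- matches_prefix(dx$icd10_code, dx_groups[[nm]])
      row[[nm]] <- any(m & dx$date <= endd)
    }
    # analgesic-class prescriptions, by window (prescription start date)
    for (cl in analgesic_roles()) {
      d <- prx$start_date[!is.na(prx$role) & prx$role == cl]
      row[[paste0("pre_", cl)]] <- any(d < idx)
      row[[paste0("during_", cl)]] <- flag_by_window(d, idx, endd)
    }
    # treatment records, by window
    for (tx in names(tx_tokens)) {
      d <- dx$date[dx$icd10_code %in% tx_tokens[[tx]]]
      row[[paste0("pre_", tx)]] <- any(d < idx)
      row[[paste0("during_", tx)]] <- flag_by_window(d, idx, endd)
    }
    rows[[i]] <- tibble::as_tibble(row)
  }
  dplyr::bind_rows(rows)
}

#' Round half-up
#'
#' Percentage-table rounding convention (half-up, unlike base R's
#' round-half-even).
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Percentage of a count, rounded half-up to one decimal
#'
#' @param n Count.
#' @param total Denominator.
#' @return `100 * n / total`, rounded half-up to one decimal.
#' @export
pct <- function(n, total) round_half_up(100 * n / total, 1)

#' Descriptive comparison table (cohort groups vs control)
#'
#' For every covariate column, summarises the three analysis groups and tests
#' each case group against the control: logical columns are summarised as
#' n (%) and tested with the Steel many-to-one rank test; numeric columns as
#' mean (SD) with the Dunnett test. Patients in exclusion categories are
#' dropped. With fewer than two groups present (or fewer than two
#' observations in a group), p-values are reported as `NA`.
#'
#' @param covariates Output of [extract_covariates()] (or any tibble with a
#'   `group` column using [cohort_levels()]).
#' @param exclude Columns never summarised: identifiers and
#'   `duration_days`, which defines the cohort outcome itself and must not
#'   re-enter as a candidate factor.
#' @return Tibble: `variable`, `type`, per-group `n_`/`stat_`/`spread_`
#'   columns (count and percent for categorical; mean and SD for
#'   continuous), `p_case_I`, `p_case_II`.
#' @export
descriptive_table <- function(covariates,
                              exclude = c("patient_id", "group", "sex",
                                          "duration_days")) {
  stopifnot("group" %in% names(covariates))
  cc <- covariates[covariates$group %in% c("control", "case_I", "case_II"), ]
  cc$group <- factor(as.character(cc$group),
                     levels = c("control", "case_I", "case_II"))
  groups <- levels(cc$group)
  n_g <- table(cc$group)
  vars <- setdiff(names(cc), exclude)
  testable <- sum(n_g >= 2) >= 2 && n_g[["control"]] >= 2

  one_var <- function(v) {
    x <- cc[[v]]
    if (is.logical(x)) {
      cnt <- unname(vapply(groups, function(g) sum(x[cc$group == g]),
                           numeric(1)))
      out <- tibble::tibble(variable = v, type = "categorical",
                            n_control = cnt[1], n_case_I = cnt[2],
                            n_case_II = cnt[3],
                            stat_control = pct(cnt[1], n_g[[1]]),
                            stat_case_I = pct(cnt[2], n_g[[2]]),
                            stat_case_II = pct(cnt[3], n_g[[3]]),
                            spread_control = NA_real_,
                            spread_case_I = NA_real_,
                            spread_case_II = NA_real_)
      p <- c(NA_real_, NA_real_)
      if (testable && stats::var(as.numeric(x)) > 0) {
        st <- steel_test(as.numeric(x), cc$group)
        p <- st$p_adjusted[match(c("case_I", "case_II"), st$comparison)]
      } else if (testable) {
        p <- c(1, 1)  # constant everywhere: no evidence of any difference
      }
    } else if (is.numeric(x)) {
      mu <- unname(vapply(groups, function(g) mean(x[cc$group == g]),
                          numeric(1)))
      sdv <- unname(vapply(groups, function(g) stats::sd(x[cc$group == g]),
                           numeric(1)))
      out <- tibble::tibble(variable = v, type = "continuous",
                            n_control = n_g[[1]], n_case_I = n_g[[2]],
                            n_case_II = n_g[[3]],
                            stat_control = mu[1], stat_case_I = mu[2],
                            stat_case_II = mu[3],
                            spread_control = sdv[1], spread_case_I = sdv[2],
                            spread_case_II = sdv[3])
      p <- c(NA_real_, NA_real_)
      if (testable) {
        dt <- dunnett_test(x, cc$group)
        p <- dt$p_adjusted[match(c("case_I", "case_II"), dt$comparison)]
      }
    } else {
      return(NULL)
    }
    out$p_case_I <- p[1]
    out$p_case_II <- p[2]
    out
  }
  dplyr::bind_rows(lapply(vars, one_var))
}
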