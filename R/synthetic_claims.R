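# Synthetic claims generation with planted ground truth.
#
# Group membership is drawn FIRST from the proportional-odds model on planted
# covariate flags; an episode consistent with the group's duration/dose band
# is then materialized as prescriptions tiling the episode span with
# uncovered gaps below the persistence threshold. Doses are solved so that
# the episode's mean daily OME equals the planted value exactly (rescue
# contributions included), which makes the planted labels recoverable by the
# pipeline without slack.

#' Default planted covariates
#'
#' Each row plants one binary covariate: a prevalence, a true log-odds
#' (`beta`) in the group-assignment model, and the claims footprint that
#' carries it (`kind`): a diagnosis code (`dx`), a pre-index or on-episode
#' prescription of a dictionary drug (`rx_pre` / `rx_during`), or a
#' treatment record (`tx_pre` / `tx_during`).
#'
#' @return Tibble with columns `name`, `prevalence`, `beta`, `kind`, `code`.
#' @export
default_sim_covariates <- function() {
  tibble::tribble(
    ~name,                    ~prevalence, ~beta,  ~kind,       ~code,
    "back_pain",               0.45,        0.30,  "dx",        "M54.5",
    "distant_metastasis",      0.33,        0.59,  "dx",        "C78.0",
    "pre_non_opioid",          0.75,       -0.79,  "rx_pre",    "NSAID",
    "during_non_opioid",       0.80,        1.20,  "rx_during", "NSAID",
    "during_gabapentinoid",    0.12,        1.53,  "rx_during", "GABA-1",
    "during_antiepileptic",    0.04,        1.03,  "rx_during", "AED-1",
    "pre_radiotherapy",        0.31,       -0.50,  "tx_pre",    "RADI",
    "during_chemotherapy",     0.70,        0.72,  "tx_during", "CHEM"
  )
}

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: a 2008--2020-style
#' claims calendar, covariate prevalences and true log-odds feeding a
#' cumulative-logit group assignment, per-group episode-duration and dose
#' distributions (log-normal, truncated to the group's band), a within-
#' episode uncovered-gap model bounded below the persistence threshold, and
#' rescue-prescription behaviour. The default intercepts are calibrated so
#' the marginal group shares loosely echo a large hospital claims cohort
#' (roughly 71% control, 0.6% case I, 3.5% case II of dose-calculable
#' patients, with about a quarter excluded as long-duration/low-dose).
#'
#' @param n_patients Number of patients.
#' @param seed Integer seed; together with the patient index it fully
#'   determines each patient's stream, so output is stable under changes of
#'   `n_patients`.
#' @param calendar_start,calendar_end Claims calendar window.
#' @param covariates See [default_sim_covariates()].
#' @param true_intercepts Two strictly decreasing cumulative-logit
#'   cutpoints `(alpha_1, alpha_2)` for `P(Y >= 1)` and `P(Y >= 2)`.
#' @param excluded_long_low_frac Fraction of patients planted with
#'   long-duration, below-dose-threshold episodes (excluded by the
#'   classifier).
#' @param excluded_not_calculable_frac Fraction planted with episodes of
#'   non-convertible opioids only.
#' @param duration_model Per-group log-normal `(meanlog, sdlog)` for episode
#'   duration, truncated to the group band.
#' @param dose_model Per-group mean daily OME model (mg/day).
#' @param gap_prob Probability that a refill boundary opens an uncovered
#'   gap; `0` generates perfectly contiguous coverage.
#' @param gap_max Maximum uncovered gap inside an episode, in days (must be
#'   below the persistence threshold used downstream).
#' @param supply_range Min/max days supplied per prescription.
#' @param rescue_status_probs Per-group probabilities of
#'   `(rescue_only, base_only, base_and_rescue)`.
#' @param rescue_rate Mean rescue dispensings per episode day for
#'   base-and-rescue patients.
#' @param post_episode_rx_prob Probability of an extra opioid prescription
#'   starting at least 30 uncovered days after the episode end.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(
    n_patients = 2000,
    seed = 1,
    calendar_start = as.Date("2008-04-01"),
    calendar_end = as.Date("2020-07-31"),
    covariates = default_sim_covariates(),
    true_intercepts = c(-4.51, -4.68),
    excluded_long_low_frac = 0.25,
    excluded_not_calculable_frac = 0.004,
    duration_model = list(control = c(meanlog = log(45), sdlog = 0.9),
                          case_I = c(meanlog = log(320), sdlog = 0.5),
                          case_II = c(meanlog = log(950), sdlog = 0.4),
                          long_low = c(meanlog = log(400), sdlog = 0.7)),
    dose_model = list(control = c(meanlog = log(15), sdlog = 1.0),
                      case_I = c(meanlog = log(70), sdlog = 0.8),
                      case_II = c(meanlog = log(95), sdlog = 0.8),
                      long_low = c(meanlog = log(25), sdlog = 0.8)),
    gap_prob = 0.35,
    gap_max = 29,
    supply_range = c(14, 30),
    rescue_status_probs = list(control = c(0.235, 0.259, 0.506),
                               case_I = c(0.00, 0.045, 0.955),
                               case_II = c(0.006, 0.026, 0.968)),
    rescue_rate = 0.04,
    post_episode_rx_prob = 0.15) {
  stopifnot(n_patients >= 0,
            calendar_end > calendar_start,
            all(covariates$prevalence >= 0 & covariates$prevalence <= 1),
            length(true_intercepts) == 2,
            excluded_long_low_frac >= 0, excluded_not_calculable_frac >= 0,
            excluded_long_low_frac + excluded_not_calculable_frac < 1,
            gap_prob >= 0, gap_prob <= 1, gap_max >= 0, gap_max <= 29,
            supply_range[1] >= 1, supply_range[2] >= supply_range[1],
            rescue_rate >= 0)
  if (diff(true_intercepts) >= 0)
    stop("true_intercepts must be strictly decreasing (P(Y>=1) > P(Y>=2))",
         call. = FALSE)
  for (p in rescue_status_probs)
    stopifnot(length(p) == 3, all(p >= 0), abs(sum(p) - 1) < 1e-8)
  structure(as.list(environment()), class = "simulation_config")
}

# per-patient stream: a deterministic function of (seed, patient index) so
# outputs are stable under n changes
patient_seed <- function(seed, i) {
  m <- 2147483629
  as.integer((abs(as.numeric(seed)) %% m * 69621 + i * 1013904223) %% m)
}

rlnorm_trunc <- function(meanlog, sdlog, lo, hi) {
  for (try in 1:100) {
    x <- round(stats::rlnorm(1, meanlog, sdlog))
    if (x >= lo && x <= hi) return(as.integer(x))
  }
  as.integer(round(stats::runif(1, lo, hi)))
}

# uniform integer draw on [lo, hi], safe for degenerate ranges
rint <- function(lo, hi) as.integer(lo) + sample.int(hi - lo + 1L, 1L) - 1L

# rescue formulations: per-unit drug mg (dictionary carries the OME factor)
rescue_menu <- function() {
  tibble::tribble(
    ~drug_code, ~unit_mg, ~weight,
    "MOR-IR",   10,       0.30,
    "OXY-IR",    5,       0.30,
    "HYD-IR",    2,       0.15,
    "MOR-SOL",  10,       0.10,
    "MOR-SUP",  10,       0.05,
    "FEN-BUC",   0.1,     0.05,
    "FEN-SL",    0.1,     0.05
  )
}

#' Generate a synthetic claims bundle with ground truth
#'
#' See [simulation_config()] for the generating model. For every patient the
#' emitted prescriptions tile the true episode span exactly: internal
#' uncovered gaps never reach 30 days, any post-episode prescription starts
#' at least 30 uncovered days after the episode end, and doses are solved so
#' the episode mean daily OME equals the planted value.
#'
#' @param config A [simulation_config()].
#' @return List of class `synthetic_claims` with elements `bundle` (a
#'   `claims_bundle`) and `truth` (tibble: `patient_id`, `group`,
#'   `index_date`, `end_date`, `duration_days`, `mean_daily_ome`,
#'   `rescue_status`, plus one logical column per planted covariate).
#' @export
generate_bundle <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cal_lo <- config$calendar_start
  cal_hi <- config$calendar_end
  window <- as.integer(cal_hi - cal_lo)
  drugs <- default_drug_dictionary()
  base_codes <- c("MOR-SR", "OXY-SR", "FEN-TTS", "TAP-SR", "HYD-SR")
  base_w <- c(0.3, 0.3, 0.25, 0.05, 0.1)
  factor_of <- stats::setNames(drugs$ome_factor, drugs$drug_code)
  site_codes <- c("C34.9", "C50.9", "C16.9", "C18.9", "C61", "C25.9",
                  "C15.9", "C82.0", "C67.9", "C00.1")
  menu <- rescue_menu()
  covs <- config$covariates
  a1 <- config$true_intercepts[1]
  a2 <- config$true_intercepts[2]

  pat_rows <- vector("list", config$n_patients)
  dx_rows <- vector("list", config$n_patients)
  rx_rows <- vector("list", config$n_patients)
  truth_rows <- vector("list", config$n_patients)

  for (i in seq_len(config$n_patients)) {
    set.seed(patient_seed(config$seed, i))
    pid <- sprintf("P%06d", i)

    flags <- stats::rbinom(nrow(covs), 1, covs$prevalence)
    u_type <- stats::runif(1)
    if (u_type < config$excluded_not_calculable_frac) {
      group <- "excluded_dose_not_calculable"
      band <- "control"
    } else if (u_type < config$excluded_not_calculable_frac +
                 config$excluded_long_low_frac) {
      group <- "excluded_long_low_dose"
      band <- "long_low"
    } else {
      eta <- sum(covs$beta * flags)
      u <- stats::runif(1)
      group <- if (u < stats::plogis(a2 + eta)) "case_II"
               else if (u < stats::plogis(a1 + eta)) "case_I"
               else "control"
      band <- group
    }

    dm <- config$duration_model[[band]]
    band_lims <- switch(band,
                        control = c(1, 182),
                        case_I = c(183, 729),
                        case_II = c(730, window - 1200),
                        long_low = c(183, window - 1200))
    D <- rlnorm_trunc(dm[["meanlog"]], dm[["sdlog"]], band_lims[1],
                      band_lims[2])
    if (D + 34 + 365 > window || 730 + 365 > window)
      stop("infeasible config: episode does not fit the calendar window",
           call. = FALSE)

    sm <- config$dose_model[[band]]
    M <- switch(band,
                control = stats::rlnorm(1, sm[["meanlog"]], sm[["sdlog"]]),
                long_low = min(stats::rlnorm(1, sm[["meanlog"]],
                                             sm[["sdlog"]]), 119),
                120 + stats::rlnorm(1, sm[["meanlog"]], sm[["sdlog"]]))

    dx_lag <- rint(0, 365)
    needed <- max(730, D + 34)
    index_off <- rint(0, window - dx_lag - needed) + dx_lag
    index <- cal_lo + index_off
    eod <- min(index + needed + rint(0, 180), cal_hi)

    status <- if (group == "excluded_dose_not_calculable") "base_only" else {
      sp <- config$rescue_status_probs[[if (band %in% c("control", "case_I",
                                                        "case_II")) band
                                        else "control"]]
      c("rescue_only", "base_only", "base_and_rescue")[
        sample.int(3, 1, prob = sp)]
    }

    # tile [1, D] with prescriptions; internal uncovered gaps < 30 days
    seg_start <- integer(0); seg_len <- integer(0)
    pos <- 1L
    repeat {
      len <- min(rint(config$supply_range[1], config$supply_range[2]),
                 D - pos + 1L)
      seg_start <- c(seg_start, pos); seg_len <- c(seg_len, len)
      e <- pos + len - 1L
      if (e >= D) break
      gap <- if (config$gap_max > 0 &&
                   stats::runif(1) < config$gap_prob)
        rint(1, config$gap_max) else 0L
      gap <- min(gap, D - e - 1L)
      pos <- e + gap + 1L
    }
    covered <- sum(seg_len)

    carrier <- if (group == "excluded_dose_not_calculable") "MET-OR"
               else if (status == "rescue_only") "OXY-IR"
               else sample(base_codes, 1, prob = base_w)

    # rescue dispensings (on top of the carrier) for base_and_rescue
    r_code <- character(0); r_start <- integer(0); r_len <- integer(0)
    r_units <- integer(0); r_daily <- numeric(0)
    if (status == "base_and_rescue") {
      n_disp <- stats::rpois(1, config$rescue_rate * D) + 1L
      pick <- sample.int(nrow(menu), n_disp, replace = TRUE,
                         prob = menu$weight)
      day <- sample.int(D, n_disp, replace = TRUE)
      len <- pmin(sample.int(3, n_disp, replace = TRUE), D - day + 1L)
      uses <- sample.int(2, n_disp, replace = TRUE)
      r_code <- menu$drug_code[pick]
      r_start <- day; r_len <- len; r_units <- len * uses
      r_daily <- uses * menu$unit_mg[pick]
    }

    if (group == "excluded_dose_not_calculable") {
      carrier_daily <- 30
      true_mean <- NA_real_
    } else {
      fac <- unname(factor_of[r_code])
      conv <- !is.na(fac)
      rescue_ome <- sum(r_daily[conv] * fac[conv] * r_len[conv])
      target <- M * D
      if (rescue_ome > 0.8 * target) {
        scl <- 0.8 * target / rescue_ome
        r_daily[conv] <- r_daily[conv] * scl
        rescue_ome <- 0.8 * target
      }
      carrier_daily <- (target - rescue_ome) / covered /
        unname(factor_of[carrier])
      true_mean <- M
    }

    rx_p <- tibble::tibble(
      patient_id = pid,
      drug_code = c(rep(carrier, length(seg_start)), r_code),
      start_date = index + c(seg_start, r_start) - 1L,
      days_supplied = as.integer(c(seg_len, r_len)),
      daily_dose_mg = c(rep(carrier_daily, length(seg_start)), r_daily),
      n_units = as.integer(c(seg_len, r_units)))

    # post-episode opioid, separated by >= 30 uncovered days
    if (stats::runif(1) < config$post_episode_rx_prob) {
      post_start <- index + D + 29L + rint(1, 30)
      if (post_start + 13L <= eod) {
        rx_p <- dplyr::bind_rows(rx_p, tibble::tibble(
          patient_id = pid, drug_code = carrier, start_date = post_start,
          days_supplied = 14L, daily_dose_mg = max(carrier_daily, 1),
          n_units = 14L))
      }
    }

    # clinical records: cancer diagnosis, planted covariates, misc noise
    dx_code <- sample(site_codes, 1)
    rec_code <- dx_code
    rec_date <- index - dx_lag
    for (j in seq_len(nrow(covs))) {
      if (!flags[j]) next
      kind <- covs$kind[j]; code <- covs$code[j]
      if (kind == "dx") {
        rec_code <- c(rec_code, code)
        rec_date <- c(rec_date, index - rint(0, dx_lag))
      } else if (kind == "tx_pre") {
        rec_code <- c(rec_code, code)
        rec_date <- c(rec_date, max(index - rint(1, 200), cal_lo))
      } else if (kind == "tx_during") {
        rec_code <- c(rec_code, code)
        rec_date <- c(rec_date, index + rint(0, D - 1))
      } else if (kind == "rx_pre") {
        rx_p <- dplyr::bind_rows(rx_p, tibble::tibble(
          patient_id = pid, drug_code = code,
          start_date = max(index - rint(10, 300), cal_lo),
          days_supplied = 14L, daily_dose_mg = 1, n_units = 14L))
      } else if (kind == "rx_during") {
        rx_p <- dplyr::bind_rows(rx_p, tibble::tibble(
          patient_id = pid, drug_code = code,
          start_date = index + rint(0, D - 1),
          days_supplied = 7L, daily_dose_mg = 1, n_units = 7L))
      }
    }

    age <- min(max(round(stats::rnorm(1, 64, 12)), 20), 95)
    pat_rows[[i]] <- tibble::tibble(
      patient_id = pid,
      sex = if (stats::runif(1) < 0.6) "male" else "female",
      birth_year = as.integer(format(index, "%Y")) - as.integer(age),
      end_of_data = eod)
    dx_rows[[i]] <- tibble::tibble(patient_id = pid, icd10_code = rec_code,
                                   date = rec_date)
    rx_rows[[i]] <- rx_p
    tr <- tibble::tibble(patient_id = pid, group = group,
                         index_date = index, end_date = index + D - 1L,
                         duration_days = as.integer(D),
                         mean_daily_ome = true_mean,
                         rescue_status = status)
    for (j in seq_len(nrow(covs))) tr[[covs$name[j]]] <- flags[j] == 1
    truth_rows[[i]] <- tr
  }

  empty_pat <- tibble::tibble(patient_id = character(), sex = character(),
                              birth_year = integer(),
                              end_of_data = as.Date(character()))
  empty_dx <- tibble::tibble(patient_id = character(),
                             icd10_code = character(),
                             date = as.Date(character()))
  empty_rx <- tibble::tibble(patient_id = character(), drug_code = character(),
                             start_date = as.Date(character()),
                             days_supplied = integer(),
                             daily_dose_mg = numeric(), n_units = integer())
  bundle <- claims_bundle(
    patients = if (config$n_patients) dplyr::bind_rows(pat_rows) else empty_pat,
    diagnoses = if (config$n_patients) dplyr::bind_rows(dx_rows) else empty_dx,
    prescriptions = if (config$n_patients) dplyr::bind_rows(rx_rows)
                    else empty_rx,
    drugs = drugs)
  structure(list(bundle = bundle,
                 truth = if (config$n_patients) dplyr::bind_rows(truth_rows)
                         else tibble::tibble(patient_id = character(),
                                             group = character()),
                 config = config),
            class = "synthetic_claims")
}

#' Simulate covariates and an ordinal outcome from the cumulative-logit model
#'
#' Draws binary covariates and an outcome `Y` in `{0, 1, 2}` from
#' `P(Y >= k | x) = logistic(alpha_k + x'beta)`. Used for parameter-recovery
#' testing of the proportional-odds fitter.
#'
#' @param n Number of observations (>= 1).
#' @param true_betas Named numeric vector of log-odds per covariate.
#' @param true_intercepts Strictly decreasing cutpoints `(alpha_1, alpha_2)`.
#' @param seed Integer seed.
#' @param prevalence Bernoulli prevalence per covariate (recycled).
#' @return List: `x` (tibble of 0/1 covariates), `y` (integer vector),
#'   `params` (the generating values).
#' @export
generate_regression_dataset <- function(n, true_betas = c(x1 = log(2)),
                                        true_intercepts = c(-3, -4),
                                        seed = 1, prevalence = 0.5) {
  stopifnot(n >= 1)
  if (length(true_intercepts) != 2 || diff(true_intercepts) >= 0)
    stop("true_intercepts must be two strictly decreasing cutpoints",
         call. = FALSE)
  set.seed(seed)
  p <- length(true_betas)
  prevalence <- rep_len(prevalence, p)
  x <- matrix(stats::rbinom(n * p, 1, rep(prevalence, each = n)), n, p)
  colnames(x) <- if (is.null(names(true_betas)))
    paste0("x", seq_len(p)) else names(true_betas)
  eta <- drop(x %*% true_betas)
  u <- stats::runif(n)
  y <- ifelse(u < stats::plogis(true_intercepts[2] + eta), 2L,
              ifelse(u < stats::plogis(true_intercepts[1] + eta), 1L, 0L))
  list(x = tibble::as_tibble(as.data.frame(x)), y = y,
       params = list(true_betas = true_betas,
                     true_intercepts = true_intercepts,
                     prevalence = prevalence, seed = seed))
}
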