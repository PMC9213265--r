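# End-to-end orchestration: eligibility -> episodes -> cohort -> descriptive
# table -> variable selection -> proportional-odds regression -> rescue
# summary, with a patient-flow report.

#' Patient-flow report
#'
#' Attrition counts and group percentages. Group percentages use the
#' dose-calculable total as denominator and are rounded half-up to one
#' decimal, table style.
#'
#' @param n_eligible Patients meeting the eligibility criteria.
#' @param n_dose_calculable Of those, patients whose episode dose could be
#'   calculated.
#' @param n_control,n_case_I,n_case_II,n_excluded_long_low Group counts
#'   (must sum to `n_dose_calculable`).
#' @return Tibble: `step`, `n`, `pct` (of the dose-calculable total where
#'   applicable).
#' @export
flow_report <- function(n_eligible, n_dose_calculable, n_control, n_case_I,
                        n_case_II, n_excluded_long_low) {
  if (n_dose_calculable > n_eligible)
    stop("dose-calculable count exceeds eligible count", call. = FALSE)
  if (n_control + n_case_I + n_case_II + n_excluded_long_low !=
        n_dose_calculable)
    stop("group counts must sum to the dose-calculable total", call. = FALSE)
  tibble::tibble(
    step = c("eligible", "dose_calculable", "control", "case_I", "case_II",
             "excluded_long_low_dose"),
    n = c(n_eligible, n_dose_calculable, n_control, n_case_I, n_case_II,
          n_excluded_long_low),
    pct = c(NA, pct(n_dose_calculable, n_eligible),
            pct(n_control, n_dose_calculable),
            pct(n_case_I, n_dose_calculable),
            pct(n_case_II, n_dose_calculable),
            pct(n_excluded_long_low, n_dose_calculable)))
}

#' Run the full claims-analysis pipeline
#'
#' Composes the whole analysis on one bundle: eligibility selection, episode
#' construction under the persistence gap, OME dosing, ordered cohort
#' classification, covariate extraction, the descriptive comparison table
#' (Dunnett/Steel vs control), two-step variable selection, the
#' proportional-odds regression, and the rescue-medication summary. The run
#' is fully deterministic given the bundle.
#'
#' @param bundle A `claims_bundle`.
#' @param thresholds See [cohort_thresholds()].
#' @param selection A [selection_config()]; `NULL` skips selection and
#'   regression.
#' @param regress Fit the proportional-odds model on the selected variables
#'   (requires all three groups present).
#' @return List of class `cohort_run`: `eligible`, `episodes` (with
#'   `group`), `flow`, `covariates`, `table1`, `selection`, `fit`,
#'   `rescue`, and `log` (one line per stage with row counts).
#' @export
run_pipeline <- function(bundle, thresholds = cohort_thresholds(),
                         selection = selection_config(), regress = TRUE) {
  stopifnot(inherits(bundle, "claims_bundle"))
  log <- character()
  stage <- function(name, nin, nout) {
    log <<- c(log, sprintf("%s: %d -> %d", name, nin, nout))
  }

  eligible <- select_eligible(bundle)
  stage("select_eligible", nrow(bundle$patients), nrow(eligible))

  episodes <- build_episodes(bundle, eligible,
                             gap_days = thresholds$gap_days)
  episodes$group <- classify_episode(episodes$duration_days,
                                     episodes$mean_daily_ome,
                                     episodes$dose_calculable, thresholds)
  stage("build_episodes", nrow(eligible), nrow(episodes))

  counts <- table(episodes$group)
  flow <- flow_report(
    n_eligible = nrow(episodes),
    n_dose_calculable = sum(episodes$dose_calculable),
    n_control = counts[["control"]],
    n_case_I = counts[["case_I"]],
    n_case_II = counts[["case_II"]],
    n_excluded_long_low = counts[["excluded_long_low_dose"]])

  covariates <- extract_covariates(bundle, episodes, thresholds, eligible)
  stage("extract_covariates", nrow(episodes), nrow(covariates))

  analysed <- covariates[covariates$group %in%
                           c("control", "case_I", "case_II"), ]
  table1 <- descriptive_table(covariates)
  stage("descriptive_table", nrow(analysed), nrow(table1))

  sel <- NULL
  fit <- NULL
  if (!is.null(selection)) {
    sel <- select_variables(table1, selection)
    stage("select_variables", nrow(table1), length(sel$selected))
    if (regress && length(sel$selected) &&
          all(c("control", "case_I", "case_II") %in% analysed$group)) {
      y <- as.integer(factor(as.character(analysed$group),
                             levels = c("control", "case_I", "case_II"))) - 1L
      x <- analysed[, sel$selected, drop = FALSE]
      keep <- vapply(x, function(col) stats::var(as.numeric(col)) > 0,
                     logical(1))
      fit <- fit_proportional_odds(x[, keep, drop = FALSE], y)
      stage("fit_proportional_odds", nrow(analysed), sum(keep))
    }
  }

  rescue <- rescue_summary(bundle, episodes, thresholds)
  stage("rescue_summary", nrow(episodes), nrow(rescue$per_patient))

  structure(list(eligible = eligible, episodes = episodes, flow = flow,
                 covariates = covariates, table1 = table1, selection = sel,
                 fit = fit, rescue = rescue, thresholds = thresholds,
                 log = log),
            class = "cohort_run")
}

#' @export
print.cohort_run <- function(x, ...) {
  cat("<cohort_run>\n")
  cat("  flow:\n")
  print(as.data.frame(x$flow), row.names = FALSE)
  if (!is.null(x$fit)) {
    cat("  regression:\n")
    print(x$fit)
  }
  invisible(x)
}
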