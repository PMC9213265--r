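# Domain model for claims-style tabular data: patients, clinical records
# (diagnoses + treatment procedures), prescriptions, and the drug dictionary.

#' Drug roles recognised by the dictionary
#'
#' `base_opioid` and `rescue_opioid` together define the opioid exposure used
#' for episode construction; the remaining analgesic classes drive covariate
#' flags; `other` covers everything else (including injectable opioid
#' preparations, which are deliberately invisible to episode construction).
#'
#' @return Character vector of valid `role` values.
#' @export
drug_roles <- function() {
  c("base_opioid", "rescue_opioid", "non_opioid_analgesic",
    "TCA", "SSRI", "SNRI", "gabapentinoid", "antiepileptic",
    "antiarrhythmic", "NMDA_antagonist", "central_muscle_relaxant", "other")
}

opioid_roles <- function() c("base_opioid", "rescue_opioid")

analgesic_roles <- function() {
  c("non_opioid_analgesic", "TCA", "SSRI", "SNRI", "gabapentinoid",
    "antiepileptic", "antiarrhythmic", "NMDA_antagonist",
    "central_muscle_relaxant")
}

treatment_names <- function() {
  c("operative", "radiotherapy", "chemotherapy", "nerve_block")
}

icd_pattern <- function() "^[A-Z][0-9]{2}([.][0-9]+)?$"

# "C00".."C14" style expansion for prefix ranges
icd_range <- function(letter, from, to) sprintf("%s%02d", letter, from:to)

#' Default ICD-10 / treatment code map
#'
#' Maps ICD-10 code prefixes to cancer-site, metastasis and comorbidity
#' covariates, and treatment-record tokens to the four cancer-treatment
#' modalities. The site blocks follow the standard ICD-10 chapter II
#' groupings; the comorbidity prefixes are a declared default and can be
#' overridden wholesale (the map is plain data).
#'
#' @return A named list with elements `cancer_codes` (prefixes defining a
#'   cancer diagnosis for eligibility), `cancer_sites`, `metastasis`,
#'   `comorbidities` (each name -> character vector of ICD-10 prefixes) and
#'   `treatments` (treatment name -> record token).
#' @export
default_code_map <- function() {
  list(
    cancer_codes = c(icd_range("C", 0, 97), icd_range("D", 0, 9)),
    cancer_sites = list(
      lip_oral_pharynx    = icd_range("C", 0, 14),
      esophagus           = "C15",
      stomach             = "C16",
      small_intestine     = "C17",
      colorectal_anal     = icd_range("C", 18, 21),
      liver_bile_ducts    = "C22",
      gallbladder_biliary = icd_range("C", 23, 24),
      pancreas            = "C25",
      other_digestive     = "C26",
      respiratory         = icd_range("C", 30, 39),
      bone_cartilage      = icd_range("C", 40, 41),
      melanoma_skin       = icd_range("C", 43, 44),
      mesothelial_soft    = icd_range("C", 45, 49),
      breast              = "C50",
      female_genital      = icd_range("C", 51, 58),
      male_genital        = icd_range("C", 60, 63),
      urinary             = icd_range("C", 64, 68),
      eye_brain_cns       = icd_range("C", 69, 72),
      thyroid_endocrine   = icd_range("C", 73, 75),
      ill_defined_sites   = c("C76", "C80"),
      lymphoid_hematopoietic = icd_range("C", 81, 96),
      multiple_sites      = "C97",
      in_situ             = icd_range("D", 0, 9)
    ),
    metastasis = list(
      bone_metastasis     = "C79.5",
      distant_metastasis  = icd_range("C", 77, 79)
    ),
    comorbidities = list(
      herpes_zoster       = "B02",
      osteoarthritis_knee = "M17",
      back_pain           = "M54",
      spinal_stenosis     = "M48.0",
      spondylosis         = "M47",
      other_bone_disorder = "M89",
      alcohol_dependence  = "F10",
      psychoactive_dependence = "F19",
      schizophrenia       = icd_range("F", 20, 29),
      mood_disorders      = icd_range("F", 30, 39),
      anxiety             = icd_range("F", 40, 48),
      sleep_disorders     = "G47",
      delirium            = "F05",
      dementia            = icd_range("F", 0, 3),
      diabetes            = icd_range("E", 10, 14),
      hepatic_disorder    = icd_range("K", 70, 77),
      chronic_kidney_disease = "N18"
    ),
    treatments = list(
      operative    = "OPER",
      radiotherapy = "RADI",
      chemotherapy = "CHEM",
      nerve_block  = "NBLK"
    )
  )
}

#' Default drug dictionary
#'
#' A compact dictionary covering the oral / transdermal opioids of the study
#' definition (morphine, oxycodone, fentanyl, tapentadol, hydromorphone,
#' methadone), the immediate-release rescue formulations, one representative
#' per non-opioid analgesic class, and an injectable opioid (role `other`,
#' excluded from exposure). `ome_factor` is mg oral morphine per mg drug;
#' `NA` marks drugs that cannot be converted (fentanyl sublingual/buccal
#' tablets, methadone). Oral morphine is the reference, factor exactly 1.
#'
#' @return A tibble with columns `drug_code`, `name`, `role`, `ome_factor`.
#' @export
default_drug_dictionary <- function() {
  tibble::tribble(
    ~drug_code, ~name,                                          ~role,                     ~ome_factor,
    "MOR-SR",   "morphine sustained-release tablet",            "base_opioid",             1.0,
    "MOR-IR",   "morphine hydrochloride immediate-release tablet", "rescue_opioid",        1.0,
    "MOR-SOL",  "morphine oral solution",                       "rescue_opioid",           1.0,
    "MOR-SUP",  "morphine suppository",                         "rescue_opioid",           1.5,
    "OXY-SR",   "oxycodone sustained-release tablet",           "base_opioid",             1.5,
    "OXY-IR",   "oxycodone immediate-release powder",           "rescue_opioid",           1.5,
    "FEN-TTS",  "fentanyl transdermal patch",                   "base_opioid",             100,
    "FEN-SL",   "fentanyl sublingual tablet",                   "rescue_opioid",           NA,
    "FEN-BUC",  "fentanyl buccal tablet",                       "rescue_opioid",           NA,
    "TAP-SR",   "tapentadol sustained-release tablet",          "base_opioid",             0.3,
    "HYD-SR",   "hydromorphone sustained-release tablet",       "base_opioid",             5.0,
    "HYD-IR",   "hydromorphone immediate-release tablet",       "rescue_opioid",           5.0,
    "MET-OR",   "methadone tablet",                             "base_opioid",             NA,
    "FEN-INJ",  "fentanyl injection",                           "other",                   NA,
    "NSAID",    "loxoprofen tablet",                            "non_opioid_analgesic",    NA,
    "ACET",     "acetaminophen tablet",                         "non_opioid_analgesic",    NA,
    "TCA-1",    "amitriptyline tablet",                         "TCA",                     NA,
    "SSRI-1",   "sertraline tablet",                            "SSRI",                    NA,
    "SNRI-1",   "duloxetine capsule",                           "SNRI",                    NA,
    "GABA-1",   "pregabalin capsule",                           "gabapentinoid",           NA,
    "AED-1",    "valproate tablet",                             "antiepileptic",           NA,
    "AAR-1",    "mexiletine capsule",                           "antiarrhythmic",          NA,
    "NMDA-1",   "ifenprodil tablet",                            "NMDA_antagonist",         NA,
    "CMR-1",    "eperisone tablet",                             "central_muscle_relaxant", NA
  )
}

as_iso_date <- function(x, what, file = NULL) {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(out) & !is.na(x) & as.character(x) != "")
  if (length(bad)) {
    stop(sprintf("malformed date in %s%s at row %d: '%s'",
                 what, if (is.null(file)) "" else paste0(" (", file, ")"),
                 bad[1], as.character(x)[bad[1]]), call. = FALSE)
  }
  out
}

#' Assemble and validate a claims bundle
#'
#' @param patients Tibble: `patient_id`, `sex` ("male"/"female"),
#'   `birth_year`, `end_of_data` (date of death or last record).
#' @param diagnoses Tibble of clinical records: `patient_id`, `icd10_code`
#'   (ICD-10 code or a treatment token declared in `code_map$treatments`),
#'   `date`.
#' @param prescriptions Tibble: `patient_id`, `drug_code`, `start_date`,
#'   `days_supplied` (>= 1; coverage is the closed interval
#'   `[start_date, start_date + days_supplied - 1]`), `daily_dose_mg`
#'   (the drug's own active-ingredient mg/day, not yet morphine-converted),
#'   `n_units` (dispensed dose units, used for rescue counting).
#' @param drugs Drug dictionary, see [default_drug_dictionary()].
#' @param code_map Code map, see [default_code_map()].
#' @return A validated object of class `claims_bundle`.
#' @export
claims_bundle <- function(patients, diagnoses, prescriptions,
                          drugs = default_drug_dictionary(),
                          code_map = default_code_map()) {
  patients <- tibble::as_tibble(patients)
  diagnoses <- tibble::as_tibble(diagnoses)
  prescriptions <- tibble::as_tibble(prescriptions)
  drugs <- tibble::as_tibble(drugs)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("%s is missing column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  need(patients, c("patient_id", "sex", "birth_year", "end_of_data"), "patients")
  need(diagnoses, c("patient_id", "icd10_code", "date"), "diagnoses")
  need(prescriptions, c("patient_id", "drug_code", "start_date",
                        "days_supplied", "daily_dose_mg", "n_units"),
       "prescriptions")
  need(drugs, c("drug_code", "name", "role", "ome_factor"), "drugs")

  patients$patient_id <- as.character(patients$patient_id)
  patients$end_of_data <- as_iso_date(patients$end_of_data, "patients$end_of_data")
  patients$birth_year <- as.integer(patients$birth_year)
  diagnoses$patient_id <- as.character(diagnoses$patient_id)
  diagnoses$date <- as_iso_date(diagnoses$date, "diagnoses$date")
  prescriptions$patient_id <- as.character(prescriptions$patient_id)
  prescriptions$drug_code <- as.character(prescriptions$drug_code)
  prescriptions$start_date <- as_iso_date(prescriptions$start_date,
                                          "prescriptions$start_date")
  prescriptions$days_supplied <- as.integer(prescriptions$days_supplied)
  prescriptions$n_units <- as.integer(prescriptions$n_units)
  prescriptions$daily_dose_mg <- as.numeric(prescriptions$daily_dose_mg)

  if (anyDuplicated(patients$patient_id))
    stop("duplicate patient_id in patients table", call. = FALSE)
  if (nrow(patients) && !all(patients$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'", call. = FALSE)

  tokens <- unlist(code_map$treatments, use.names = FALSE)
  ok_code <- grepl(icd_pattern(), diagnoses$icd10_code) |
    diagnoses$icd10_code %in% tokens
  if (nrow(diagnoses) && !all(ok_code))
    stop(sprintf("invalid record code at diagnoses row %d: '%s'",
                 which(!ok_code)[1], diagnoses$icd10_code[which(!ok_code)[1]]),
         call. = FALSE)

  if (nrow(prescriptions)) {
    if (any(prescriptions$days_supplied < 1L))
      stop("days_supplied must be >= 1", call. = FALSE)
    if (any(prescriptions$daily_dose_mg < 0))
      stop("daily_dose_mg must be non-negative", call. = FALSE)
    if (any(prescriptions$n_units < 1L))
      stop("n_units must be >= 1", call. = FALSE)
  }
  if (nrow(drugs) && !all(drugs$role %in% drug_roles()))
    stop("unknown drug role: ",
         paste(setdiff(drugs$role, drug_roles()), collapse = ", "),
         call. = FALSE)
  if (any(!is.na(drugs$ome_factor) & drugs$ome_factor < 0))
    stop("ome_factor must be non-negative", call. = FALSE)

  fk <- function(keys, universe, what) {
    bad <- which(!(keys %in% universe))
    if (length(bad))
      stop(sprintf("unresolvable %s at row %d: '%s'", what, bad[1],
                   keys[bad[1]]), call. = FALSE)
  }
  fk(diagnoses$patient_id, patients$patient_id, "patient_id in diagnoses")
  fk(prescriptions$patient_id, patients$patient_id, "patient_id in prescriptions")
  fk(prescriptions$drug_code, drugs$drug_code, "drug_code in prescriptions")

  structure(
    list(patients = patients, diagnoses = diagnoses,
         prescriptions = prescriptions, drugs = drugs, code_map = code_map),
    class = "claims_bundle")
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle>\n",
      sprintf("  patients:      %d\n", nrow(x$patients)),
      sprintf("  records:       %d\n", nrow(x$diagnoses)),
      sprintf("  prescriptions: %d\n", nrow(x$prescriptions)),
      sprintf("  drugs:         %d\n", nrow(x$drugs)), sep = "")
  invisible(x)
}

bundle_sort <- function(b) {
  b$patients <- dplyr::arrange(b$patients, .data$patient_id)
  b$diagnoses <- dplyr::arrange(b$diagnoses, .data$patient_id, .data$date,
                                .data$icd10_code)
  b$prescriptions <- dplyr::arrange(b$prescriptions, .data$patient_id,
                                    .data$start_date, .data$drug_code,
                                    .data$days_supplied)
  b$drugs <- dplyr::arrange(b$drugs, .data$drug_code)
  b
}

#' Read a claims bundle from a directory of CSV files
#'
#' Expects `patients.csv`, `diagnoses.csv`, `prescriptions.csv`, `drugs.csv`
#' (UTF-8, comma-separated, header row, ISO-8601 dates). A blank `ome_factor`
#' in `drugs.csv` is the reserved not-convertible token. If the directory
#' contains `code_map.json` it overrides the default code map.
#'
#' Row order never affects downstream results: tables are canonically sorted
#' on read.
#'
#' @param directory Path containing the four CSV files.
#' @param code_map Optional code map; default read from `code_map.json` if
#'   present, else [default_code_map()].
#' @return A `claims_bundle`.
#' @export
read_bundle <- function(directory, code_map = NULL) {
  path <- function(f) {
    p <- file.path(directory, f)
    if (!file.exists(p)) stop("missing file: ", f, call. = FALSE)
    p
  }
  rd <- function(f, types) {
    readr::read_csv(path(f), col_types = types, progress = FALSE)
  }
  patients <- rd("patients.csv", readr::cols(
    patient_id = readr::col_character(), sex = readr::col_character(),
    birth_year = readr::col_integer(), end_of_data = readr::col_date()))
  diagnoses <- rd("diagnoses.csv", readr::cols(
    patient_id = readr::col_character(), icd10_code = readr::col_character(),
    date = readr::col_date()))
  prescriptions <- rd("prescriptions.csv", readr::cols(
    patient_id = readr::col_character(), drug_code = readr::col_character(),
    start_date = readr::col_date(), days_supplied = readr::col_integer(),
    daily_dose_mg = readr::col_double(), n_units = readr::col_integer()))
  drugs <- rd("drugs.csv", readr::cols(
    drug_code = readr::col_character(), name = readr::col_character(),
    role = readr::col_character(), ome_factor = readr::col_double()))

  if (is.null(code_map)) {
    cm_path <- file.path(directory, "code_map.json")
    code_map <- if (file.exists(cm_path)) read_code_map(cm_path)
                else default_code_map()
  }
  bundle_sort(claims_bundle(patients, diagnoses, prescriptions, drugs,
                            code_map))
}

#' Write a claims bundle to a directory of CSV files
#'
#' Inverse of [read_bundle()]: `read_bundle(write_bundle(b, d))` returns a
#' bundle equal to `b` up to canonical row order. The not-convertible
#' `ome_factor` sentinel is serialized as a blank field.
#'
#' @param bundle A `claims_bundle`.
#' @param directory Output directory (created if absent).
#' @return `directory`, invisibly.
#' @export
write_bundle <- function(bundle, directory) {
  stopifnot(inherits(bundle, "claims_bundle"))
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  wr <- function(df, f) readr::write_csv(df, file.path(directory, f), na = "")
  wr(bundle$patients, "patients.csv")
  wr(bundle$diagnoses, "diagnoses.csv")
  wr(bundle$prescriptions, "prescriptions.csv")
  wr(bundle$drugs, "drugs.csv")
  jsonlite::write_json(bundle$code_map, file.path(directory, "code_map.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(directory)
}

#' Read a code map from JSON
#'
#' @param path JSON file with the structure of [default_code_map()].
#' @return A code-map list.
#' @export
read_code_map <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (part in c("cancer_sites", "metastasis", "comorbidities", "treatments"))
    raw[[part]] <- as.list(raw[[part]])
  raw
}

# prefix matching on ICD-10 codes, dot-insensitive: "C79.5" matches "C79.51"
# and prefix "C79" matches "C79.5"
matches_prefix <- function(codes, prefixes) {
  if (!length(codes)) return(logical(0))
  nc <- gsub(".", "", codes, fixed = TRUE)
  np <- gsub(".", "", prefixes, fixed = TRUE)
  out <- rep(FALSE, length(nc))
  for (p in np) out <- out | startsWith(nc, p)
  out
}
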