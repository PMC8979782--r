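#' Default medication-to-comorbidity mapping
#'
#' A small, documented stand-in for a medication-based comorbidity index
#' (Rx-Risk style): each row maps an ATC code prefix to a comorbidity
#' category. It is deliberately compact and user-replaceable — pass your own
#' table with the same columns to [claims_config()]. Categories
#' `hypertension`, `chf`, `diabetes`, `copd` and `statin` are identified
#' individually by the covariate derivation; the comorbidity count excludes
#' them.
#'
#' @return data.frame with columns `atc_prefix`, `category`.
#' @export
default_comorbidity_map <- function() {
  data.frame(
    atc_prefix = c("C02", "C03", "C07", "C08", "C09",   # antihypertensives
                   "C01AA",                              # cardiac glycosides
                   "A10",                                # antidiabetics
                   "C10AA",                              # statins
                   "R03BB",                              # inhaled anticholinergics
                   "H02AB",                              # systemic glucocorticoids
                   "A02BC",                              # proton pump inhibitors
                   "N06A",                               # antidepressants
                   "M05BA",                              # bisphosphonates
                   "M04A",                               # antigout
                   "N03A"),                              # antiepileptics
    category = c(rep("hypertension", 5), "chf", "diabetes", "statin", "copd",
                 "glucocorticoid", "gord", "depression", "osteoporosis",
                 "gout", "epilepsy"),
    stringsAsFactors = FALSE
  )
}

#' Analysis configuration: code lists, windows and supply rules
#'
#' Bundles every configurable definition used by the cohort builder and the
#' exposure reconstruction, with defaults matching the COPD/paracetamol
#' analysis the package implements: study period 2011-01-01 to 2015-09-30,
#' eligibility ages 45-100, COPD evidence via inhaled anticholinergic
#' dispensings (ATC `R03BB`, excluding `R03BB01`) or hospital episodes coded
#' J43*/J440/J441/J448/J449 in any position, outcome restricted to
#' primary-position codes from the same list, paracetamol `N02BE01`, statins
#' `C10AA`, systemic glucocorticoids `H02AB`.
#'
#' @param study_start,study_end study period (Dates).
#' @param age_range eligible age range (completed years) at study start.
#' @param lookback_days length of the baseline covariate/evidence window.
#' @param washout_days paracetamol-free window required before study start.
#' @param copd_icd_prefixes ICD-10 prefixes (dots stripped) defining COPD.
#' @param copd_atc_prefix,copd_atc_exclude ATC evidence rule for COPD.
#' @param paracetamol_atc,statin_atc_prefix,glucocorticoid_atc_prefix ATC codes.
#' @param comorbidity_map see [default_comorbidity_map()].
#' @param tablets_per_day,dose_per_day supply-duration and daily-dose rules,
#'   see [days_of_supply()] and [build_daily_series()].
#' @param statin_tablets_per_day tablets/day assumed for statin supply.
#' @return list of class `claims_config`.
#' @export
claims_config <- function(study_start = as.Date("2011-01-01"),
                          study_end = as.Date("2015-09-30"),
                          age_range = c(45, 100),
                          lookback_days = 365L,
                          washout_days = 183L,
                          copd_icd_prefixes = c("J43", "J440", "J441", "J448", "J449"),
                          copd_atc_prefix = "R03BB",
                          copd_atc_exclude = "R03BB01",
                          paracetamol_atc = "N02BE01",
                          statin_atc_prefix = "C10AA",
                          glucocorticoid_atc_prefix = "H02AB",
                          comorbidity_map = default_comorbidity_map(),
                          tablets_per_day = c("500" = 8, "665" = 6),
                          dose_per_day = c("500" = 4.0, "665" = 3.99),
                          statin_tablets_per_day = 1) {
  stopifnot(as.Date(study_start) < as.Date(study_end),
            length(age_range) == 2, age_range[1] <= age_range[2],
            all(c("atc_prefix", "category") %in% names(comorbidity_map)))
  structure(list(
    study_start = as.Date(study_start), study_end = as.Date(study_end),
    age_range = age_range, lookback_days = as.integer(lookback_days),
    washout_days = as.integer(washout_days),
    copd_icd_prefixes = copd_icd_prefixes,
    copd_atc_prefix = copd_atc_prefix, copd_atc_exclude = copd_atc_exclude,
    paracetamol_atc = paracetamol_atc,
    statin_atc_prefix = statin_atc_prefix,
    glucocorticoid_atc_prefix = glucocorticoid_atc_prefix,
    comorbidity_map = comorbidity_map,
    tablets_per_day = tablets_per_day, dose_per_day = dose_per_day,
    statin_tablets_per_day = statin_tablets_per_day
  ), class = "claims_config")
}

# -- small code-matching helpers ---------------------------------------------

# prefix match on ICD codes after dot-stripping
icd_matches <- function(codes, prefixes) {
  codes <- gsub(".", "", toupper(as.character(codes)), fixed = TRUE)
  Reduce(`|`, lapply(prefixes, function(p) startsWith(codes, p)),
         rep(FALSE, length(codes)))
}

atc_matches <- function(codes, prefix, exclude = NULL) {
  codes <- toupper(as.character(codes))
  hit <- startsWith(codes, toupper(prefix))
  if (!is.null(exclude)) hit <- hit & !startsWith(codes, toupper(exclude))
  hit
}

# age in completed years at a reference date
age_at <- function(dob, ref) {
  dob <- as.Date(dob); ref <- as.Date(ref)
  dobl <- as.POSIXlt(dob); refl <- as.POSIXlt(ref)
  yrs <- refl$year - dobl$year
  before <- (refl$mon < dobl$mon) | (refl$mon == dobl$mon & refl$mday < dobl$mday)
  yrs - as.integer(before)
}
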