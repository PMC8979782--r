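#' Eligibility cascade for one patient
#'
#' Applies the new-user eligibility gates at the study start date: age within
#' range, full entitlement throughout the prior 12 months, evidence of COPD in
#' the prior 12 months (qualifying ATC dispensing, or a hospital episode with
#' a qualifying ICD code in *any* position), no paracetamol dispensed in the
#' prior washout window, not in residential aged care at study start, at least
#' one paracetamol dispensing during the study period (treatment initiation),
#' and more than one day of follow-up from initiation. Every failed gate is
#' reported, so exclusion counts reconcile with the input.
#'
#' @param patient one-row data.frame with columns `patient_id`,
#'   `date_of_birth`, `sex`, `death_date`, `rac_entry_date`,
#'   `full_entitlement_start` (dates may be `NA`).
#' @param dispensings,episodes this patient's claims rows (see
#'   [build_cohort()] for schemas).
#' @param config a [claims_config()].
#' @return list with `eligible` (logical) and `reasons` (character vector of
#'   machine-readable gate names, empty when eligible).
#' @export
assess_eligibility <- function(patient, dispensings, episodes, config = claims_config()) {
  ss <- config$study_start
  if (is.na(patient$date_of_birth))
    stop("unusable record: missing date of birth for patient ",
         patient$patient_id, call. = FALSE)
  reasons <- character(0)
  age <- age_at(patient$date_of_birth, ss)
  if (age < config$age_range[1] || age > config$age_range[2])
    reasons <- c(reasons, "age-range")
  fe <- as.Date(patient$full_entitlement_start)
  if (is.na(fe) || fe > ss - config$lookback_days)
    reasons <- c(reasons, "entitlement")

  d_date <- as.Date(dispensings$supply_date)
  e_date <- as.Date(episodes$admission_date)
  lb <- d_date >= ss - config$lookback_days & d_date < ss
  copd_rx <- any(lb & atc_matches(dispensings$atc_code, config$copd_atc_prefix,
                                  config$copd_atc_exclude))
  copd_hosp <- any(e_date >= ss - config$lookback_days & e_date < ss &
                     icd_matches(episodes$diagnosis_code, config$copd_icd_prefixes))
  if (!copd_rx && !copd_hosp) reasons <- c(reasons, "no-copd-evidence")

  washout <- d_date >= ss - config$washout_days & d_date < ss &
    atc_matches(dispensings$atc_code, config$paracetamol_atc)
  if (any(washout)) reasons <- c(reasons, "prior-paracetamol")

  rac <- as.Date(patient$rac_entry_date)
  if (!is.na(rac) && rac <= ss) reasons <- c(reasons, "in-rac")

  in_study <- d_date >= ss & d_date <= config$study_end &
    atc_matches(dispensings$atc_code, config$paracetamol_atc)
  if (!any(in_study)) {
    reasons <- c(reasons, "no-initiation")
  } else {
    entry <- min(d_date[in_study])
    end <- suppressWarnings(min(c(as.Date(patient$death_date), rac,
                                  config$study_end), na.rm = TRUE))
    if (as.integer(end - entry) <= 1L) reasons <- c(reasons, "short-follow-up")
  }
  list(eligible = length(reasons) == 0L, reasons = reasons)
}

#' Cohort entry date: first in-study paracetamol dispensing
#'
#' Follow-up starts at treatment initiation (the first qualifying dispensing
#' on or after study start), which avoids immortal time between study start
#' and first exposure.
#'
#' @inheritParams assess_eligibility
#' @return a Date.
#' @export
determine_entry <- function(dispensings, config = claims_config()) {
  d_date <- as.Date(dispensings$supply_date)
  hit <- d_date >= config$study_start & d_date <= config$study_end &
    atc_matches(dispensings$atc_code, config$paracetamol_atc)
  if (!any(hit))
    stop("no in-study paracetamol dispensing; entry is undefined", call. = FALSE)
  min(d_date[hit])
}

#' Outcome and censoring for one cohort member
#'
#' The outcome is the first post-entry hospital episode whose *primary*
#' diagnosis code matches the COPD list; secondary-position matches qualify a
#' patient for cohort inclusion but never count as an outcome. Otherwise the
#' member is censored at the earliest of death, residential-aged-care entry
#' and study end.
#'
#' @param entry cohort entry date.
#' @inheritParams assess_eligibility
#' @return list with `event` (logical), `end_date`, `censor_reason`
#'   (`"event"`, `"death"`, `"rac"` or `"study-end"`).
#' @export
define_outcome <- function(patient, episodes, entry, config = claims_config()) {
  e_date <- as.Date(episodes$admission_date)
  prim <- episodes$position == "primary" &
    icd_matches(episodes$diagnosis_code, config$copd_icd_prefixes) &
    e_date > as.Date(entry)
  censor <- suppressWarnings(min(c(as.Date(patient$death_date),
                                   as.Date(patient$rac_entry_date),
                                   config$study_end), na.rm = TRUE))
  reasons <- c("death", "rac", "study-end")
  which_c <- which.min(c(as.Date(patient$death_date), as.Date(patient$rac_entry_date),
                         config$study_end))
  if (any(prim) && min(e_date[prim]) <= censor) {
    list(event = TRUE, end_date = min(e_date[prim]), censor_reason = "event")
  } else {
    list(event = FALSE, end_date = censor, censor_reason = reasons[which_c])
  }
}

#' Baseline disease-severity stratum
#'
#' `high` iff the patient had any COPD hospitalization (any code position) or
#' any systemic glucocorticoid dispensing in the 12 months before study start.
#'
#' @inheritParams assess_eligibility
#' @return `"high"` or `"low"`.
#' @export
classify_stratum <- function(dispensings, episodes, config = claims_config()) {
  ss <- config$study_start
  d_date <- as.Date(dispensings$supply_date)
  e_date <- as.Date(episodes$admission_date)
  gluco <- any(d_date >= ss - config$lookback_days & d_date < ss &
                 atc_matches(dispensings$atc_code, config$glucocorticoid_atc_prefix))
  hosp <- any(e_date >= ss - config$lookback_days & e_date < ss &
                icd_matches(episodes$diagnosis_code, config$copd_icd_prefixes))
  if (gluco || hosp) "high" else "low"
}

#' Baseline covariates from pre-entry dispensing claims
#'
#' Maps dispensings in the 12 months before cohort entry through the
#' configured medication-to-comorbidity table (ATC-prefix match). Returns the
#' three named comorbidity indicators, and a comorbidity count of the distinct
#' remaining categories (excluding hypertension, CHF, diabetes, the indication
#' itself and statins, which enter the model separately).
#'
#' @param entry cohort entry date.
#' @inheritParams assess_eligibility
#' @return list with `hypertension`, `chf`, `diabetes` (logicals) and
#'   `comorbidity_count` (integer).
#' @export
derive_covariates <- function(dispensings, entry, config = claims_config()) {
  entry <- as.Date(entry)
  d_date <- as.Date(dispensings$supply_date)
  win <- d_date >= entry - config$lookback_days & d_date < entry
  codes <- toupper(as.character(dispensings$atc_code[win]))
  map <- config$comorbidity_map
  cats <- character(0)
  if (length(codes)) {
    hit <- lapply(seq_len(nrow(map)), function(i)
      startsWith(codes, toupper(map$atc_prefix[i])))
    cats <- unique(map$category[vapply(hit, any, logical(1))])
  }
  excl <- c("hypertension", "chf", "diabetes", "copd", "statin")
  list(hypertension = "hypertension" %in% cats,
       chf = "chf" %in% cats,
       diabetes = "diabetes" %in% cats,
       comorbidity_count = length(setdiff(cats, excl)))
}

#' Build the analysis cohort from claims tables
#'
#' Runs the eligibility cascade over all patients, determines entry, outcome,
#' censoring, stratum and baseline covariates for the eligible, and
#' reconstructs each member's daily paracetamol dose series and daily binary
#' statin series over follow-up.
#'
#' @param patients data.frame: `patient_id`, `date_of_birth`, `sex`
#'   (`"F"`/`"M"`), `death_date`, `rac_entry_date`, `full_entitlement_start`,
#'   optionally `health_services_12m`.
#' @param dispensings data.frame: `patient_id`, `supply_date`, `atc_code`,
#'   `strength_mg`, `quantity`.
#' @param episodes data.frame: `patient_id`, `admission_date`,
#'   `diagnosis_code`, `position` (`"primary"`/`"secondary"`).
#' @param config a [claims_config()].
#' @return list of class `claims_cohort`:
#'   `members` (data.frame: id, entry/end dates, `futime` in days, `event`,
#'   `stratum`, covariates), `exposure` and `statin` (named lists of
#'   [build_daily_series()] objects aligned at entry), and `exclusions`
#'   (data.frame `patient_id`, `reason`; one row per failed gate).
#' @export
build_cohort <- function(patients, dispensings, episodes, config = claims_config()) {
  patients <- as.data.frame(patients)
  dispensings <- as.data.frame(dispensings)
  episodes <- as.data.frame(episodes)
  n <- nrow(patients)
  ss <- as.integer(config$study_start)
  se <- as.integer(config$study_end)
  lb <- config$lookback_days
  wo <- config$washout_days

  pid <- as.character(patients$patient_id)
  if (anyDuplicated(pid)) stop("duplicated patient ids", call. = FALSE)
  if (any(is.na(patients$date_of_birth)))
    stop("unusable record: missing date of birth for patient ",
         pid[which(is.na(patients$date_of_birth))[1]], call. = FALSE)
  d_pid <- as.character(dispensings$patient_id)
  e_pid <- as.character(episodes$patient_id)
  d_day <- as.integer(as.Date(dispensings$supply_date))
  e_day <- as.integer(as.Date(episodes$admission_date))
  d_atc <- toupper(as.character(dispensings$atc_code))
  e_code <- gsub(".", "", toupper(as.character(episodes$diagnosis_code)),
                 fixed = TRUE)
  e_prim <- as.character(episodes$position) == "primary"
  pf <- factor(d_pid, levels = pid)
  ef <- factor(e_pid, levels = pid)
  any_d <- function(mask) {
    v <- tapply(mask, pf, any)
    ifelse(is.na(v), FALSE, v)
  }
  any_e <- function(mask) {
    v <- tapply(mask, ef, any)
    ifelse(is.na(v), FALSE, v)
  }
  min_day <- function(day, mask, fac_src) {     # earliest masked day per patient
    v <- tapply(ifelse(mask, day, NA_integer_), fac_src,
                function(x) if (all(is.na(x))) NA_integer_ else min(x, na.rm = TRUE))
    as.integer(v)
  }

  is_para <- startsWith(d_atc, toupper(config$paracetamol_atc))
  is_copd_rx <- startsWith(d_atc, toupper(config$copd_atc_prefix)) &
    !startsWith(d_atc, toupper(config$copd_atc_exclude))
  is_statin <- startsWith(d_atc, toupper(config$statin_atc_prefix))
  is_gluco <- startsWith(d_atc, toupper(config$glucocorticoid_atc_prefix))
  e_copd <- icd_matches(e_code, config$copd_icd_prefixes)

  in_lb_d <- d_day >= ss - lb & d_day < ss
  in_lb_e <- e_day >= ss - lb & e_day < ss
  in_study_para <- is_para & d_day >= ss & d_day <= se

  age_start <- age_at(patients$date_of_birth, config$study_start)
  fe <- as.integer(as.Date(patients$full_entitlement_start))
  death <- as.integer(as.Date(patients$death_date))
  rac <- as.integer(as.Date(patients$rac_entry_date))
  entry <- min_day(d_day, in_study_para, pf)
  end0 <- pmin(ifelse(is.na(death), se, death),
               ifelse(is.na(rac), se, rac), se)

  # eligibility gates (every failed gate is reported)
  g_age <- age_start < config$age_range[1] | age_start > config$age_range[2]
  g_ent <- is.na(fe) | fe > ss - lb
  g_evid <- !(any_d(is_copd_rx & in_lb_d) | any_e(e_copd & in_lb_e))
  g_wash <- any_d(is_para & d_day >= ss - wo & d_day < ss)
  g_rac <- !is.na(rac) & rac <= ss
  g_init <- is.na(entry)
  g_short <- !g_init & (end0 - entry) <= 1L
  gates <- cbind(`age-range` = g_age, entitlement = g_ent,
                 `no-copd-evidence` = g_evid, `prior-paracetamol` = g_wash,
                 `in-rac` = g_rac, `no-initiation` = g_init,
                 `short-follow-up` = g_short)
  hit <- which(gates, arr.ind = TRUE)
  hit <- hit[order(hit[, "row"], hit[, "col"]), , drop = FALSE]
  exclusions <- data.frame(patient_id = pid[hit[, "row"]],
                           reason = colnames(gates)[hit[, "col"]])
  elig <- !apply(gates, 1, any)

  # outcome and censoring for eligible members
  entry_row_d <- entry[match(d_pid, pid)]       # entry of the row's patient
  entry_row_e <- entry[match(e_pid, pid)]
  ev_day <- min_day(e_day, e_prim & e_copd & !is.na(entry_row_e) &
                      e_day > entry_row_e, ef)
  event <- !is.na(ev_day) & ev_day <= end0
  endd <- ifelse(event, ev_day, end0)
  censor_reason <- ifelse(event, "event",
    c("death", "rac", "study-end")[apply(cbind(ifelse(is.na(death), Inf, death),
                                               ifelse(is.na(rac), Inf, rac),
                                               se), 1, which.min)])

  # severity stratum from the 12-month pre-start window
  stratum <- ifelse(any_d(is_gluco & in_lb_d) | any_e(e_copd & in_lb_e),
                    "high", "low")

  # comorbidity categories: first matching ATC prefix per dispensing row
  map <- config$comorbidity_map
  d_cat <- rep(NA_character_, length(d_atc))
  for (k in seq_len(nrow(map))) {
    m <- is.na(d_cat) & startsWith(d_atc, toupper(map$atc_prefix[k]))
    d_cat[m] <- map$category[k]
  }
  in_cov_win <- !is.na(entry_row_d) & d_day >= entry_row_d - lb &
    d_day < entry_row_d & !is.na(d_cat)
  cat_flag <- function(cat) any_d(in_cov_win & d_cat == cat)
  excl_cats <- c("hypertension", "chf", "diabetes", "copd", "statin")
  nco <- tapply(ifelse(in_cov_win & !(d_cat %in% excl_cats), d_cat, NA), pf,
                function(x) length(unique(x[!is.na(x)])))
  nco <- ifelse(is.na(nco), 0L, nco)

  has_hs <- "health_services_12m" %in% names(patients)
  members <- data.frame(
    patient_id = pid,
    entry_date = as.Date(entry, origin = "1970-01-01"),
    end_date = as.Date(as.integer(endd), origin = "1970-01-01"),
    futime = as.integer(endd - entry),
    event = event, censor_reason = censor_reason, stratum = stratum,
    age = age_at(patients$date_of_birth,
                 as.Date(ifelse(is.na(entry), ss, entry), origin = "1970-01-01")),
    sexF = as.integer(as.character(patients$sex) == "F"),
    hypertension = as.integer(cat_flag("hypertension")),
    chf = as.integer(cat_flag("chf")),
    diabetes = as.integer(cat_flag("diabetes")),
    comorbidity_count = as.integer(nco),
    health_services_12m = if (has_hs) patients$health_services_12m else NA_real_
  )[elig, , drop = FALSE]
  rownames(members) <- NULL

  # daily exposure and statin series for members
  exposure <- list(); statin <- list()
  stp <- config$statin_tablets_per_day
  d_rows <- split(seq_along(d_pid), pf)
  dose_of <- config$dose_per_day
  for (i in which(elig)) {
    id <- pid[i]
    rows <- d_rows[[id]]
    ent <- entry[i]; end_i <- as.integer(endd[i]); L <- end_i - ent
    pr <- rows[is_para[rows] & d_day[rows] >= ent & d_day[rows] < end_i]
    pr <- pr[order(d_day[pr])]
    strength <- as.character(dispensings$strength_mg[pr])
    x <- coverage_series(d_day[pr] - ent,
                         days_of_supply(dispensings$quantity[pr], strength,
                                        config$tablets_per_day),
                         dose_of[strength], L)
    exposure[[id]] <- structure(
      list(origin = as.Date(ent, origin = "1970-01-01"),
           end = as.Date(end_i, origin = "1970-01-01"), doses = x),
      class = "daily_series")
    sr <- rows[is_statin[rows] & d_day[rows] < end_i]
    sr <- sr[order(d_day[sr])]
    sx <- if (length(sr))
      as.numeric(coverage_series(
        d_day[sr] - ent,
        pmax(1L, as.integer(floor(dispensings$quantity[sr] / stp))),
        rep(1, length(sr)), L) > 0)
    else numeric(L)
    statin[[id]] <- structure(
      list(origin = as.Date(ent, origin = "1970-01-01"),
           end = as.Date(end_i, origin = "1970-01-01"), doses = sx),
      class = "daily_series")
  }
  structure(list(members = members, exposure = exposure, statin = statin,
                 exclusions = exclusions, config = config),
            class = "claims_cohort")
}

#' @export
print.claims_cohort <- function(x, ...) {
  cat(sprintf("claims_cohort: %d member(s), %d event(s); %d patient(s) excluded\n",
              nrow(x$members), sum(x$members$event),
              length(unique(x$exclusions$patient_id))))
  invisible(x)
}

#' Counting-process table for a cohort
#'
#' Lays the cohort out as half-open `(start, stop]` day intervals from entry,
#' splitting at every day on which a time-varying quantity (daily dose or
#' statin status) changes and coalescing runs of constant values. The interval
#' `(start, stop]` carries the dose and statin status of day `start` (the
#' exposure day the interval covers). Each member's intervals partition
#' `(0, futime]`; the event flag sits on the final interval of event members.
#' The `start` column doubles as the day index for WCE covariate lookup.
#'
#' @param cohort a [build_cohort()] result.
#' @return data.frame with columns `patient_id`, `start`, `stop`, `event`,
#'   `stratum`, fixed covariates, `dose_g`, `statin`.
#' @export
build_counting_process <- function(cohort) {
  stopifnot(inherits(cohort, "claims_cohort"))
  m <- cohort$members
  rows <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    id <- m$patient_id[i]
    L <- m$futime[i]
    if (L < 1L) next
    x <- cohort$exposure[[id]]$doses[seq_len(L)]
    s <- cohort$statin[[id]]$doses[seq_len(L)]
    if (length(x) != L || length(s) != L)
      stop("internal consistency failure: series length does not match follow-up for ",
           id, call. = FALSE)
    chg <- c(TRUE, x[-1] != x[-L] | s[-1] != s[-L])
    start <- (which(chg)) - 1L
    stop_ <- c(start[-1], L)
    rows[[i]] <- data.frame(
      patient_id = id, start = start, stop = stop_,
      event = c(rep(FALSE, length(start) - 1L), m$event[i]),
      stratum = m$stratum[i], age = m$age[i], sexF = m$sexF[i],
      hypertension = m$hypertension[i], chf = m$chf[i], diabetes = m$diabetes[i],
      comorbidity_count = m$comorbidity_count[i],
      dose_g = x[start + 1L], statin = s[start + 1L]
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  out
}
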