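#' Default true weight function for simulations
#'
#' A biphasic lag-weight function expressed exactly on a 75-day, one-interior-
#' knot cubic spline basis: negative weights in the first week after exposure
#' (a transient protective dip), positive weights peaking around four weeks
#' (a delayed harmful phase), and essentially zero beyond two months. The
#' amplitude is calibrated so that, at the 4 g/day maximum dose, a week of
#' current use gives a hazard ratio below 1 and a month of use a hazard ratio
#' around 1.2-1.3 — the order of magnitude seen in claims studies of this
#' design.
#'
#' @param scale multiplier on the coefficient vector (0 gives a null weight
#'   function on the same basis).
#' @return list with elements `basis` (a [spline_basis()]) and `theta`.
#' @export
default_true_weights <- function(scale = 1) {
  basis <- spline_basis(75, n_knots = 1)
  theta <- scale * c(-0.0160, 0.0136, -0.0029, 0.0004, -0.0001)
  names(theta) <- colnames(basis$B)
  list(basis = basis, theta = theta)
}

#' Simulation configuration for synthetic claims
#'
#' Defines the data-generating process for a synthetic elderly claims
#' population with existing COPD: demographics, baseline comorbidity
#' dispensing patterns, a paracetamol refill process with early refills and
#' gaps, daily death and residential-aged-care censoring, and hospitalization
#' events drawn day-by-day from a discrete-time Cox hazard driven by a known
#' (true) weight function applied to the reconstructed exposure series.
#'
#' @param n_patients number of patients.
#' @param seed RNG seed; a fixed seed gives byte-identical tables.
#' @param claims a [claims_config()]; supplies the study period and code lists.
#' @param true_weights `NULL` (no exposure effect) or a list
#'   `(basis, theta)` as from [default_true_weights()].
#' @param true_covariate_effects named log-hazard-ratios for
#'   `age` (per year, centred at `age_center`), `sexF`, `hypertension`, `chf`,
#'   `diabetes`, `comorbidity_count`, `statin`.
#' @param baseline_hazard per-day event probability scale for the low-severity
#'   stratum at covariate reference values.
#' @param stratum_hr_high multiplier on the baseline hazard in the
#'   high-severity stratum (stratified-model ground truth).
#' @param age_mean,age_sd,age_center age distribution (truncated to the
#'   eligible range) and centring constant for the age effect.
#' @param sex_ratio fraction female.
#' @param p_initiate probability a patient initiates paracetamol in-study.
#' @param p_prior_para probability of a paracetamol dispensing in the washout
#'   window (an exclusion the cascade must catch).
#' @param p_rac_at_start probability of residential-care residence at study
#'   start.
#' @param p_late_entitlement probability the entitlement window is too short.
#' @param p_copd_rx,p_copd_hosp,p_r03bb01_only baseline COPD evidence mix
#'   (every patient gets at least one qualifying marker unless flagged
#'   `p_r03bb01_only`, which plants the excluded ATC code as sole evidence).
#' @param p_h02ab probability of baseline systemic glucocorticoid use (drives
#'   the high-severity stratum together with baseline COPD hospitalization).
#' @param comorbidity_prev named prevalences for the generated comorbidity
#'   dispensing categories.
#' @param p_statin statin-user fraction.
#' @param refill list: `persistence` (per-refill continuation probability),
#'   `gap_mean` (mean extra days between the end of one supply and the next
#'   script), `early_max` (maximum early-refill overlap in days),
#'   `cr_fraction` (fraction of patients on 665 mg controlled release),
#'   `pack_500`, `pack_665` (tablets per pack), `restart` (probability a
#'   stopped patient later starts a new episode of use), `break_mean` (mean
#'   additional break length in days between episodes).
#' @param death_rate,rac_rate per-day censoring hazards from study start.
#' @param p_noise_episode probability of a non-outcome admission during
#'   follow-up (osteoarthritis primary, sometimes with a secondary COPD code —
#'   these must not be counted as outcomes).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 2000, seed = 1L,
                       claims = claims_config(),
                       true_weights = default_true_weights(),
                       true_covariate_effects = c(
                         age = 0.0296, sexF = -0.288, hypertension = -0.223,
                         chf = 0.239, diabetes = -0.117,
                         comorbidity_count = 0.058, statin = -0.186),
                       baseline_hazard = 2.0e-4, stratum_hr_high = 2,
                       age_mean = 84, age_sd = 7, age_center = 84,
                       sex_ratio = 0.38,
                       p_initiate = 0.85, p_prior_para = 0.04,
                       p_rac_at_start = 0.02, p_late_entitlement = 0.02,
                       p_copd_rx = 0.85, p_copd_hosp = 0.16,
                       p_r03bb01_only = 0.01, p_h02ab = 0.30,
                       comorbidity_prev = c(hypertension = 0.45, chf = 0.23,
                                            diabetes = 0.125, gord = 0.30,
                                            depression = 0.20,
                                            osteoporosis = 0.25, gout = 0.10),
                       p_statin = 0.53,
                       refill = list(persistence = 0.85, gap_mean = 6,
                                     early_max = 5, cr_fraction = 0.67,
                                     pack_500 = 100, pack_665 = 96,
                                     restart = 0.45, break_mean = 100),
                       death_rate = 1.2e-4, rac_rate = 4e-5,
                       p_noise_episode = 0.25) {
  probs <- c(sex_ratio, p_initiate, p_prior_para, p_rac_at_start,
             p_late_entitlement, p_copd_rx, p_copd_hosp, p_r03bb01_only,
             p_h02ab, comorbidity_prev, p_statin, refill$persistence,
             refill$cr_fraction, refill$restart, p_noise_episode)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (baseline_hazard <= 0 || death_rate < 0 || rac_rate < 0)
    stop("rates must be non-negative and baseline_hazard positive", call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

#' True hazard ratio for an exposure pattern under a simulation config
#'
#' The analytic recovery target for [pattern_hr()]:
#' `exp(sum_t w_true(t) x(t))` with `w_true` the configured true weight
#' function (identically zero when `true_weights` is `NULL`).
#'
#' @param config a [sim_config()].
#' @param pattern dose vector over lags `1, 2, ...` (g/day).
#' @return positive scalar.
#' @export
true_pattern_hr <- function(config, pattern) {
  if (is.null(config$true_weights)) return(exp(0 * sum(pattern)))
  Tw <- config$true_weights$basis$window
  if (length(pattern) > Tw)
    stop("pattern-window mismatch: pattern longer than the true window",
         call. = FALSE)
  w <- eval_weights(config$true_weights$basis, config$true_weights$theta)
  exp(sum(w[seq_along(pattern)] * pattern))
}

#' Generate synthetic claims tables with known ground truth
#'
#' Draws a population under the configured process and returns the three
#' claims tables the pipeline consumes plus the simulation truth. Events are
#' drawn in discrete time: on each follow-up day `u` a Bernoulli trial at
#' `h(u) = h0 * stratum_mult * exp(theta' D(u) + beta' Z(u))` decides the
#' outcome, where `D(u)` are the true-basis WCE covariates of the generated
#' exposure series. The first event day becomes a primary-position COPD
#' hospital episode. Configurations whose implied daily hazard exceeds 1 on
#' any simulated day are rejected.
#'
#' @param config a [sim_config()].
#' @return list with `patients`, `dispensings`, `episodes` (data.frames with
#'   ISO-8601 dates) and `truth` (list: `weights`, `per_patient` data.frame
#'   with entry/event bookkeeping, `hazard` — named list of daily hazard
#'   vectors over follow-up).
#' @export
simulate_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cc <- config$claims
  ss <- as.integer(cc$study_start)        # work in integer days
  se <- as.integer(cc$study_end)
  study_days <- se - ss
  rf <- config$refill
  w_basis <- if (!is.null(config$true_weights)) config$true_weights$basis else NULL
  w_theta <- if (!is.null(w_basis)) config$true_weights$theta else NULL
  beta <- config$true_covariate_effects

  # accumulators (numeric dates; converted once at the end)
  p_id <- character(0); p_dob <- numeric(0); p_sex <- character(0)
  p_death <- numeric(0); p_rac <- numeric(0); p_fe <- numeric(0); p_hs <- numeric(0)
  d_id <- list(); d_date <- list(); d_atc <- list(); d_str <- list(); d_qty <- list()
  e_id <- list(); e_date <- list(); e_code <- list(); e_pos <- list()
  tr_id <- character(0); tr_entry <- numeric(0); tr_len <- integer(0)
  tr_event <- logical(0); tr_eday <- integer(0)
  hazards <- list()

  alive_until <- Inf   # per-patient cap: no claims are generated after death
  add_disp <- function(id, dates, atc, strength, qty) {
    dates <- dates[dates <= alive_until]
    if (!length(dates)) return(invisible())
    k <- length(d_id) + 1L
    d_id[[k]] <<- rep(id, length(dates)); d_date[[k]] <<- dates
    d_atc[[k]] <<- rep(atc, length(dates))
    d_str[[k]] <<- rep(strength, length(dates))
    d_qty[[k]] <<- rep(qty, length(dates))
  }
  add_epi <- function(id, date, code, pos) {
    keep <- date <= alive_until
    if (!any(keep)) return(invisible())
    k <- length(e_id) + 1L
    e_id[[k]] <<- rep(id, sum(keep)); e_date[[k]] <<- date[keep]
    e_code[[k]] <<- rep(code, length(date))[keep]
    e_pos[[k]] <<- rep(pos, length(date))[keep]
  }
  # recurring scripts from `from` to `to` with mean spacing `gap` days
  recurring <- function(from, to, gap) {
    out <- numeric(0); t <- from
    while (t <= to) { out <- c(out, t); t <- t + max(1, round(gap * (0.7 + 0.6 * stats::runif(1)))) }
    out
  }
  category_atc <- c(hypertension = "C09AA05", chf = "C01AA05",
                    diabetes = "A10BA02", gord = "A02BC01",
                    depression = "N06AB04", osteoporosis = "M05BA04",
                    gout = "M04AA01")
  copd_codes <- c("J440", "J441", "J448", "J449", "J439")

  for (i in seq_len(config$n_patients)) {
    id <- sprintf("P%05d", i)
    sex <- if (stats::runif(1) < config$sex_ratio) "F" else "M"
    repeat {
      age <- stats::rnorm(1, config$age_mean, config$age_sd)
      if (age >= config$claims$age_range[1] && age <= config$claims$age_range[2]) break
    }
    dob <- ss - round(age * 365.25) - sample.int(365, 1) + 1
    fe_start <- if (stats::runif(1) < config$p_late_entitlement)
      ss - sample(30:300, 1) else ss - 365 - sample.int(2000, 1)

    rac_date <- if (stats::runif(1) < config$p_rac_at_start)
      ss - sample.int(300, 1)
    else if (config$rac_rate > 0) ss + round(stats::rexp(1, config$rac_rate))
    else NA_real_
    death_date <- if (config$death_rate > 0)
      ss + round(stats::rexp(1, config$death_rate)) else NA_real_
    alive_until <- if (is.na(death_date)) Inf else death_date

    # baseline COPD evidence
    copd_rx <- stats::runif(1) < config$p_copd_rx
    copd_hosp <- stats::runif(1) < config$p_copd_hosp
    if (!copd_rx && !copd_hosp) copd_rx <- TRUE
    if (stats::runif(1) < config$p_r03bb01_only) {          # excluded-code trap
      add_disp(id, ss - sample.int(365, 1), "R03BB01", NA, 30)
      copd_rx <- FALSE; copd_hosp <- FALSE
    }
    if (copd_rx)
      add_disp(id, ss - sample.int(365, sample(1:3, 1)), "R03BB04", NA, 30)
    if (copd_hosp)
      add_epi(id, ss - sample.int(365, 1), sample(copd_codes, 1),
              sample(c("primary", "secondary"), 1))
    h02ab <- stats::runif(1) < config$p_h02ab
    if (h02ab)
      add_disp(id, recurring(ss - 365 + sample.int(60, 1), se, 90), "H02AB06", NA, 30)

    comorb <- names(config$comorbidity_prev)[
      stats::runif(length(config$comorbidity_prev)) < config$comorbidity_prev]
    for (cat in comorb)
      add_disp(id, recurring(ss - 365 + sample.int(90, 1), se, 120),
               category_atc[[cat]], NA, 30)

    statin_user <- stats::runif(1) < config$p_statin
    statin_dates <- numeric(0)
    if (statin_user) {
      t <- ss - 365 + sample.int(500, 1)
      while (t <= se) {
        statin_dates <- c(statin_dates, t)
        if (stats::runif(1) > 0.97) break
        t <- t + 30 + sample(-2:4, 1)
      }
      add_disp(id, statin_dates, "C10AA01", NA, 30)
    }

    if (stats::runif(1) < config$p_prior_para)
      add_disp(id, ss - sample.int(cc$washout_days, 1), cc$paracetamol_atc, "500", 100)

    # paracetamol refill chain
    para_dates <- numeric(0); para_strength <- character(0); para_qty <- numeric(0)
    initiates <- stats::runif(1) < config$p_initiate
    if (initiates) {
      cr <- stats::runif(1) < rf$cr_fraction
      strength <- if (cr) "665" else "500"
      qty <- if (cr) rf$pack_665 else rf$pack_500
      dur <- days_of_supply(qty, strength, cc$tablets_per_day)
      # patient-level persistence heterogeneity: chronic users coexist with
      # short-course users, spreading total exposed days as in real claims
      pers_i <- stats::rbeta(1, 10 * rf$persistence, 10 * (1 - rf$persistence))
      t <- ss + sample.int(max(1L, floor(0.9 * study_days)), 1) - 1L
      repeat {                                  # episodes of use with breaks
        while (t <= se) {
          para_dates <- c(para_dates, t)
          para_strength <- c(para_strength, strength)
          para_qty <- c(para_qty, qty)
          if (stats::runif(1) > pers_i) break
          gap <- stats::rgeom(1, 1 / (1 + rf$gap_mean + rf$early_max)) - rf$early_max
          t <- t + dur + gap
        }
        if (t > se || stats::runif(1) > rf$restart) break
        t <- t + dur + 30 + round(stats::rexp(1, 1 / rf$break_mean))
      }
      add_disp(id, para_dates, cc$paracetamol_atc, strength, qty)
    }

    # event process from entry (first in-study paracetamol script)
    event <- FALSE; event_day <- NA_integer_; entry <- NA_real_; L <- 0L
    if (initiates && length(para_dates) && min(para_dates) >= ss) {
      entry <- min(para_dates)
      end0 <- min(c(death_date, rac_date, se), na.rm = TRUE)
      L <- as.integer(end0 - entry)
      if (L >= 1L) {
        keep <- para_dates < end0
        pdur <- days_of_supply(para_qty[keep], para_strength[keep], cc$tablets_per_day)
        doses <- coverage_series(para_dates[keep] - entry, pdur,
                                 cc$dose_per_day[para_strength[keep]], L)
        wce_term <- if (!is.null(w_basis)) {
          w_curve <- drop(w_basis$B %*% w_theta)
          Tw <- w_basis$window
          drop(stats::filter(c(rep(0, Tw), doses), w_curve,
                             sides = 1))[(Tw + 1):(Tw + L)]
        } else numeric(L)
        st_cov <- numeric(L)
        if (length(statin_dates)) {
          sk <- statin_dates < end0
          st_cov <- as.numeric(coverage_series(
            statin_dates[sk] - entry,
            rep(round(30 / config$claims$statin_tablets_per_day), sum(sk)),
            rep(1, sum(sk)), L) > 0)                # status on day u-1
        }
        age_entry <- (entry - dob) / 365.25
        nco_true <- length(setdiff(comorb, c("hypertension", "chf", "diabetes"))) +
          as.integer(h02ab)
        lp_fixed <- beta[["age"]] * (age_entry - config$age_center) +
          beta[["sexF"]] * (sex == "F") +
          beta[["hypertension"]] * ("hypertension" %in% comorb) +
          beta[["chf"]] * ("chf" %in% comorb) +
          beta[["diabetes"]] * ("diabetes" %in% comorb) +
          beta[["comorbidity_count"]] * nco_true
        stratum_high <- copd_hosp || h02ab
        h <- config$baseline_hazard *
          (if (stratum_high) config$stratum_hr_high else 1) *
          exp(lp_fixed + wce_term + beta[["statin"]] * st_cov)
        if (any(h > 1))
          stop("hazard-overflow: configured effects imply a daily hazard above 1",
               call. = FALSE)
        hit <- stats::runif(L) < h
        if (any(hit)) {
          event <- TRUE
          event_day <- which(hit)[1]
          L <- event_day
          h <- h[seq_len(L)]
          add_epi(id, entry + event_day, sample(copd_codes, 1), "primary")
        }
        hazards[[id]] <- h
        # non-outcome noise admissions (never primary COPD)
        if (stats::runif(1) < config$p_noise_episode) {
          nd <- entry + sample.int(max(L, 2L), 1)
          add_epi(id, nd, "M159", "primary")
          if (stats::runif(1) < 0.5) add_epi(id, nd, sample(copd_codes, 1), "secondary")
        }
      }
    }
    if (is.na(L) || L < 0L) L <- 0L
    tr_id <- c(tr_id, id); tr_entry <- c(tr_entry, entry)
    tr_len <- c(tr_len, L); tr_event <- c(tr_event, event)
    tr_eday <- c(tr_eday, event_day)

    p_id <- c(p_id, id); p_dob <- c(p_dob, dob); p_sex <- c(p_sex, sex)
    p_death <- c(p_death, death_date); p_rac <- c(p_rac, rac_date)
    p_fe <- c(p_fe, fe_start)
    p_hs <- c(p_hs, round(stats::rlnorm(1, log(45), 0.5)))
  }

  patients <- data.frame(
    patient_id = p_id, date_of_birth = p_dob, sex = p_sex,
    death_date = p_death, rac_entry_date = p_rac,
    full_entitlement_start = p_fe, health_services_12m = p_hs)
  for (v in c("date_of_birth", "death_date", "rac_entry_date", "full_entitlement_start"))
    patients[[v]] <- as.Date(patients[[v]], origin = "1970-01-01")
  dispensings <- data.frame(
    patient_id = unlist(d_id), supply_date = as.Date(unlist(d_date), origin = "1970-01-01"),
    atc_code = unlist(d_atc), strength_mg = unlist(d_str), quantity = unlist(d_qty))
  episodes <- data.frame(
    patient_id = unlist(e_id), admission_date = as.Date(unlist(e_date), origin = "1970-01-01"),
    diagnosis_code = unlist(e_code), position = unlist(e_pos))
  if (!nrow(dispensings))
    dispensings <- data.frame(patient_id = character(0), supply_date = as.Date(character(0)),
                              atc_code = character(0), strength_mg = character(0),
                              quantity = numeric(0))
  if (!nrow(episodes))
    episodes <- data.frame(patient_id = character(0), admission_date = as.Date(character(0)),
                           diagnosis_code = character(0), position = character(0))
  rownames(patients) <- rownames(dispensings) <- rownames(episodes) <- NULL

  truth <- list(
    weights = config$true_weights,
    per_patient = data.frame(
      patient_id = tr_id,
      entry_date = as.Date(tr_entry, origin = "1970-01-01"),
      followup_days = tr_len, event = tr_event, event_day = tr_eday),
    hazard = hazards)
  list(patients = patients, dispensings = dispensings, episodes = episodes,
       truth = truth)
}
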