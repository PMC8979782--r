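# Shared fixtures and independent oracles, built in code.

# A minimal hand-laid cohort object compatible with wce_cox_data():
# `spec` is a data.frame with futime, event, stratum, covariates and a list
# column `doses` (daily dose vectors) and optionally `statin`.
make_mini_cohort <- function(spec) {
  n <- nrow(spec)
  ids <- sprintf("S%02d", seq_len(n))
  members <- data.frame(
    patient_id = ids,
    entry_date = as.Date("2011-02-01"),
    end_date = as.Date("2011-02-01") + spec$futime,
    futime = spec$futime, event = spec$event,
    censor_reason = ifelse(spec$event, "event", "study-end"),
    stratum = spec$stratum,
    age = spec$age, sexF = spec$sexF,
    hypertension = 0L, chf = 0L, diabetes = 0L, comorbidity_count = 0L,
    health_services_12m = 40)
  exposure <- list(); statin <- list()
  for (i in seq_len(n)) {
    exposure[[ids[i]]] <- structure(
      list(origin = members$entry_date[i], end = members$end_date[i],
           doses = spec$doses[[i]]), class = "daily_series")
    sdose <- if (!is.null(spec$statin)) spec$statin[[i]] else numeric(spec$futime[i])
    statin[[ids[i]]] <- structure(
      list(origin = members$entry_date[i], end = members$end_date[i],
           doses = sdose), class = "daily_series")
  }
  structure(list(members = members, exposure = exposure, statin = statin,
                 exclusions = data.frame(patient_id = character(0),
                                         reason = character(0)),
                 config = claims_config()),
            class = "claims_cohort")
}

# Independent person-day oracle for the stratified Cox partial likelihood.
# Expands the cohort to person-days, evaluates every covariate directly from
# the series (double loops, no shared code with the fitting machinery), and
# computes the Efron/Breslow log partial likelihood from first principles.
persondays_loglik <- function(cohort, basis, par, ties = "efron",
                              covariates = c("age", "sexF"), statin = TRUE) {
  m <- cohort$members
  J <- ncol(basis$B)
  rows <- list()
  for (i in seq_len(nrow(m))) {
    id <- m$patient_id[i]
    x <- cohort$exposure[[id]]$doses
    s <- cohort$statin[[id]]$doses
    for (u in seq_len(m$futime[i])) {
      D <- numeric(J)
      for (t in seq_len(min(u, basis$window)))
        D <- D + basis$B[t, ] * x[u - t + 1]   # X(u - t), day d at index d + 1
      z <- c(D, as.numeric(m[i, covariates]), if (statin) s[u])
      rows[[length(rows) + 1L]] <- data.frame(
        t(z), day = u, stratum = m$stratum[i],
        dead = m$event[i] && u == m$futime[i])
    }
  }
  pd <- do.call(rbind, rows)
  zc <- seq_len(length(par))
  eta <- as.matrix(pd[, zc]) %*% par
  ll <- 0
  for (st in unique(pd$stratum)) {
    for (u in sort(unique(pd$day[pd$dead & pd$stratum == st]))) {
      rs <- which(pd$stratum == st & pd$day == u)     # at risk on day u
      dr <- rs[pd$dead[rs]]
      d <- length(dr)
      wr <- exp(eta[rs]); wd <- exp(eta[dr])
      ll <- ll + sum(eta[dr])
      for (k in seq_len(d) - 1) {
        f <- if (ties == "efron") k / d else 0
        ll <- ll - log(sum(wr) - f * sum(wd))
      }
    }
  }
  ll
}

# central finite differences of a scalar function
fd_gradient <- function(fun, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (fun(x + e) - fun(x - e)) / (2 * h)
  }, numeric(1))
}

# 20-patient eligibility fixture: one intended violation (or none) per
# patient, with the expected reason sets enumerated by hand.
eligibility_fixture <- function() {
  ss <- as.Date("2011-01-01")
  base_patient <- function(id, dob = as.Date("1935-06-15"), sex = "M",
                           death = NA, rac = NA, fe = ss - 1000) {
    data.frame(patient_id = id, date_of_birth = dob, sex = sex,
               death_date = as.Date(death), rac_entry_date = as.Date(rac),
               full_entitlement_start = fe)
  }
  disp <- function(id, date, atc, strength = NA, qty = 30) {
    data.frame(patient_id = id, supply_date = as.Date(date), atc_code = atc,
               strength_mg = strength, quantity = qty)
  }
  epi <- function(id, date, code, pos) {
    data.frame(patient_id = id, admission_date = as.Date(date),
               diagnosis_code = code, position = pos)
  }
  evid <- function(id) disp(id, "2010-06-01", "R03BB04")       # COPD evidence
  para <- function(id, date = "2011-03-01")
    disp(id, date, "N02BE01", "500", 100)                      # initiation

  patients <- list(); dispensings <- list(); episodes <- list()
  expected <- list()
  add <- function(p, d, e, reasons) {
    patients[[p$patient_id]] <<- p
    dispensings[[p$patient_id]] <<- d
    episodes[[p$patient_id]] <<- e
    expected[[p$patient_id]] <<- reasons
  }
  none <- dispensings_none <- NULL

  # 1-5: clean eligible patients (varied evidence routes)
  add(base_patient("E01"), rbind(evid("E01"), para("E01")), NULL, character(0))
  add(base_patient("E02", sex = "F"),
      para("E02"),
      epi("E02", "2010-10-01", "J441", "secondary"), character(0))  # episode evidence, any position
  add(base_patient("E03"), rbind(evid("E03"), para("E03", "2011-01-01")), NULL,
      character(0))                                            # entry on study start
  add(base_patient("E04"),
      para("E04"),
      epi("E04", "2010-03-03", "J439", "primary"), character(0))  # J43* prefix evidence
  add(base_patient("E05", dob = as.Date("1965-12-31")),        # age 45 at start
      rbind(evid("E05"), para("E05")), NULL, character(0))

  # 6: aged 44 at study start
  add(base_patient("X06", dob = as.Date("1966-06-15")),
      rbind(evid("X06"), para("X06")), NULL, "age-range")
  # 7: aged 101
  add(base_patient("X07", dob = as.Date("1909-06-15")),
      rbind(evid("X07"), para("X07")), NULL, "age-range")
  # 8: entitlement starts inside the lookback year
  add(base_patient("X08", fe = ss - 100),
      rbind(evid("X08"), para("X08")), NULL, "entitlement")
  # 9: no COPD evidence at all
  add(base_patient("X09"), para("X09"), NULL, "no-copd-evidence")
  # 10: only the excluded ATC code as evidence
  add(base_patient("X10"),
      rbind(disp("X10", "2010-06-01", "R03BB01"), para("X10")), NULL,
      "no-copd-evidence")
  # 11: COPD episode too old (13 months before start)
  add(base_patient("X11"), para("X11"),
      epi("X11", "2009-11-20", "J440", "primary"), "no-copd-evidence")
  # 12: bronchitis-only episode does not qualify
  add(base_patient("X12"), para("X12"),
      epi("X12", "2010-08-01", "J42", "primary"), "no-copd-evidence")
  # 13: paracetamol in the 6-month washout
  add(base_patient("X13"),
      rbind(evid("X13"), disp("X13", "2010-10-01", "N02BE01", "500", 100),
            para("X13")), NULL, "prior-paracetamol")
  # 14: paracetamol 7+ months before start is allowed
  add(base_patient("E14"),
      rbind(evid("E14"), disp("E14", "2010-05-01", "N02BE01", "500", 100),
            para("E14")), NULL, character(0))
  # 15: in residential care at study start (follow-up also collapses,
  # since censoring at RAC entry precedes cohort entry)
  add(base_patient("X15", rac = "2010-09-01"),
      rbind(evid("X15"), para("X15")), NULL, c("in-rac", "short-follow-up"))
  # 16: never initiates in-study
  add(base_patient("X16"), evid("X16"), NULL, "no-initiation")
  # 17: pre-study paracetamol only (outside washout) and none in-study
  add(base_patient("X17"),
      rbind(evid("X17"), disp("X17", "2010-05-01", "N02BE01", "500", 100)),
      NULL, "no-initiation")
  # 18: dies the day after initiation (one day of follow-up)
  add(base_patient("X18", death = "2011-03-02"),
      rbind(evid("X18"), para("X18")), NULL, "short-follow-up")
  # 19: two violations at once (age + washout)
  add(base_patient("X19", dob = as.Date("1968-01-01")),
      rbind(evid("X19"), disp("X19", "2010-12-01", "N02BE01", "500", 100),
            para("X19")), NULL, c("age-range", "prior-paracetamol"))
  # 20: residential care entered the day after entry: 1 day of follow-up
  add(base_patient("X20", rac = "2011-03-02"),
      rbind(evid("X20"), para("X20")), NULL, "short-follow-up")

  list(patients = do.call(rbind, patients),
       dispensings = do.call(rbind, dispensings),
       episodes = do.call(rbind, episodes),
       expected = expected)
}

# small shared simulation (cached across tests in one run)
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_patients = 600, seed = 922)
      sim <- simulate_population(cfg)
      cohort <- build_cohort(sim$patients, sim$dispensings, sim$episodes,
                             cfg$claims)
      cache <<- list(cfg = cfg, sim = sim, cohort = cohort)
    }
    cache
  }
})
`%||%` <- function(a, b) if (is.null(a)) b else a

# shared 8-subject oracle fixture
mini_spec <- function() {
  set.seed(31)
  n <- 8
  futime <- c(10L, 12L, 7L, 12L, 9L, 11L, 10L, 12L)
  event <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  spec <- data.frame(futime = futime, event = event,
                     stratum = rep(c("low", "high"), each = 4),
                     age = c(78, 85, 81, 90, 74, 88, 83, 79),
                     sexF = c(0L, 1L, 0L, 1L, 1L, 0L, 0L, 1L))
  spec$doses <- lapply(futime, function(L) sample(c(0, 3.99, 4), L, replace = TRUE))
  spec$statin <- lapply(futime, function(L) rep(sample(0:1, 1), L))
  spec
}

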