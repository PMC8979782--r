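test_that("eligibility cascade reproduces hand-enumerated reason sets", {
  fx <- eligibility_fixture()
  cfg <- claims_config()
  co <- build_cohort(fx$patients, fx$dispensings, fx$episodes, cfg)
  got <- split(co$exclusions$reason, co$exclusions$patient_id)
  for (id in names(fx$expected)) {
    exp_r <- fx$expected[[id]]
    if (length(exp_r) == 0) {
      expect_true(id %in% co$members$patient_id, label = paste(id, "eligible"))
    } else {
      expect_true(setequal(got[[id]], exp_r),
                  label = paste(id, "reasons:", paste(got[[id]], collapse = ",")))
    }
  }
  # bookkeeping reconciles: every patient is a member or carries >= 1 reason
  expect_equal(sort(unique(c(co$members$patient_id, co$exclusions$patient_id))),
               sort(fx$patients$patient_id))
  # per-reason exclusion counts match the enumeration
  tab <- table(co$exclusions$reason)
  exp_tab <- table(unlist(fx$expected))
  expect_equal(as.vector(tab[names(exp_tab)]), as.vector(exp_tab))
})

test_that("entry is the first in-study paracetamol dispensing", {
  cfg <- claims_config()
  d <- data.frame(patient_id = "A",
                  supply_date = as.Date(c("2010-10-10", "2011-03-01", "2011-06-01")),
                  atc_code = "N02BE01", strength_mg = "500", quantity = 100)
  expect_equal(determine_entry(d, cfg), as.Date("2011-03-01"))
  d2 <- d; d2$supply_date[2] <- as.Date("2011-01-01")
  expect_equal(determine_entry(d2, cfg), as.Date("2011-01-01"))  # boundary inclusive
  d3 <- d[1, , drop = FALSE]
  expect_error(determine_entry(d3, cfg), "undefined")
})

test_that("outcome requires a primary-position code; inclusion does not", {
  cfg <- claims_config()
  p <- data.frame(patient_id = "A", date_of_birth = as.Date("1935-01-01"),
                  sex = "M", death_date = as.Date("2012-05-10"),
                  rac_entry_date = as.Date(NA),
                  full_entitlement_start = as.Date("2008-01-01"))
  entry <- as.Date("2011-02-01")
  ep_prim <- data.frame(patient_id = "A",
                        admission_date = as.Date("2011-05-12"),
                        diagnosis_code = "J449", position = "primary")
  out <- define_outcome(p, ep_prim, entry, cfg)
  expect_true(out$event)
  expect_equal(out$end_date, as.Date("2011-05-12"))   # event beats later death

  ep_sec <- ep_prim; ep_sec$position <- "secondary"
  out2 <- define_outcome(p, ep_sec, entry, cfg)
  expect_false(out2$event)
  expect_equal(out2$censor_reason, "death")

  # episode before entry is ignored even with a matching primary code
  ep_pre <- ep_prim; ep_pre$admission_date <- as.Date("2011-01-20")
  out3 <- define_outcome(p, ep_pre, entry, cfg)
  expect_false(out3$event)

  # no events, no death/RAC: censored at study end
  p2 <- p; p2$death_date <- as.Date(NA)
  out4 <- define_outcome(p2, ep_sec, entry, cfg)
  expect_equal(out4$end_date, cfg$study_end)
  expect_equal(out4$censor_reason, "study-end")
})

test_that("severity stratum uses the 12-month pre-start window", {
  cfg <- claims_config()
  no_d <- data.frame(patient_id = character(0), supply_date = as.Date(character(0)),
                     atc_code = character(0), strength_mg = character(0),
                     quantity = numeric(0))
  no_e <- data.frame(patient_id = character(0), admission_date = as.Date(character(0)),
                     diagnosis_code = character(0), position = character(0))
  gluco <- data.frame(patient_id = "A", supply_date = as.Date("2010-11-01"),
                      atc_code = "H02AB06", strength_mg = NA, quantity = 30)
  expect_equal(classify_stratum(gluco, no_e, cfg), "high")
  expect_equal(classify_stratum(no_d, no_e, cfg), "low")
  old_hosp <- data.frame(patient_id = "A",
                         admission_date = as.Date("2009-11-15"),  # 13 months before
                         diagnosis_code = "J440", position = "primary")
  expect_equal(classify_stratum(no_d, old_hosp, cfg), "low")
  recent_hosp <- old_hosp; recent_hosp$admission_date <- as.Date("2010-07-01")
  expect_equal(classify_stratum(no_d, recent_hosp, cfg), "high")
})

test_that("covariate derivation maps ATC prefixes and excludes named categories", {
  cfg <- claims_config()
  entry <- as.Date("2011-03-01")
  d <- function(atc, date = "2010-09-01")
    data.frame(patient_id = "A", supply_date = as.Date(date), atc_code = atc,
               strength_mg = NA, quantity = 30)
  # hypertension + statin only: flag set, count zero
  cv <- derive_covariates(rbind(d("C09AA05"), d("C10AA01")), entry, cfg)
  expect_true(cv$hypertension)
  expect_equal(cv$comorbidity_count, 0)
  # five distinct non-excluded categories
  cv2 <- derive_covariates(rbind(d("A02BC01"), d("N06AB04"), d("M05BA04"),
                                 d("M04AA01"), d("N03AB02")), entry, cfg)
  expect_equal(cv2$comorbidity_count, 5)
  expect_false(cv2$hypertension || cv2$chf || cv2$diabetes)
  # empty dispensing history
  cv3 <- derive_covariates(d("C09AA05")[0, ], entry, cfg)
  expect_false(cv3$hypertension || cv3$chf || cv3$diabetes)
  expect_equal(cv3$comorbidity_count, 0)
  # outside the 12-month window
  cv4 <- derive_covariates(d("C01AA05", "2009-09-01"), entry, cfg)
  expect_false(cv4$chf)
})

test_that("counting process partitions follow-up and carries the event flag", {
  spec <- data.frame(futime = c(3L, 5L), event = c(TRUE, FALSE),
                     stratum = "low", age = 80, sexF = 0L)
  spec$doses <- list(c(4, 4, 0), c(0, 4, 4, 4, 0))
  spec$statin <- list(c(0, 0, 0), c(1, 1, 0, 0, 0))
  co <- make_mini_cohort(spec)
  cp <- build_counting_process(co)
  # subject 1: dose change at day 2 -> intervals (0,2], (2,3]
  s1 <- cp[cp$patient_id == "S01", ]
  expect_equal(s1$start, c(0, 2))
  expect_equal(s1$stop, c(2, 3))
  expect_equal(s1$event, c(FALSE, TRUE))
  expect_equal(s1$dose_g, c(4, 0))
  # subject 2: changes at days 1, 2 and 4
  s2 <- cp[cp$patient_id == "S02", ]
  expect_equal(s2$start, c(0, 1, 2, 4))
  expect_equal(s2$stop, c(1, 2, 4, 5))
  expect_false(any(s2$event))
  # partition property
  for (id in unique(cp$patient_id)) {
    rows <- cp[cp$patient_id == id, ]
    expect_equal(rows$start[-1], rows$stop[-nrow(rows)])
    expect_equal(rows$stop[nrow(rows)],
                 co$members$futime[co$members$patient_id == id])
  }
})

test_that("no immortal time: follow-up never precedes the first dispensing", {
  sh <- shared_sim()
  co <- sh$cohort
  first_para <- vapply(co$members$patient_id, function(id) {
    d <- sh$sim$dispensings
    min(d$supply_date[d$patient_id == id & d$atc_code == "N02BE01" &
                        d$supply_date >= co$config$study_start])
  }, numeric(1))
  expect_equal(as.numeric(co$members$entry_date), unname(first_para))
  expect_true(all(co$members$futime >= 1))
})

test_that("vectorised cohort builder agrees with the per-patient operations", {
  cfg <- sim_config(n_patients = 120, seed = 55)
  sim <- simulate_population(cfg)
  co <- build_cohort(sim$patients, sim$dispensings, sim$episodes, cfg$claims)
  disp_by <- split(seq_len(nrow(sim$dispensings)), sim$dispensings$patient_id)
  epi_by <- split(seq_len(nrow(sim$episodes)), sim$episodes$patient_id)
  for (i in seq_len(nrow(sim$patients))) {
    p <- sim$patients[i, , drop = FALSE]
    id <- p$patient_id
    d <- sim$dispensings[disp_by[[id]] %||% integer(0), , drop = FALSE]
    e <- sim$episodes[epi_by[[id]] %||% integer(0), , drop = FALSE]
    elig <- assess_eligibility(p, d, e, cfg$claims)
    expect_equal(id %in% co$members$patient_id, elig$eligible, label = id)
    if (!elig$eligible) {
      expect_true(setequal(co$exclusions$reason[co$exclusions$patient_id == id],
                           elig$reasons), label = id)
      next
    }
    entry <- determine_entry(d, cfg$claims)
    out <- define_outcome(p, e, entry, cfg$claims)
    cv <- derive_covariates(d, entry, cfg$claims)
    row <- co$members[co$members$patient_id == id, ]
    expect_equal(row$entry_date, entry, label = id)
    expect_equal(row$end_date, out$end_date, label = id)
    expect_equal(row$event, out$event, label = id)
    expect_equal(row$censor_reason, out$censor_reason, label = id)
    expect_equal(row$stratum, classify_stratum(d, e, cfg$claims), label = id)
    expect_equal(row$hypertension, as.integer(cv$hypertension), label = id)
    expect_equal(row$comorbidity_count, cv$comorbidity_count, label = id)
    para <- d[as.Date(d$supply_date) >= entry &
                as.Date(d$supply_date) < out$end_date &
                d$atc_code == "N02BE01", , drop = FALSE]
    ref <- build_daily_series(para, entry, out$end_date)
    expect_equal(co$exposure[[id]]$doses, ref$doses, label = id)
  }
})
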