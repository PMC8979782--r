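test_that("matched sets satisfy every matching invariant and are reproducible", {
  sh <- shared_sim()
  co <- sh$cohort
  sets <- sample_risk_sets(co, seed = 5)
  s <- sets$sets
  m <- co$members
  rix <- match(s$patient_id, m$patient_id)
  entry <- as.Date(m$entry_date)[rix]
  endd <- entry + m$futime[rix]
  ev <- m$event[rix]
  is_ctl <- s$role == "control"
  idx <- as.Date(s$index_date)
  # under follow-up at the index date, no event on or before it
  expect_true(all(entry[is_ctl] <= idx[is_ctl]))
  expect_true(all(ifelse(ev[is_ctl], endd[is_ctl] > idx[is_ctl],
                         endd[is_ctl] >= idx[is_ctl])))
  # matching calipers, per set
  for (sid in unique(s$set_id)) {
    rows <- which(s$set_id == sid)
    case <- rows[s$role[rows] == "case"]
    ctls <- setdiff(rows, case)
    expect_true(length(ctls) >= 1 && length(ctls) <= 2)
    expect_true(all(m$sexF[rix[ctls]] == m$sexF[rix[case]]))
    age_idx <- m$age[rix] + as.numeric(idx - entry) / 365.25
    expect_true(all(abs(age_idx[ctls] - age_idx[case]) <= 2))
    expect_true(all(abs(as.numeric(entry[ctls] - entry[case])) <= 30))
  }
  # a case is its own set's case exactly once, never its own control
  expect_true(all(tapply(s$role, s$set_id, function(r) sum(r == "case")) == 1))
  # reproducibility
  sets2 <- sample_risk_sets(co, seed = 5)
  expect_identical(sets$sets, sets2$sets)
  sets3 <- sample_risk_sets(co, seed = 6)
  expect_false(identical(sets$sets, sets3$sets))
})

test_that("control pools equal a brute-force scan of the cohort", {
  sh <- shared_sim()
  co <- sh$cohort
  m <- co$members
  # take all eligible controls by setting the target high: the sampled set
  # must then equal the brute-force pool exactly
  sets <- sample_risk_sets(co, seed = 1, n_controls = 10000L)
  s <- sets$sets
  entry <- as.Date(m$entry_date); endd <- entry + m$futime
  for (sid in unique(s$set_id)) {
    rows <- which(s$set_id == sid)
    case_id <- s$patient_id[rows[s$role[rows] == "case"]]
    ci <- match(case_id, m$patient_id)
    index <- endd[ci]
    pool <- c()
    for (j in seq_len(nrow(m))) {                      # O(n^2) oracle scan
      if (j == ci) next
      if (entry[j] > index) next
      if (m$event[j] && endd[j] <= index) next
      if (!m$event[j] && endd[j] < index) next
      if (m$sexF[j] != m$sexF[ci]) next
      aj <- m$age[j] + as.numeric(index - entry[j]) / 365.25
      ac <- m$age[ci] + as.numeric(m$futime[ci]) / 365.25
      if (abs(aj - ac) > 2) next
      if (abs(as.numeric(entry[j] - entry[ci])) > 30) next
      pool <- c(pool, m$patient_id[j])
    }
    got <- s$patient_id[rows[s$role[rows] == "control"]]
    expect_true(setequal(got, pool), label = paste("pool for case", case_id))
  }
  # every reported unmatched case truly has an empty pool
  for (uid in sets$unmatched) {
    expect_false(uid %in% s$patient_id[s$role == "case"])
  }
})

test_that("a later case can serve as an earlier control; empty pools are reported", {
  # S01 fails at day 100; S02 fails later (day 200) and is the only member
  # still at risk on S01's index date, so incidence-density sampling must use
  # the future case as the control. S02's own set has an empty pool (S01 has
  # already failed, S03 was censored), so S02 is reported unmatched.
  spec <- data.frame(futime = c(100L, 200L, 50L), event = c(TRUE, TRUE, FALSE),
                     stratum = "low", age = 80, sexF = 0L)
  spec$doses <- lapply(spec$futime, numeric)
  co <- make_mini_cohort(spec)
  sets <- sample_risk_sets(co, seed = 1)
  s <- sets$sets
  expect_equal(s$patient_id[s$role == "control" &
                              s$set_id == s$set_id[s$patient_id == "S01"]],
               "S02")
  expect_equal(sets$unmatched, "S02")
  # the reuse happens strictly before the control's own event date
  expect_true(all(as.Date(s$index_date[s$patient_id == "S02" &
                                         s$role == "control"]) <
                    as.Date("2011-02-01") + 200))
})

test_that("conditional logistic likelihood and fit match closed forms", {
  # null coefficients: logL = sum over sets of log(1 / set size)
  sh <- shared_sim()
  co <- sh$cohort
  sets <- sample_risk_sets(co, seed = 5)
  b <- spline_basis(30, 1)
  fit <- fit_wce_clogit(sets, co, sh$sim$dispensings, b)
  expect_true(fit$converged)
  d0 <- fit$data
  p0 <- cox_loglik_parts(d0, numeric(ncol(d0$Z)), "breslow")
  expect_equal(p0$loglik, sum(log(1 / table(d0$grp))))

  # 1:1 sets with one binary covariate: estimate = log(discordant ratio)
  n10 <- 7; n01 <- 3; n_conc <- 5
  Z <- matrix(c(rep(c(1, 0), n10), rep(c(0, 1), n01), rep(c(1, 1), n_conc)),
              ncol = 1)
  colnames(Z) <- "x"
  md <- list(Z = Z, grp = rep(seq_len(n10 + n01 + n_conc), each = 2),
             death = rep(c(TRUE, FALSE), n10 + n01 + n_conc),
             basis = NULL, n = nrow(Z))
  cd <- wceclaims:::clogit_data(md)
  f <- wceclaims:::newton_fit(cd, ties = "breslow")
  expect_equal(unname(f$par), log(n10 / n01), tolerance = 1e-8)
})

test_that("clogit WCE fit matches survival::clogit on the same member rows", {
  skip_if_not_installed("survival")
  sh <- shared_sim()
  co <- sh$cohort
  sets <- sample_risk_sets(co, seed = 5)
  b <- spline_basis(30, 1)
  fit <- fit_wce_clogit(sets, co, sh$sim$dispensings, b)
  md <- wceclaims:::ncc_member_rows(sets, co, sh$sim$dispensings, b,
                                    config = co$config)
  df <- data.frame(md$Z, case = as.integer(md$death), grp = md$grp)
  # one case per set, so the conditional likelihood equals the Breslow Cox
  # likelihood on a constant event time stratified by set
  cl <- survival::coxph(
    survival::Surv(rep(1, nrow(df)), case) ~ wce1 + wce2 + wce3 + wce4 + wce5 +
      hypertension + chf + diabetes + comorbidity_count + statin30 +
      log_health_services + survival::strata(grp),
    data = df, ties = "breslow",
    control = survival::coxph.control(eps = 1e-9, iter.max = 50))
  expect_equal(unname(fit$coef), unname(coef(cl)), tolerance = 1e-5)
  expect_equal(unname(fit$vcov), unname(vcov(cl)), tolerance = 1e-5)
})

test_that("conventional clogit exposure metrics summarise the index window", {
  sh <- shared_sim()
  co <- sh$cohort
  sets <- sample_risk_sets(co, seed = 5)
  for (metric in c("mean_dose", "any_exposure")) {
    md <- wceclaims:::ncc_member_rows(sets, co, sh$sim$dispensings, NULL,
                                      exposure_metric = metric,
                                      metric_window = 30, config = co$config)
    s <- sets$sets
    m <- co$members
    rix <- match(s$patient_id, m$patient_id)
    off <- as.numeric(as.Date(s$index_date) - as.Date(m$entry_date)[rix])
    for (r in sample(nrow(s), 25)) {
      x <- co$exposure[[s$patient_id[r]]]$doses
      vals <- vapply(1:30, function(t) {
        i <- off[r] - t + 1
        if (i >= 1 && i <= length(x)) x[i] else 0
      }, numeric(1))
      expected <- if (metric == "mean_dose") mean(vals) else as.numeric(any(vals > 0))
      expect_equal(unname(md$Z[r, metric]), expected)
    }
  }
  # continuously exposed member: mean 4 (or 3.99 for CR) and any = 1
  f_any <- conventional_clogit(sets, co, sh$sim$dispensings, "any_exposure",
                               window_days = 30)
  expect_true(f_any$converged)
  expect_true("any_exposure" %in% names(f_any$beta))
})
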