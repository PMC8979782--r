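#' Incidence-density sampling of matched risk sets
#'
#' For each case (cohort member with the outcome) the index date is the event
#' date; eligible controls are members under follow-up on that date who have
#' not yet had the outcome (a future case may serve as a control before its
#' own event), of the same sex, within the age caliper at the index date, and
#' with a first-dispensing (entry) date within the entry caliper. Two controls
#' (or as many as the pool holds) are drawn uniformly without replacement
#' within each set; sampling is independent across sets, so controls may be
#' reused. Cases with an empty pool are reported, not dropped silently.
#'
#' @param cohort a [build_cohort()] result.
#' @param seed RNG seed; identical seeds give identical sets.
#' @param n_controls target controls per case.
#' @param age_caliper maximum age difference at the index date (years, closed
#'   interval).
#' @param entry_caliper maximum difference between first-dispensing dates
#'   (days, closed interval).
#' @return list of class `ncc_sets`: `sets` (data.frame `set_id`, `role`,
#'   `patient_id`, `index_date`) and `unmatched` (case ids with empty pools).
#' @export
sample_risk_sets <- function(cohort, seed = 1L, n_controls = 2L,
                             age_caliper = 2, entry_caliper = 30) {
  m <- cohort$members
  if (!any(m$event)) stop("cohort has no cases", call. = FALSE)
  set.seed(seed)
  entry <- as.Date(m$entry_date)
  endd <- entry + m$futime
  age_at_index <- function(i, index) m$age[i] + as.numeric(index - entry[i]) / 365.25
  cases <- which(m$event)
  cases <- cases[order(endd[cases], m$patient_id[cases])]
  sets <- list(); unmatched <- character(0); sid <- 0L
  for (ci in cases) {
    index <- endd[ci]
    at_risk <- entry <= index & ifelse(m$event, endd > index, endd >= index)
    at_risk[ci] <- FALSE
    pool <- which(at_risk & m$sexF == m$sexF[ci])
    if (length(pool)) {
      da <- abs(vapply(pool, age_at_index, numeric(1), index = index) -
                  age_at_index(ci, index))
      de <- abs(as.numeric(entry[pool] - entry[ci]))
      pool <- pool[da <= age_caliper & de <= entry_caliper]
    }
    if (!length(pool)) {
      unmatched <- c(unmatched, m$patient_id[ci])
      next
    }
    picked <- if (length(pool) <= n_controls) pool else
      pool[sample.int(length(pool), n_controls)]
    sid <- sid + 1L
    sets[[sid]] <- data.frame(
      set_id = sid,
      role = c("case", rep("control", length(picked))),
      patient_id = c(m$patient_id[ci], m$patient_id[picked]),
      index_date = index)
  }
  if (!length(sets)) stop("no matchable cases", call. = FALSE)
  structure(list(sets = do.call(rbind, sets), unmatched = unmatched,
                 n_controls = n_controls, age_caliper = age_caliper,
                 entry_caliper = entry_caliper, seed = seed),
            class = "ncc_sets")
}

#' @export
print.ncc_sets <- function(x, ...) {
  cat(sprintf("ncc_sets: %d matched set(s), %d unmatched case(s)\n",
              length(unique(x$sets$set_id)), length(x$unmatched)))
  invisible(x)
}

# Member-level covariates and WCE terms at the index date. For member with
# entry e and index i, lag t before the index corresponds to exposure day
# (i - e) - t of that member's series; days outside follow-up carry dose 0.
ncc_member_rows <- function(sets, cohort, dispensings, basis = NULL,
                            exposure_metric = NULL, metric_window = NULL,
                            config = cohort$config) {
  s <- sets$sets
  m <- cohort$members
  rowix <- match(s$patient_id, m$patient_id)
  entry <- as.Date(m$entry_date)[rowix]
  offset <- as.numeric(as.Date(s$index_date) - entry)    # days from entry to index
  disp_by <- split(seq_len(nrow(dispensings)), dispensings$patient_id)

  n <- nrow(s)
  cols <- list(); cn <- character(0)
  if (!is.null(basis)) {
    J <- ncol(basis$B)
    D <- matrix(0, n, J, dimnames = list(NULL, colnames(basis$B)))
    for (r in seq_len(n)) {
      if (offset[r] < 1) next                             # entered on the index date
      x <- cohort$exposure[[s$patient_id[r]]]$doses
      D[r, ] <- wce_covariates(x, basis, offset[r])
    }
    for (j in seq_len(J)) cols[[length(cols) + 1L]] <- D[, j]
    cn <- c(cn, colnames(basis$B))
  }
  if (!is.null(exposure_metric)) {
    v <- numeric(n)
    for (r in seq_len(n)) {
      x <- cohort$exposure[[s$patient_id[r]]]$doses
      lags <- seq_len(metric_window)
      xi <- offset[r] - lags + 1L                         # series index of day (i - e - t)
      vals <- numeric(length(xi))
      ok <- xi >= 1 & xi <= length(x)
      vals[ok] <- x[xi[ok]]
      v[r] <- if (exposure_metric == "mean_dose") mean(vals) else as.numeric(any(vals > 0))
    }
    cols[[length(cols) + 1L]] <- v
    cn <- c(cn, exposure_metric)
  }
  # adjustment covariates at the index date
  ht <- chf <- dm <- nco <- st30 <- numeric(n)
  for (r in seq_len(n)) {
    id <- s$patient_id[r]
    d <- if (!is.null(disp_by[[id]])) dispensings[disp_by[[id]], , drop = FALSE] else
      dispensings[0, , drop = FALSE]
    cv <- derive_covariates(d, as.Date(s$index_date[r]), config)
    ht[r] <- cv$hypertension; chf[r] <- cv$chf; dm[r] <- cv$diabetes
    nco[r] <- cv$comorbidity_count
    sd_ <- cohort$statin[[id]]$doses
    days <- (offset[r] - 30):(offset[r] - 1)
    days <- days[days >= 0 & days < length(sd_)]
    st30[r] <- as.numeric(length(days) > 0 && any(sd_[days + 1L] > 0))
  }
  hs <- m$health_services_12m[rowix]
  cols <- c(cols, list(ht, chf, dm, nco, st30, log(hs + 1)))
  cn <- c(cn, "hypertension", "chf", "diabetes", "comorbidity_count",
          "statin30", "log_health_services")
  Z <- do.call(cbind, cols)
  colnames(Z) <- cn
  list(Z = Z, grp = as.integer(factor(s$set_id)), death = s$role == "case",
       basis = basis, n = n)
}

#' Conditional logistic WCE model on matched sets
#'
#' For each member `k` of set `s` the linear predictor at the set's index
#' date is `sum_j theta_j D_j(index) + beta' Z_k`; the conditional likelihood
#' contribution is `exp(eta_case) / sum_k exp(eta_k)`. Maximised by
#' Newton-Raphson (this is the one-case-per-set special case of the grouped
#' partial likelihood, so the Cox machinery is reused with exact tie-free
#' groups). The adjustment set is the comorbidity indicators and count in the
#' 12 months before the index date, any statin use in the 30 days before the
#' index date, and log(health services + 1) as a severity proxy. Weight
#' function and pattern hazard ratios are available through
#' [weight_function_ci()] and [pattern_hr()] applied to the returned fit.
#'
#' @param sets a [sample_risk_sets()] result.
#' @param cohort the cohort the sets were drawn from.
#' @param dispensings the dispensing claims table (for index-date covariates).
#' @param basis a [spline_basis()] for the WCE terms.
#' @param config a [claims_config()]; defaults to the cohort's.
#' @return a `wce_fit` with `model = "clogit"`.
#' @export
fit_wce_clogit <- function(sets, cohort, dispensings, basis,
                           config = cohort$config) {
  md <- ncc_member_rows(sets, cohort, dispensings, basis, config = config)
  data <- clogit_data(md)
  fit <- newton_fit(data, ties = "breslow")
  finish_fit(fit, data, ties = "breslow", model = "clogit")
}

#' Conventional conditional-logistic comparator models
#'
#' Fixed-in-time exposure summarised over a window before the index date:
#' mean daily dose or any-exposure indicator, with the same adjustment set as
#' [fit_wce_clogit()].
#'
#' @inheritParams fit_wce_clogit
#' @param metric `"mean_dose"` or `"any_exposure"`.
#' @param window_days window length before the index date (days); the
#'   conventional grid is 7, 15, 30, 60, 75, 90, but any positive window is
#'   accepted.
#' @return a `wce_fit` with `model = "clogit"` and empty `theta`.
#' @export
conventional_clogit <- function(sets, cohort, dispensings,
                                metric = c("mean_dose", "any_exposure"),
                                window_days = 30, config = cohort$config) {
  metric <- match.arg(metric)
  stopifnot(window_days >= 1)
  md <- ncc_member_rows(sets, cohort, dispensings, basis = NULL,
                        exposure_metric = metric, metric_window = window_days,
                        config = config)
  data <- clogit_data(md)
  fit <- newton_fit(data, ties = "breslow")
  out <- finish_fit(fit, data, ties = "breslow", model = "clogit")
  out$metric <- metric; out$window_days <- window_days
  out
}

# wrap member rows in the grouped-likelihood data layout; drop sets that are
# all-concordant in every column (they contribute no information but are kept
# -- the likelihood handles them; only fully degenerate single-member sets are
# removed).
clogit_data <- function(md) {
  keep <- ave(seq_along(md$grp), md$grp, FUN = length) > 1
  structure(list(
    Z = md$Z[keep, , drop = FALSE], grp = md$grp[keep], death = md$death[keep],
    member = seq_len(sum(keep)),
    group_day = tapply(rep(0, sum(keep)), md$grp[keep], function(z) 0),
    group_stratum = NULL,
    n_events = sum(md$death[keep]), n_members = sum(keep),
    basis = md$basis, covariates = setdiff(colnames(md$Z),
                                           if (!is.null(md$basis)) colnames(md$basis$B) else character(0)),
    statin = FALSE, exposure_metric = NULL, metric_window = NULL
  ), class = c("ncc_clogit_data", "wce_cox_data"))
}
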