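#' Risk-set data for a stratified WCE Cox model
#'
#' Expands a cohort into the arrays the partial likelihood needs: one row per
#' (event time, at-risk member) pair, within stratum, on the follow-up time
#' scale (days since entry). Covariate columns are, in order: the WCE spline
#' covariates `D_j(u)` (when a basis is supplied), the fixed baseline
#' covariates, the daily statin indicator, and optionally a scalar
#' conventional exposure metric. Time-varying values on the risk interval
#' `(u-1, u]` are those of exposure day `u-1`; WCE covariates at `u` use doses
#' up to day `u-1` (minimum lag one day).
#'
#' @param cohort a [build_cohort()] result (or a compatible list with
#'   `members`, `exposure`, `statin`).
#' @param basis a [spline_basis()], or `NULL` for models without WCE terms.
#' @param covariates names of fixed covariate columns in `cohort$members`.
#' @param statin logical; include the daily statin indicator.
#' @param exposure_metric `NULL`, or one of `"current_dose"`, `"mean_dose"`,
#'   `"cumulative_dose"` for conventional comparator models.
#' @param metric_window lag window (days) for the windowed metrics.
#' @return object of class `wce_cox_data` (see Details in the source); used by
#'   [fit_wce_cox()] and [cox_loglik_parts()].
#' @export
wce_cox_data <- function(cohort, basis = NULL,
                         covariates = c("age", "sexF", "hypertension", "chf",
                                        "diabetes", "comorbidity_count"),
                         statin = TRUE,
                         exposure_metric = NULL, metric_window = NULL) {
  m <- cohort$members
  n <- nrow(m)
  if (!n) stop("empty cohort", call. = FALSE)
  L <- m$futime
  ev <- m$event
  strat <- as.character(m$stratum)
  ids <- as.character(m$patient_id)
  if (!any(ev)) stop("no events in cohort; nothing to fit", call. = FALSE)

  gt <- unique(data.frame(stratum = strat[ev], day = L[ev]))
  gt <- gt[order(gt$stratum, gt$day), , drop = FALSE]
  nG <- nrow(gt)

  idx_list <- vector("list", nG)
  for (g in seq_len(nG))
    idx_list[[g]] <- which(strat == gt$stratum[g] & L >= gt$day[g])
  sizes <- lengths(idx_list)
  if (any(sizes == 0L)) stop("empty risk set; data are inconsistent", call. = FALSE)
  flat_i <- unlist(idx_list, use.names = FALSE)
  flat_g <- rep.int(seq_len(nG), sizes)
  death <- ev[flat_i] & L[flat_i] == gt$day[flat_g]

  # per-member group ranges within stratum (groups with day <= L_i)
  member_groups <- function(i) {
    gs <- which(gt$stratum == strat[i] & gt$day <= L[i])
    gs
  }

  cols <- list(); colnames_out <- character(0)
  if (!is.null(basis)) {
    J <- ncol(basis$B)
    Dk <- lapply(seq_len(J), function(j) matrix(0, n, nG))
    Tw <- basis$window
    for (i in seq_len(n)) {
      gs <- member_groups(i)
      if (!length(gs)) next
      # lag-embed the dose series at the needed event days only
      du <- gt$day[gs]
      xpad <- c(rep(0, Tw), cohort$exposure[[ids[i]]]$doses[seq_len(L[i])])
      M <- matrix(xpad[rep(Tw + du, Tw) - rep(seq_len(Tw), each = length(du)) + 1L],
                  length(du), Tw)
      Di <- M %*% basis$B
      for (j in seq_len(J)) Dk[[j]][i, gs] <- Di[, j]
    }
    for (j in seq_len(J)) cols[[length(cols) + 1L]] <- Dk[[j]][cbind(flat_i, flat_g)]
    colnames_out <- c(colnames_out, colnames(basis$B))
  }
  for (v in covariates) {
    cols[[length(cols) + 1L]] <- as.numeric(m[[v]])[flat_i]
    colnames_out <- c(colnames_out, v)
  }
  if (isTRUE(statin)) {
    Sb <- matrix(0, n, nG)
    for (i in seq_len(n)) {
      gs <- member_groups(i)
      if (length(gs)) Sb[i, gs] <- cohort$statin[[ids[i]]]$doses[gt$day[gs]]
    }
    cols[[length(cols) + 1L]] <- Sb[cbind(flat_i, flat_g)]
    colnames_out <- c(colnames_out, "statin")
  }
  if (!is.null(exposure_metric)) {
    Mx <- matrix(0, n, nG)
    for (i in seq_len(n)) {
      gs <- member_groups(i)
      if (!length(gs)) next
      v <- exposure_metric_series(cohort$exposure[[ids[i]]]$doses[seq_len(L[i])],
                                  exposure_metric, metric_window)
      Mx[i, gs] <- v[gt$day[gs]]
    }
    cols[[length(cols) + 1L]] <- Mx[cbind(flat_i, flat_g)]
    colnames_out <- c(colnames_out, exposure_metric)
  }
  Z <- do.call(cbind, cols)
  colnames(Z) <- colnames_out

  structure(list(
    Z = Z, grp = flat_g, death = death, member = flat_i,
    rows_by_g = split(seq_along(flat_g), flat_g),
    group_day = gt$day, group_stratum = gt$stratum,
    n_events = sum(death), n_members = n,
    basis = basis, covariates = covariates,
    statin = isTRUE(statin), exposure_metric = exposure_metric,
    metric_window = metric_window,
    member_ids = ids, futime = L, event = ev, stratum = strat
  ), class = "wce_cox_data")
}

#' Partial likelihood, score and information at given coefficients
#'
#' Evaluates the stratified Cox log partial likelihood (Efron or Breslow tie
#' handling), its gradient and the observed information for a risk-set layout
#' built by [wce_cox_data()] — or for conditional-logistic data where each
#' group is a matched set with one case. Exposed so the likelihood machinery
#' can be verified against brute-force and finite-difference computations.
#'
#' @param data a `wce_cox_data` (or `ncc_clogit_data`) object.
#' @param par coefficient vector, one per column of `data$Z`.
#' @param ties `"efron"` or `"breslow"`.
#' @return list with `loglik`, `score`, `information`.
#' @export
cox_loglik_parts <- function(data, par, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  Z <- data$Z; grp <- data$grp; death <- data$death
  p <- ncol(Z)
  stopifnot(length(par) == p)
  eta <- drop(Z %*% par)
  eta <- eta - max(eta)                # guard overflow; PL is shift-invariant
  w <- exp(eta)
  rows_by_g <- if (!is.null(data$rows_by_g)) data$rows_by_g else
    split(seq_along(grp), grp)
  nG <- length(rows_by_g)
  ll <- 0; U <- numeric(p); I <- matrix(0, p, p)
  for (g in seq_len(nG)) {
    rows <- rows_by_g[[g]]
    dr <- rows[death[rows]]
    d <- length(dr)
    Zg <- Z[rows, , drop = FALSE]
    wg <- w[rows]
    S0 <- sum(wg)
    S1 <- drop(crossprod(Zg, wg))
    S2 <- crossprod(Zg * wg, Zg)
    ll <- ll + sum(eta[dr])
    U <- U + drop(colSums(Z[dr, , drop = FALSE]))
    if (ties == "breslow" || d == 1L) {
      kk <- if (ties == "breslow") rep(0, d) else 0
      reps <- if (ties == "breslow") d else 1L
      ll <- ll - reps * log(S0)
      U <- U - reps * S1 / S0
      I <- I + reps * (S2 / S0 - tcrossprod(S1 / S0))
    } else {
      Zd <- Z[dr, , drop = FALSE]
      wd <- w[dr]
      S0d <- sum(wd)
      S1d <- drop(crossprod(Zd, wd))
      S2d <- crossprod(Zd * wd, Zd)
      for (k in seq_len(d) - 1L) {
        f <- k / d
        phi0 <- S0 - f * S0d
        phi1 <- S1 - f * S1d
        phi2 <- S2 - f * S2d
        ll <- ll - log(phi0)
        U <- U - phi1 / phi0
        I <- I + phi2 / phi0 - tcrossprod(phi1 / phi0)
      }
    }
  }
  list(loglik = ll, score = U, information = I)
}

# Newton-Raphson with step-halving on the (conditional/partial) likelihood.
newton_fit <- function(data, ties = "efron", init = NULL,
                       max_iter = 30L, tol_score = 1e-8, tol_ll = 1e-10) {
  p <- ncol(data$Z)
  par <- if (is.null(init)) numeric(p) else init
  parts <- cox_loglik_parts(data, par, ties)
  ll <- parts$loglik
  ll0 <- cox_loglik_parts(data, numeric(p), ties)$loglik
  converged <- FALSE; iter <- 0L
  repeat {
    iter <- iter + 1L
    step <- tryCatch(solve(parts$information, parts$score),
                     error = function(e)
                       stop("fit-failure: singular information matrix (possible separation)",
                            call. = FALSE))
    fac <- 1
    repeat {
      cand <- par + fac * step
      cand_parts <- cox_loglik_parts(data, cand, ties)
      if (is.finite(cand_parts$loglik) && cand_parts$loglik >= ll - 1e-12) break
      fac <- fac / 2
      if (fac < 1e-10)
        stop("fit-failure: step-halving failed to improve the likelihood",
             call. = FALSE)
    }
    rel <- abs(cand_parts$loglik - ll) / (abs(ll) + 1e-12)
    par <- cand; ll <- cand_parts$loglik; parts <- cand_parts
    if (max(abs(parts$score)) < tol_score || rel < tol_ll) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  if (!converged)
    warning("fit did not converge in ", max_iter,
            " iterations (max |score| = ", format(max(abs(parts$score))), ")")
  if (max(abs(par)) > 15)
    warning("monotone-likelihood warning: very large coefficients suggest separation")
  vcov <- solve(parts$information)
  list(par = par, vcov = vcov, loglik = ll, loglik_null = ll0,
       score = parts$score, information = parts$information,
       iter = iter, converged = converged)
}

#' Fit a stratified weighted-cumulative-exposure Cox model
#'
#' Maximizes the stratified Cox partial likelihood in which each member's
#' linear predictor at risk-set day `u` is
#' `sum_j theta_j D_j(u) + beta' Z(u)`: spline-projected weighted past doses
#' plus fixed baseline covariates and the daily statin indicator. Risk sets
#' are formed within severity stratum on the days-since-entry time scale.
#' Newton-Raphson with step-halving; convergence when the maximum absolute
#' score falls below `1e-8` or the relative log-partial-likelihood change
#' below `1e-10`. The covariance is the inverse observed information.
#'
#' @inheritParams wce_cox_data
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param data optionally, a prebuilt [wce_cox_data()] object (then `cohort`,
#'   `basis` etc. are ignored).
#' @return object of class `wce_fit` with elements `theta` (spline
#'   coefficients), `beta` (covariate log-HRs), `coef` (both), `vcov`,
#'   `loglik`, `loglik_null`, `bic`, `n_events`, `basis`, `ties`, `iter`,
#'   `converged`, and the risk-set `data` (retained for diagnostics).
#' @export
fit_wce_cox <- function(cohort = NULL, basis = NULL,
                        covariates = c("age", "sexF", "hypertension", "chf",
                                       "diabetes", "comorbidity_count"),
                        statin = TRUE, ties = c("efron", "breslow"),
                        data = NULL) {
  ties <- match.arg(ties)
  if (is.null(data))
    data <- wce_cox_data(cohort, basis, covariates, statin)
  fit <- newton_fit(data, ties)
  finish_fit(fit, data, ties, model = "cox")
}

finish_fit <- function(fit, data, ties, model) {
  p <- ncol(data$Z)
  nm <- colnames(data$Z)
  names(fit$par) <- nm
  dimnames(fit$vcov) <- list(nm, nm)
  J <- if (!is.null(data$basis)) ncol(data$basis$B) else 0L
  theta <- if (J) fit$par[seq_len(J)] else numeric(0)
  beta <- if (p > J) fit$par[(J + 1L):p] else numeric(0)
  structure(list(
    theta = theta, beta = beta, coef = fit$par, vcov = fit$vcov,
    loglik = fit$loglik, loglik_null = fit$loglik_null,
    bic = -2 * fit$loglik + p * log(data$n_events),
    n_events = data$n_events, basis = data$basis, ties = ties,
    iter = fit$iter, converged = fit$converged, score = fit$score,
    information = fit$information, model = model, data = data
  ), class = "wce_fit")
}

#' @export
print.wce_fit <- function(x, ...) {
  cat(sprintf("%s model (%s ties): %d events, logPL = %.3f, BIC = %.2f%s\n",
              if (length(x$theta)) "WCE" else "conventional",
              x$ties, x$n_events, x$loglik, x$bic,
              if (x$converged) "" else " [NOT CONVERGED]"))
  if (length(x$theta))
    cat(sprintf("  weight function: window %d days, %d interior knot(s)%s\n",
                x$basis$window, x$basis$n_knots,
                if (x$basis$constrained) ", right-constrained" else ""))
  if (length(x$beta)) {
    se <- sqrt(diag(x$vcov))[names(x$beta)]
    tab <- data.frame(coef = x$beta, HR = exp(x$beta), se = se,
                      p = 2 * stats::pnorm(-abs(x$beta / se)))
    print(round(tab, 4))
  }
  invisible(x)
}

#' Covariate hazard-ratio table from a fit
#'
#' @param fit a `wce_fit` or `clogit_fit`.
#' @param level confidence level.
#' @return data.frame: term, estimate (log scale), HR, lower, upper, p.
#' @export
covariate_table <- function(fit, level = 0.95) {
  b <- fit$beta
  se <- sqrt(diag(fit$vcov))[names(b)]
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(term = names(b), estimate = unname(b), se = unname(se),
             hr = exp(unname(b)),
             lower = exp(unname(b) - z * se), upper = exp(unname(b) + z * se),
             p = 2 * stats::pnorm(-abs(unname(b) / se)),
             row.names = NULL)
}

#' Conventional (non-WCE) Cox comparator models
#'
#' Fits the same stratified Cox machinery with a single scalar time-varying
#' exposure covariate: the current day's dose, or the mean or cumulative dose
#' over a fixed lag window before the current day.
#'
#' @inheritParams fit_wce_cox
#' @param metric `"current_dose"`, `"mean_dose"` or `"cumulative_dose"`.
#' @param window_days lag window for the windowed metrics (2 to 90 days).
#' @return a `wce_fit` (with empty `theta`); BIC comparable with WCE fits.
#' @export
conventional_cox <- function(cohort, metric = c("current_dose", "mean_dose",
                                                "cumulative_dose"),
                             window_days = NULL,
                             covariates = c("age", "sexF", "hypertension", "chf",
                                            "diabetes", "comorbidity_count"),
                             statin = TRUE, ties = c("efron", "breslow")) {
  metric <- match.arg(metric)
  ties <- match.arg(ties)
  if (metric != "current_dose") {
    if (is.null(window_days) || window_days < 2 || window_days > 90)
      stop("window_days must be in [2, 90] for windowed metrics", call. = FALSE)
  }
  data <- wce_cox_data(cohort, basis = NULL, covariates = covariates,
                       statin = statin, exposure_metric = metric,
                       metric_window = window_days)
  fit <- newton_fit(data, ties)
  out <- finish_fit(fit, data, ties, model = "cox")
  out$metric <- metric; out$window_days <- window_days
  out
}

#' Fit and rank candidate weight-function shapes by BIC
#'
#' Fits one WCE model per candidate `(window, knots, constrained)` triple and
#' ranks them by BIC (`-2 logPL + p log(n_events)`), ascending. Ties are
#' broken toward fewer free parameters, then the smaller window. Candidates
#' whose fit fails are dropped with a message.
#'
#' @inheritParams fit_wce_cox
#' @param candidates data.frame with columns `window`, `knots`, `constrained`.
#' @return list of class `wce_selection`: `table` (ranked data.frame with BIC)
#'   and `fits` (in ranked order).
#' @export
select_model <- function(cohort, candidates,
                         covariates = c("age", "sexF", "hypertension", "chf",
                                        "diabetes", "comorbidity_count"),
                         statin = TRUE, ties = "efron") {
  stopifnot(nrow(candidates) >= 1)
  fits <- list(); rowsok <- integer(0)
  for (i in seq_len(nrow(candidates))) {
    b <- try(spline_basis(candidates$window[i], candidates$knots[i],
                          isTRUE(candidates$constrained[i])), silent = TRUE)
    f <- if (inherits(b, "try-error")) b else
      try(fit_wce_cox(cohort, b, covariates, statin, ties), silent = TRUE)
    if (inherits(f, "try-error")) {
      message("candidate ", i, " dropped: ", attr(f, "condition")$message)
      next
    }
    fits[[length(fits) + 1L]] <- f
    rowsok <- c(rowsok, i)
  }
  if (!length(fits)) stop("all candidates failed to fit", call. = FALSE)
  tab <- candidates[rowsok, , drop = FALSE]
  tab$n_params <- vapply(fits, function(f) length(f$coef), numeric(1))
  tab$loglik <- vapply(fits, function(f) f$loglik, numeric(1))
  tab$bic <- vapply(fits, function(f) f$bic, numeric(1))
  ord <- order(tab$bic, tab$n_params, tab$window)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits[ord]), class = "wce_selection")
}

#' @export
print.wce_selection <- function(x, ...) {
  cat("WCE model selection (BIC ascending):\n")
  print(x$table)
  invisible(x)
}
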