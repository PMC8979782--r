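#' Schoenfeld residuals of a fitted model
#'
#' One row per event: `z_i - zbar(t_i)`, the covariates of the failing
#' subject minus the risk-weighted mean over the risk set at the event time.
#' With Efron ties the mean is the average of the tie-adjusted risk-set means
#' over the tied deaths, and the attached risk-set variance is the matching
#' tie-adjusted average.
#'
#' @param fit a `wce_fit` from [fit_wce_cox()] or [conventional_cox()].
#' @return list with `residuals` (events x parameters matrix), `times`
#'   (event day per row) and `V` (per-event risk-set covariance matrices).
#' @export
schoenfeld_residuals <- function(fit) {
  data <- fit$data
  Z <- data$Z; grp <- data$grp; death <- data$death
  p <- ncol(Z)
  eta <- drop(Z %*% fit$coef)
  w <- exp(eta - max(eta))
  rows_by_g <- if (!is.null(data$rows_by_g)) data$rows_by_g else
    split(seq_along(grp), grp)
  res <- NULL; times <- NULL; Vlist <- list()
  for (g in seq_along(rows_by_g)) {
    rows <- rows_by_g[[g]]
    dr <- rows[death[rows]]
    d <- length(dr)
    Zg <- Z[rows, , drop = FALSE]
    wg <- w[rows]
    S0 <- sum(wg); S1 <- drop(crossprod(Zg, wg))
    S2 <- crossprod(Zg * wg, Zg)
    if (fit$ties == "efron" && d > 1L) {
      Zd <- Z[dr, , drop = FALSE]; wd <- w[dr]
      S0d <- sum(wd); S1d <- drop(crossprod(Zd, wd))
      S2d <- crossprod(Zd * wd, Zd)
      zb <- matrix(0, p, d); Vsum <- matrix(0, p, p)
      for (k in seq_len(d) - 1L) {
        f <- k / d
        phi0 <- S0 - f * S0d
        phi1 <- (S1 - f * S1d) / phi0
        zb[, k + 1L] <- phi1
        Vsum <- Vsum + (S2 - f * S2d) / phi0 - tcrossprod(phi1)
      }
      zbar <- rowMeans(zb)
      Vk <- Vsum / d                   # average tie-adjusted risk-set variance
    } else {
      zbar <- S1 / S0
      Vk <- S2 / S0 - tcrossprod(zbar)
    }
    r <- sweep(Z[dr, , drop = FALSE], 2, zbar)
    res <- rbind(res, r)
    times <- c(times, rep(data$group_day[g], d))
    for (k in seq_len(d)) Vlist[[length(Vlist) + 1L]] <- Vk
  }
  list(residuals = res, times = times, V = Vlist)
}

#' Proportional-hazards diagnostics from Schoenfeld residuals
#'
#' Score test of a time-varying coefficient `beta(t) = beta + theta g(t)` at
#' `theta = 0`: the slope of the Schoenfeld residuals on a transform `g` of
#' follow-up time. The score is `u = sum_k (g_k - gbar) s_k` over the
#' per-event residuals and its exact variance uses the per-event risk-set
#' covariances `V_k` with the estimated-`beta` correction,
#' `Var(u) = sum g^2 V_k - (sum g V_k) I^{-1} (sum g V_k)`. Per-parameter and
#' global statistics are compared to chi-squared laws. The default transform
#' is one minus the Kaplan-Meier estimate of the follow-up distribution,
#' evaluated just before each event time, which spreads event times evenly
#' under heavy censoring.
#'
#' @param fit a `wce_fit` from [fit_wce_cox()] or [conventional_cox()].
#' @param transform `"km"`, `"rank"` or `"identity"`.
#' @return data.frame with one row per parameter plus a `GLOBAL` row:
#'   `term`, `chisq`, `df`, `p`.
#' @export
schoenfeld_test <- function(fit, transform = c("km", "rank", "identity")) {
  transform <- match.arg(transform)
  data <- fit$data
  if (data$n_events < 3L)
    stop("untestable: fewer than 3 events", call. = FALSE)
  sr <- schoenfeld_residuals(fit)
  res <- sr$residuals; times <- sr$times; Vlist <- sr$V
  p <- ncol(res)
  d_tot <- nrow(res)
  gt <- switch(transform,
    identity = times,
    rank = rank(times, ties.method = "average"),
    km = {
      km <- km_left(data$futime, data$event)
      1 - km(times)
    })
  gc_ <- gt - mean(gt)
  u <- drop(crossprod(gc_, res))
  I_gg <- matrix(0, p, p); I_gb <- matrix(0, p, p)
  for (k in seq_len(d_tot)) {
    Vk <- Vlist[[k]]
    I_gg <- I_gg + gc_[k]^2 * Vk
    I_gb <- I_gb + gc_[k] * Vk
  }
  Vtheta <- I_gg - I_gb %*% fit$vcov %*% I_gb
  chisq <- u^2 / diag(Vtheta)
  global <- drop(t(u) %*% solve(Vtheta, u))
  out <- data.frame(term = c(colnames(res), "GLOBAL"),
                    chisq = c(chisq, global),
                    df = c(rep(1L, p), p))
  out$p <- stats::pchisq(out$chisq, out$df, lower.tail = FALSE)
  rownames(out) <- NULL
  out
}

# Kaplan-Meier estimate of the follow-up survival curve, returned as a
# left-continuous step function (value just before t).
km_left <- function(futime, event) {
  ut <- sort(unique(futime[event]))
  surv <- numeric(length(ut)); s <- 1
  for (k in seq_along(ut)) {
    at_risk <- sum(futime >= ut[k])
    d <- sum(futime == ut[k] & event)
    s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  function(t) {
    idx <- findInterval(t - 1e-9, ut)            # strictly-before lookup
    c(1, surv)[idx + 1L]
  }
}
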