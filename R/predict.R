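#' Estimated weight function with pointwise confidence bands
#'
#' `w_hat(t) = b(t)' theta_hat` at integer lags `1..window`, with pointwise
#' variance `b(t)' Sigma_theta b(t)` (delta method on the spline coefficients)
#' and normal-quantile bands.
#'
#' @param fit a `wce_fit` (or `clogit_fit`) with WCE terms.
#' @param level confidence level (default 0.95).
#' @return data.frame: `lag`, `weight`, `se`, `lower`, `upper`.
#' @export
weight_function_ci <- function(fit, level = 0.95) {
  if (!length(fit$theta)) stop("fit has no WCE terms", call. = FALSE)
  B <- fit$basis$B
  Sig <- fit$vcov[names(fit$theta), names(fit$theta), drop = FALSE]
  ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("unstable-fit: spline covariance is not positive semidefinite",
         call. = FALSE)
  w <- drop(B %*% fit$theta)
  v <- rowSums((B %*% Sig) * B)
  se <- sqrt(pmax(v, 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(lag = seq_len(nrow(B)), weight = w, se = se,
             lower = w - z * se, upper = w + z * se)
}

#' Hazard ratio for an arbitrary exposure pattern versus non-use
#'
#' For a pattern `x(t)` of daily doses at lags `1..T` before the evaluation
#' day, `HR = exp(sum_t w_hat(t) x(t)) = exp(d' theta_hat)` with
#' `d_j = sum_t B_j(t) x(t)`; the confidence interval is
#' `exp(d' theta +/- z sqrt(d' Sigma d))`. The comparator is the all-zero
#' pattern (non-use), so a zero pattern returns exactly 1.
#'
#' @param fit a `wce_fit` (or `clogit_fit`) with WCE terms.
#' @param pattern numeric vector of doses (g/day) at lags `1, 2, ...`; shorter
#'   patterns are zero-padded to the window.
#' @param level confidence level.
#' @return named numeric: `hr`, `lower`, `upper`.
#' @export
pattern_hr <- function(fit, pattern, level = 0.95) {
  if (!length(fit$theta)) stop("fit has no WCE terms", call. = FALSE)
  Tw <- fit$basis$window
  if (length(pattern) > Tw)
    stop("pattern-window mismatch: pattern longer than the lag window",
         call. = FALSE)
  if (any(pattern < 0)) stop("pattern doses must be >= 0", call. = FALSE)
  x <- c(pattern, rep(0, Tw - length(pattern)))
  d <- drop(crossprod(fit$basis$B, x))
  Sig <- fit$vcov[names(fit$theta), names(fit$theta), drop = FALSE]
  est <- sum(d * fit$theta)
  se <- sqrt(max(0, drop(t(d) %*% Sig %*% d)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(hr = exp(est), lower = exp(est - z * se), upper = exp(est + z * se))
}

#' Hazard-ratio surface over doses, durations and stopping lags
#'
#' Builds the pattern grid behind dose-duration heatmaps and past-use curves:
#' for current use, the pattern is `dose` at lags `1..duration`; for use
#' stopped `s` days ago, the pattern is `dose` at lags `s+1 .. s+duration`
#' (zero elsewhere, truncated at the window, so a stop lag at or beyond the
#' window gives HR exactly 1).
#'
#' @inheritParams pattern_hr
#' @param doses daily doses in g/day.
#' @param durations exposure durations in days.
#' @param stop_lags days since stopping (0 = current use).
#' @return data.frame: `dose`, `duration`, `stop_lag`, `hr`, `lower`, `upper`.
#' @export
hr_surface <- function(fit, doses = 1:4, durations = c(2, 7, 30),
                       stop_lags = 0, level = 0.95) {
  Tw <- fit$basis$window
  grid <- expand.grid(dose = doses, duration = durations, stop_lag = stop_lags,
                      KEEP.OUT.ATTRS = FALSE)
  res <- t(apply(grid, 1, function(r) {
    s <- r[["stop_lag"]]; dur <- r[["duration"]]
    pat <- numeric(Tw)
    lo <- min(s + 1, Tw + 1); hi <- min(s + dur, Tw)
    if (lo <= hi) pat[lo:hi] <- r[["dose"]]
    pattern_hr(fit, pat, level)
  }))
  cbind(grid, data.frame(hr = res[, "hr"], lower = res[, "lower"],
                         upper = res[, "upper"]))
}
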