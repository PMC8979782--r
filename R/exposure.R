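#' Days of supply implied by one dispensing
#'
#' Converts a dispensed tablet count into a supply duration under the
#' maximum-dose assumption: 8 tablets/day for 500 mg immediate-release
#' (8 x 500 mg = 4 g/day) and 6 tablets/day for 665 mg controlled-release
#' (6 x 665 mg = 3.99 g/day). The duration is `floor(quantity / tablets_per_day)`
#' clamped to a minimum of one day. The tablets-per-day convention is
#' overridable because the exact supply-duration function is an analysis
#' choice, isolated here.
#'
#' @param quantity tablet count(s), > 0. Vectorised.
#' @param strength_mg tablet strength(s); must appear in `names(tablets_per_day)`.
#' @param tablets_per_day named numeric vector mapping strength (mg, as
#'   character) to tablets consumed per day.
#' @return integer vector of supply days (>= 1).
#' @export
days_of_supply <- function(quantity, strength_mg,
                           tablets_per_day = c("500" = 8, "665" = 6)) {
  if (any(is.na(quantity)) || any(quantity <= 0))
    stop("quantity must be a positive tablet count", call. = FALSE)
  key <- as.character(strength_mg)
  unknown <- setdiff(unique(key), names(tablets_per_day))
  if (length(unknown))
    stop("unsupported-formulation: no tablets-per-day rule for strength ",
         paste(unknown, collapse = ", "), " mg", call. = FALSE)
  pmax(1L, as.integer(floor(quantity / tablets_per_day[key])))
}

#' Daily dose series from dispensing records under the supply-extension rule
#'
#' Reconstructs a per-patient daily dose series (g/day) on the half-open
#' calendar window `[origin, end)`. A running covered-until pointer advances by
#' the supply days of each dispensing, in dispensing order: a refill dated
#' before the end of current coverage appends its full supply after the
#' current coverage (early refills extend exposure rather than being lost); a
#' refill dated after coverage has lapsed starts new coverage at its own date,
#' leaving the gap days at dose zero. Covered days carry the daily dose of the
#' script that covers them (queue semantics, first dispensed first consumed):
#' 4.0 g/day for 500 mg and 3.99 g/day for 665 mg controlled-release by
#' default. Coverage is truncated at `end`. Dispensings dated before `origin`
#' are processed so that coverage extending into the window is kept, then
#' clipped.
#'
#' @param dispensings data.frame with columns `supply_date` (Date),
#'   `strength_mg`, `quantity`. Rows need not be sorted.
#' @param origin,end Dates delimiting follow-up; day 0 of the series is
#'   `origin`, the last represented day is `end - 1`.
#' @param dose_per_day named numeric vector mapping strength (mg) to the daily
#'   dose in grams assigned to days covered by that strength.
#' @param tablets_per_day passed to [days_of_supply()].
#' @return An object of class `daily_series`: list with `origin`, `end` and
#'   `doses`, a numeric vector of length `end - origin` whose element `d + 1`
#'   is the dose on day `d` after `origin`.
#' @export
build_daily_series <- function(dispensings, origin, end,
                               dose_per_day = c("500" = 4.0, "665" = 3.99),
                               tablets_per_day = c("500" = 8, "665" = 6)) {
  origin <- as.Date(origin); end <- as.Date(end)
  if (end < origin) stop("end must not precede origin", call. = FALSE)
  L <- as.integer(end - origin)
  doses <- numeric(L)
  if (!is.null(dispensings) && nrow(dispensings)) {
    late <- as.Date(dispensings$supply_date) >= end
    if (any(late)) {
      message(sum(late), " dispensing(s) dated on/after end of follow-up skipped")
      dispensings <- dispensings[!late, , drop = FALSE]
    }
  }
  if (is.null(dispensings) || !nrow(dispensings))
    return(structure(list(origin = origin, end = end, doses = doses),
                     class = "daily_series"))
  o <- order(as.Date(dispensings$supply_date))
  day <- as.integer(as.Date(dispensings$supply_date)[o] - origin)  # may be negative
  dur <- days_of_supply(dispensings$quantity[o], dispensings$strength_mg[o],
                        tablets_per_day)
  g <- dose_per_day[as.character(dispensings$strength_mg[o])]
  doses <- coverage_series(day, dur, g, L)
  structure(list(origin = origin, end = end, doses = doses),
            class = "daily_series")
}

# supply-extension core on day offsets: scripts at `day` (sorted, relative to
# the series origin, possibly negative) with supply `dur` and daily dose `g`;
# returns the dose vector over days 0..L-1.
coverage_series <- function(day, dur, g, L) {
  doses <- numeric(L)
  covered_until <- -.Machine$integer.max / 2  # exclusive end of current coverage
  for (k in seq_along(day)) {
    start <- max(day[k], covered_until)
    stop_ <- start + dur[k]
    covered_until <- stop_
    a <- max(start, 0L); b <- min(stop_, L)   # clip to [origin, end)
    if (b > a) doses[(a + 1L):b] <- g[k]
  }
  doses
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf("daily_series: %s to %s (%d days), %d exposed day(s)\n",
              format(x$origin), format(x$end), length(x$doses),
              sum(x$doses > 0)))
  invisible(x)
}

#' Convert a list of daily series to long format
#'
#' @param series named list of `daily_series` (names are patient ids).
#' @return data.frame with columns `patient_id`, `day`, `dose_g` (exposed days
#'   only are retained to keep the artifact compact; absent days are zero).
#' @export
series_to_long <- function(series) {
  out <- lapply(names(series), function(id) {
    d <- series[[id]]$doses
    idx <- which(d > 0)
    if (!length(idx)) return(NULL)
    data.frame(patient_id = id, day = idx - 1L, dose_g = d[idx])
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(patient_id = character(), day = integer(), dose_g = numeric())
  rownames(out) <- NULL
  out
}

# Scalar conventional-exposure series derived from a dose vector:
# value at risk-set day u (1-based) for
#   current_dose    -- the dose on the current day of follow-up, X(u - 1);
#   mean_dose       -- mean of X over the `window` days before the current day;
#   cumulative_dose -- the corresponding sum.
# Days outside the series contribute zero dose.
exposure_metric_series <- function(doses, metric = c("current_dose", "mean_dose",
                                                     "cumulative_dose"),
                                   window = NULL) {
  metric <- match.arg(metric)
  L <- length(doses)
  if (metric == "current_dose") return(doses)
  stopifnot(!is.null(window), window >= 1)
  xpad <- c(rep(0, window), doses)
  cs <- c(0, cumsum(xpad))
  # window before the current day u (current day index c = u - 1):
  # days c - window .. c - 1, i.e. doses indices (u - window) .. (u - 1)
  u <- seq_len(L)
  tot <- cs[window + u] - cs[u]
  if (metric == "mean_dose") tot / window else tot
}
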