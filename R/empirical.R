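# Model-free hazard summaries used as goodness-of-fit diagnostics.
#
# Day convention: a subject whose follow-up ends on day d (death or
# censoring) is counted at risk on day d; continuous times are binned to the
# day they fall in (floor), so day d collects events in [d, d + 1).

.day_counts <- function(time, event, start_day, end_day) {
  fl <- floor(time)
  days <- start_day:end_day
  deaths <- tabulate(fl[event == 1] - start_day + 1L,
                     nbins = length(days))
  ended <- tabulate(fl - start_day + 1L, nbins = length(days))
  before <- sum(fl < start_day)
  # at risk on day d: everyone whose follow-up day is >= d
  at_risk <- length(time) - before - c(0L, cumsum(ended)[-length(days)])
  list(day = days, deaths = deaths, at_risk = at_risk)
}

#' Daily empirical hazard
#'
#' Deaths and at-risk counts per postoperative day, with the observed rate
#' `deaths / at_risk` reported per 1000 patients and day.  Days with an
#' empty risk set get `NA` rates (undefined, not zero).
#'
#' @param time follow-up days since surgery.
#' @param event 1 = died, 0 = censored.
#' @param window integer `c(start_day, end_day)`; default day 0 to the last
#'   observed day.
#' @return a data frame of class `"hazard_series"` with columns `day`,
#'   `deaths`, `at_risk`, `rate` (per 1000).
#' @export
daily_hazard <- function(time, event, window = NULL) {
  if (length(time) == 0L) stop("empty cohort")
  if (is.null(window)) window <- c(0, floor(max(time)))
  if (window[1] < 0) stop("window must start at day 0 or later")
  dc <- .day_counts(time, event, window[1], window[2])
  rate <- ifelse(dc$at_risk > 0, 1000 * dc$deaths / dc$at_risk, NA_real_)
  structure(data.frame(day = dc$day, deaths = dc$deaths,
                       at_risk = dc$at_risk, rate = rate),
            class = c("hazard_series", "data.frame"))
}

#' Peak day of the empirical hazard
#'
#' @param series a `"hazard_series"` from [daily_hazard()].
#' @param search_window optional `c(start, end)` restriction in days.
#' @return list with `day` (earliest maximizer) and `tied` (all maximizers).
#' @export
peak_day <- function(series, search_window = NULL) {
  s <- series
  if (!is.null(search_window))
    s <- s[s$day >= search_window[1] & s$day <= search_window[2], ]
  if (nrow(s) == 0L || all(is.na(s$rate)))
    stop("no defined hazard values in the search window")
  mx <- max(s$rate, na.rm = TRUE)
  tied <- s$day[!is.na(s$rate) & s$rate == mx]
  list(day = tied[1], tied = tied)
}

#' Nelson-Aalen cumulative hazard with pointwise confidence intervals
#'
#' The running sum of daily `deaths / at_risk` with pointwise intervals on
#' the log scale using the standard variance estimate
#' `sum(deaths / at_risk^2)`.
#'
#' @param time,event as in [daily_hazard()].
#' @param horizon last day of the series (default: last observed day).
#' @param level pointwise coverage.
#' @return a `"hazard_series"` data frame with `cum_hazard`, `ci_low`,
#'   `ci_high` columns added.
#' @export
nelson_aalen <- function(time, event, horizon = NULL, level = 0.95) {
  if (length(time) == 0L) stop("empty cohort")
  if (is.null(horizon)) horizon <- floor(max(time))
  s <- daily_hazard(time, event, window = c(0, horizon))
  inc <- ifelse(s$at_risk > 0, s$deaths / s$at_risk, 0)
  H <- cumsum(inc)
  V <- cumsum(ifelse(s$at_risk > 0, s$deaths / s$at_risk^2, 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  pos <- H > 0
  lo <- hi <- H
  lo[pos] <- H[pos] * exp(-z * sqrt(V[pos]) / H[pos])
  hi[pos] <- H[pos] * exp(z * sqrt(V[pos]) / H[pos])
  s$cum_hazard <- H
  s$ci_low <- lo
  s$ci_high <- hi
  s
}

#' Constant-rate check on the late follow-up window
#'
#' Constant-hazard fit on a late window (default days 180-360): the MLE is
#' events per person-day, reported per 1000.  Constancy is checked by a
#' likelihood-ratio test of one rate against two rates split at the window
#' midpoint (df = 1); "approximately constant" corresponds to a
#' non-significant check.
#'
#' @param time,event follow-up extending past the window start.
#' @param window `c(start, end)` in days.
#' @param alpha significance level of the constancy check.
#' @return list of class `"late_window"`: `rate` (per 1000 per day),
#'   `events`, `person_days`, `check` (a `"jp_lrt"`), `constant`.
#' @export
late_window_rate <- function(time, event, window = c(180, 360),
                             alpha = 0.05) {
  start <- window[1]; end <- window[2]; mid <- (start + end) / 2
  pd <- function(a, b) sum(pmax(0, pmin(time, b) - a))
  ev <- function(a, b) sum(event == 1 & time > a & time <= b)
  PD <- pd(start, end); E <- ev(start, end)
  if (PD <= 0) stop("no person-time in the window")
  pois_ll <- function(e, p) if (e == 0) 0 else e * log(e / p) - e
  r <- E / PD
  ll1 <- pois_ll(ev(start, mid), pd(start, mid)) +
    pois_ll(ev(mid, end), pd(mid, end))
  ll0 <- pois_ll(E, PD)
  check <- .jp_lrt(ll0, ll1, df = 1L,
                   sprintf("constant hazard on days %g-%g", start, end))
  structure(list(rate = 1000 * r, events = E, person_days = PD,
                 check = check, constant = check$p_value >= alpha),
            class = "late_window")
}

#' @export
print.late_window <- function(x, ...) {
  cat(sprintf("Late-window death rate: %.3f per 1000 patients and day\n",
              x$rate))
  cat(sprintf("  %d deaths over %.0f person-days\n", x$events,
              x$person_days))
  cat(sprintf("  constancy check: p = %.3g (%s)\n", x$check$p_value,
              if (x$constant) "approximately constant" else
                "evidence of trend"))
  invisible(x)
}
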