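#' Join-point hazard parameters
#'
#' Construct and validate the parameter set of the join-point postoperative
#' hazard model.  The hazard declines linearly from `acute` at the
#' acute-phase origin (postoperative day `origin`, default 3) down to
#' `background` at the join point `shift` (the "phase shift time"), and is
#' constant at `background` thereafter.
#'
#' All rates are on the internal scale of events per person-day.  The
#' conventional reporting scale of deaths per 1000 patients and day is applied
#' only when printing or when explicitly requested (`per1000 = TRUE` in the
#' accessors of fitted models).
#'
#' @param acute hazard at the acute-phase origin, events per person-day.
#' @param background plateau hazard after the phase shift, events per
#'   person-day.  Must satisfy `acute >= background >= 0`.
#' @param shift phase shift time, days since surgery; must exceed `origin`.
#' @param origin acute-phase start, days since surgery.  Fixed by design
#'   (the empirical daily hazard peaks at day 3), not estimated.
#'
#' @return An object of class `"jp_params"`: a named list with elements
#'   `acute`, `background`, `shift`, `origin`.
#' @examples
#' p <- jp_params(acute = 0.917e-3, background = 0.185e-3, shift = 23.8)
#' jp_hazard(c(3, 13.4, 23.8, 100), p) * 1000
#' @export
jp_params <- function(acute, background, shift, origin = 3) {
  stopifnot(is.numeric(acute), is.numeric(background), is.numeric(shift),
            is.numeric(origin), length(acute) == 1L, length(background) == 1L,
            length(shift) == 1L, length(origin) == 1L)
  if (!is.finite(acute) || !is.finite(background) || !is.finite(shift) ||
      !is.finite(origin))
    stop("jp_params: all parameters must be finite")
  if (background < 0)
    stop("jp_params: background rate must be non-negative")
  if (acute < background)
    stop("jp_params: acute rate must be >= background rate ",
         "(the model is a decline to a plateau)")
  if (shift <= origin)
    stop("jp_params: phase shift time must exceed the origin day")
  structure(list(acute = acute, background = background,
                 shift = shift, origin = origin),
            class = "jp_params")
}

#' @export
print.jp_params <- function(x, ...) {
  cat("Join-point hazard parameters (rates per 1000 patients and day):\n")
  cat(sprintf("  acute phase death rate (day %g): %.3f\n",
              x$origin, 1000 * x$acute))
  cat(sprintf("  background death rate:           %.3f\n", 1000 * x$background))
  cat(sprintf("  phase shift time:                %.1f days\n", x$shift))
  invisible(x)
}

.check_params <- function(params) {
  if (!inherits(params, "jp_params")) {
    if (is.list(params) &&
        all(c("acute", "background", "shift", "origin") %in% names(params)))
      params <- jp_params(params$acute, params$background,
                          params$shift, params$origin)
    else stop("expected a 'jp_params' object")
  }
  params
}

.check_domain <- function(t, origin) {
  if (any(!is.finite(t))) stop("times must be finite")
  if (any(t < origin - 1e-12))
    stop("time before the acute-phase origin (day ", origin,
         "): the model is undefined there")
}

#' Join-point hazard and derived quantities
#'
#' Pure functions of a [jp_params()] parameter set: the hazard itself, the
#' cumulative hazard since the acute-phase origin, the conditional survival
#' given being alive at the origin, and the inverse cumulative hazard used
#' for inverse-transform simulation.
#'
#' The cumulative hazard is measured from the origin, so
#' `jp_cum_hazard(origin, p) == 0` and `jp_survival(origin, p) == 1`:
#' everything is conditional on having survived the first `origin` days,
#' matching a likelihood that left-truncates at the origin.
#'
#' @param t days since surgery; must be `>= origin`.
#' @param h non-negative cumulative hazard value(s) to invert.
#' @param params a [jp_params()] object.
#' @return `jp_hazard`: hazard in events per person-day. `jp_cum_hazard`:
#'   dimensionless cumulative hazard. `jp_survival`: survival probability
#'   given alive at the origin. `jp_quantile`: the day `t` with
#'   `jp_cum_hazard(t, params) == h`.
#' @examples
#' p <- jp_params(0.917e-3, 0.185e-3, 23.8)
#' jp_survival(180, p)                    # P(alive at 180 | alive at day 3)
#' jp_quantile(jp_cum_hazard(60, p), p)   # 60
#' @export
jp_hazard <- function(t, params) {
  params <- .check_params(params)
  .check_domain(t, params$origin)
  w <- pmax(0, params$shift - t) / (params$shift - params$origin)
  params$background + (params$acute - params$background) * pmin(1, w)
}

#' @rdname jp_hazard
#' @export
jp_cum_hazard <- function(t, params) {
  params <- .check_params(params)
  .check_domain(t, params$origin)
  a <- params$acute; b <- params$background
  o <- params$origin; tau <- params$shift
  L <- tau - o
  tm <- pmin(t, tau)
  # integral of the linear segment up to min(t, tau), then the plateau
  seg1 <- b * (tm - o) + (a - b) * (L^2 - (tau - tm)^2) / (2 * L)
  seg1 + b * pmax(0, t - tau)
}

#' @rdname jp_hazard
#' @export
jp_survival <- function(t, params) {
  exp(-jp_cum_hazard(t, params))
}

#' @rdname jp_hazard
#' @export
jp_quantile <- function(h, params) {
  params <- .check_params(params)
  if (any(!is.finite(h)) || any(h < 0))
    stop("cumulative hazard values must be finite and non-negative")
  a <- params$acute; b <- params$background
  o <- params$origin; tau <- params$shift
  L <- tau - o
  H1 <- (a + b) * L / 2           # cumulative hazard at the join point
  s <- (a - b) / L                # absolute slope of the declining segment
  out <- numeric(length(h))
  past <- h >= H1
  if (any(past)) {
    if (b <= 0 && any(h[past] > H1 + 1e-15))
      stop("cumulative hazard not attainable: background rate is 0 and h ",
           "exceeds the total hazard of the declining segment")
    out[past] <- tau + (h[past] - H1) / ifelse(b > 0, b, Inf)
  }
  if (any(!past)) {
    hh <- h[!past]
    if (s > 0) {
      # root of (s/2) u^2 - a u + h = 0 closer to the origin, stable form
      u <- 2 * hh / (a + sqrt(pmax(0, a^2 - 2 * s * hh)))
    } else {
      u <- if (a > 0) hh / a else rep(0, length(hh))
    }
    out[!past] <- o + u
  }
  out
}
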