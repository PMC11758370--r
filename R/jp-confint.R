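# Profile-likelihood confidence intervals.
#
# An interval at level 1 - alpha collects the parameter values whose profile
# log-likelihood stays within qchisq(1 - alpha, 1) / 2 of the maximum, the
# likelihood-ratio inversion that produces the asymmetric intervals typical
# of the phase-shift parameter.  Endpoints are located by scanning outward
# from the MLE until the profile drops below the cutoff, then root-finding.

# profile value for a pinned rate: maximize over the phase shift (coarse
# grid + local refinement) and the remaining rate (safeguarded Newton).
.pll_rate <- function(time, event, origin, horizon, which, value,
                      coarse = 2) {
  taus <- seq(origin + 0.5, horizon, by = coarse)
  fixed <- stats::setNames(list(value), which)
  prof <- .profile_tau(time, event, origin, taus, fixed = fixed)
  i <- which.max(prof$ll)
  lo <- taus[max(1L, i - 1L)]; hi <- taus[min(length(taus), i + 1L)]
  ref <- stats::optimize(function(tt)
    .pll_at_tau(time, event, origin, tt, fixed = fixed),
    interval = c(lo, hi), maximum = TRUE, tol = 0.05)
  max(prof$ll[i], ref$objective)
}

# Precomputed per-tau sufficient statistics, reused across the many profile
# evaluations a confidence bound needs: a coarse grid over the whole search
# range plus a fine grid around the fitted join point.
.tau_stats_grid <- function(time, event, origin, horizon, tau_hat,
                            coarse = 2, fine = 0.5, span = 8) {
  taus <- sort(unique(c(
    seq(origin + fine, horizon, by = coarse),
    seq(max(origin + fine, tau_hat - span), min(horizon, tau_hat + span),
        by = fine))))
  lapply(taus, function(tt) .tau_stats(time, event, origin, tt))
}

.pll_rate_cached <- function(stats_grid, which, value) {
  best <- -Inf; warm <- NULL
  for (st in stats_grid) {
    sol <- if (which == "acute") .inner_fix_acute(st, value, start = warm)
    else .inner_fix_background(st, value, start = warm)
    warm <- if (which == "acute") sol$b else sol$a
    if (sol$ll > best) best <- sol$ll
  }
  best
}

# scan outward from the MLE until pll < cutoff, then uniroot the crossing.
# Returns c(endpoint, unbounded_flag).
.ci_endpoint <- function(pll, mle, cutoff, side, lower_bound = 0,
                         upper_bound = Inf, tol = 1e-3) {
  f <- function(v) pll(v) - cutoff
  v_in <- mle
  if (side == "lower") {
    v <- mle
    for (i in 1:60) {
      v_new <- max(lower_bound, v - max(0.15 * abs(v - lower_bound),
                                        1e-3 * (mle - lower_bound)))
      if (v_new <= lower_bound + 1e-12) {
        if (f(max(v_new, lower_bound + 1e-12)) > 0)
          return(c(lower_bound, TRUE))
        v <- v_new; break
      }
      if (f(v_new) < 0) { v <- v_new; break }
      v_in <- v_new; v <- v_new
    }
    root <- stats::uniroot(f, c(v, v_in),
                           tol = max(tol * abs(mle), 1e-12))$root
  } else {
    v <- mle
    for (i in 1:60) {
      v_new <- min(upper_bound, v + max(0.2 * abs(v - lower_bound),
                                        1e-3 * max(abs(mle), 1)))
      if (v_new >= upper_bound - 1e-12) {
        if (f(upper_bound) > 0) return(c(upper_bound, TRUE))
        v <- v_new; break
      }
      if (f(v_new) < 0) { v <- v_new; break }
      v_in <- v_new; v <- v_new
    }
    root <- stats::uniroot(f, c(v_in, v),
                           tol = max(tol * abs(mle), 1e-12))$root
  }
  c(root, FALSE)
}

#' Profile-likelihood confidence intervals for a join-point fit
#'
#' Inverts the likelihood-ratio test: the interval for a parameter is the
#' set of values whose profile log-likelihood lies within
#' `qchisq(level, 1) / 2` of the maximum (1.921 at 95%).  Intervals are
#' typically asymmetric, especially for the phase shift.  If the profile
#' never drops below the cutoff within the search bounds (origin/horizon for
#' the shift, zero/a large multiple of the MLE for the rates) the endpoint
#' is reported at the bound and flagged in the `"unbounded"` attribute.
#'
#' @param object a [jp_fit()] object.
#' @param parm parameters to profile, among `"acute"`, `"background"`,
#'   `"shift"`.
#' @param level coverage probability.
#' @param ... unused.
#' @return matrix with one row per parameter (internal rate scale,
#'   events/person-day; days for the shift) and attribute `"unbounded"`.
#' @export
confint.jp_fit <- function(object, parm = c("acute", "background", "shift"),
                           level = 0.95, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  if (!object$converged)
    warning("fit did not converge; intervals may be unreliable")
  cutoff <- object$loglik - stats::qchisq(level, df = 1) / 2
  time <- object$time; event <- object$event
  origin <- object$origin; horizon <- object$horizon
  out <- matrix(NA_real_, length(parm), 2,
                dimnames = list(parm, c("lower", "upper")))
  unb <- matrix(FALSE, length(parm), 2, dimnames = dimnames(out))
  stats_grid <- if (any(parm != "shift"))
    .tau_stats_grid(time, event, origin, horizon, object$params$shift)
  for (p in parm) {
    if (p == "shift") {
      pll <- function(v) .pll_at_tau(time, event, origin, v)
      mle <- object$params$shift
      lo <- .ci_endpoint(pll, mle, cutoff, "lower",
                         lower_bound = origin + 1e-3, upper_bound = horizon,
                         tol = 1e-3)
      hi <- .ci_endpoint(pll, mle, cutoff, "upper",
                         lower_bound = origin + 1e-3, upper_bound = horizon,
                         tol = 1e-3)
    } else {
      key <- if (p == "acute") "acute" else "background"
      pll <- function(v) .pll_rate_cached(stats_grid, key, v)
      mle <- object$params[[key]]
      ub <- max(10 * mle, 20 * object$n_events /
                  max(sum(time - origin), 1))
      lo <- .ci_endpoint(pll, mle, cutoff, "lower", lower_bound = 0,
                         upper_bound = ub)
      hi <- .ci_endpoint(pll, mle, cutoff, "upper", lower_bound = 0,
                         upper_bound = ub)
    }
    out[p, ] <- c(lo[1], hi[1])
    unb[p, ] <- c(lo[2] > 0, hi[2] > 0)
  }
  attr(out, "unbounded") <- unb
  attr(out, "level") <- level
  out
}

#' @export
profile.jp_fit <- function(fitted, ...) {
  data.frame(tau = fitted$profile$tau, loglik = fitted$profile$loglik)
}
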