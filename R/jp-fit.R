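#' Fit the join-point postoperative hazard model by maximum likelihood
#'
#' Estimates the acute phase death rate, background death rate and phase
#' shift time from right-censored follow-up, conditional on survival to the
#' acute-phase origin.  The likelihood is profiled over the phase shift: for
#' each candidate join point on a grid the two rates are maximized (a concave
#' problem solved with a bounded quasi-Newton step), then the join point is
#' refined by golden-section search around the grid argmax.
#'
#' @param time follow-up days since surgery, one per subject, all
#'   `>= origin`; alternatively a `survival::Surv` object or a formula
#'   `Surv(time, event) ~ 1` evaluated in `data`.
#' @param event death indicator (1 = died, 0 = censored); ignored when
#'   `time` is a `Surv` object or formula.
#' @param data optional data frame for the formula interface.
#' @param origin acute-phase start day (default 3).
#' @param horizon administrative follow-up horizon in days; the upper end of
#'   the phase-shift search.  Defaults to the largest observed time.
#' @param tau_step grid step for phase-shift profiling, days.
#' @param tau_tol refinement tolerance on the phase shift, days.
#' @return An object of class `"jp_fit"` with components `params`
#'   ([jp_params()] at the MLE), `loglik`, `n`, `n_events`, `profile` (the
#'   phase-shift profile grid), `converged`, `boundary` (`TRUE` when the fit
#'   hit the `acute >= background` constraint or a grid end), and the data.
#' @examples
#' p <- jp_params(0.917e-3, 0.185e-3, 23.8)
#' set.seed(1)
#' d <- simulate_survival(5000, p, horizon = 180)
#' fit <- jp_fit(d$time, d$event)
#' coef(fit, per1000 = TRUE)
#' @seealso [confint.jp_fit()] for profile-likelihood intervals,
#'   [jp_overall_test()] and [jp_equality_test()] for group comparisons.
#' @export
jp_fit <- function(time, event = NULL, data = NULL, origin = 3,
                   horizon = NULL, tau_step = 0.5, tau_tol = 0.01) {
  cl <- match.call()
  if (inherits(time, "formula")) {
    mf <- stats::model.frame(time, data = data)
    y <- stats::model.response(mf)
    if (!survival::is.Surv(y))
      stop("the formula response must be a survival::Surv object")
    if (ncol(mf) > 1L)
      stop("jp_fit takes no covariates; stratify with subgroup_fit()")
    time <- as.numeric(y[, "time"]); event <- as.numeric(y[, "status"])
  } else if (survival::is.Surv(time)) {
    event <- as.numeric(time[, "status"]); time <- as.numeric(time[, "time"])
  }
  .jp_check_cohort(time, event, origin)
  n <- length(time); m <- sum(event)
  if (n == 0L) stop("empty cohort")
  if (m == 0L) stop("no events in cohort: the rates are unidentifiable")
  all_events <- m == n
  if (is.null(horizon)) horizon <- max(time)
  if (horizon <= origin + tau_step) stop("horizon too close to origin")

  taus <- seq(origin + tau_step, horizon, by = tau_step)
  prof <- .profile_tau(time, event, origin, taus)
  i <- which.max(prof$ll)
  lo <- taus[max(1L, i - 1L)]; hi <- taus[min(length(taus), i + 1L)]
  ref <- .refine_tau(function(tt) .pll_at_tau(time, event, origin, tt),
                     lo, hi, tau_tol)
  tau_hat <- if (ref$ll >= prof$ll[i]) ref$tau else taus[i]
  sol <- .inner_free(.tau_stats(time, event, origin, tau_hat))
  boundary <- (sol$d <= 1e-10 || sol$d < 1e-6 * sol$a) ||
    i == 1L || i == length(taus)
  params <- jp_params(max(sol$a, sol$b), sol$b, tau_hat, origin)
  structure(list(
    params = params, loglik = sol$ll, n = n, n_events = m,
    profile = data.frame(tau = prof$tau, loglik = prof$ll,
                         acute = prof$acute, background = prof$background),
    converged = sol$convergence == 0, boundary = boundary,
    all_events = all_events,
    origin = origin, horizon = horizon, tau_step = tau_step,
    tau_tol = tau_tol, time = time, event = event, call = cl),
    class = "jp_fit")
}

#' @export
coef.jp_fit <- function(object, per1000 = FALSE, ...) {
  s <- if (per1000) 1000 else 1
  c(acute = s * object$params$acute,
    background = s * object$params$background,
    shift = object$params$shift)
}

#' @export
logLik.jp_fit <- function(object, ...) {
  structure(object$loglik, df = 3L, nobs = object$n, class = "logLik")
}

#' @export
print.jp_fit <- function(x, digits = 3, ...) {
  cat("Join-point postoperative hazard model\n")
  cat(sprintf("  n = %d subjects, %d deaths; origin day %g, horizon %g days\n",
              x$n, x$n_events, x$origin, x$horizon))
  cat(sprintf("  acute phase death rate: %.*f per 1000 patients and day\n",
              digits, 1000 * x$params$acute))
  cat(sprintf("  background death rate:  %.*f per 1000 patients and day\n",
              digits, 1000 * x$params$background))
  cat(sprintf("  phase shift time:       %.1f days\n", x$params$shift))
  cat(sprintf("  log-likelihood: %.3f\n", x$loglik))
  if (x$boundary)
    cat("  note: estimate on the constraint boundary (flat hazard or grid edge)\n")
  if (x$all_events)
    cat("  warning: no censored subjects; the plateau may be weakly identified\n")
  invisible(x)
}

#' @export
summary.jp_fit <- function(object, level = 0.95, ci = TRUE, ...) {
  tab <- cbind(estimate = coef(object, per1000 = TRUE))
  if (ci) {
    cim <- confint(object, level = level)
    cim[1:2, ] <- 1000 * cim[1:2, ]
    tab <- cbind(tab, cim)
  }
  structure(list(table = tab, level = level, fit = object),
            class = "summary.jp_fit")
}

#' @export
print.summary.jp_fit <- function(x, ...) {
  f <- x$fit
  cat("Join-point postoperative hazard model\n")
  cat(sprintf("  n = %d subjects, %d deaths (origin day %g, horizon %g)\n\n",
              f$n, f$n_events, f$origin, f$horizon))
  tab <- x$table
  rownames(tab) <- c("acute rate (/1000/day)", "background (/1000/day)",
                     "phase shift (days)")
  print(round(tab, 3))
  cat(sprintf("\n  log-likelihood %.3f; %d%% profile-likelihood intervals\n",
              f$loglik, round(100 * x$level)))
  invisible(x)
}

#' Model quantities at new times
#'
#' @param object a fitted `jp_fit` model.
#' @param newtimes days since surgery (default: integer days from origin to
#'   horizon).
#' @param type `"hazard"`, `"cumhaz"` or `"survival"`.
#' @param per1000 report hazards per 1000 patients and day.
#' @param ... unused.
#' @export
predict.jp_fit <- function(object, newtimes = NULL,
                           type = c("hazard", "cumhaz", "survival"),
                           per1000 = FALSE, ...) {
  type <- match.arg(type)
  if (is.null(newtimes))
    newtimes <- seq(object$origin, object$horizon)
  out <- switch(type,
    hazard = jp_hazard(newtimes, object$params),
    cumhaz = jp_cum_hazard(newtimes, object$params),
    survival = jp_survival(newtimes, object$params))
  if (per1000 && type == "hazard") out <- 1000 * out
  out
}

#' @export
residuals.jp_fit <- function(object, type = c("martingale", "coxsnell"), ...) {
  type <- match.arg(type)
  cs <- jp_cum_hazard(object$time, object$params)
  if (type == "coxsnell") cs else object$event - cs
}

#' Simulate follow-up from a fitted join-point model
#'
#' Draws new right-censored survival times from the fitted hazard,
#' conditional on survival to the origin, with administrative censoring at
#' the fitted horizon.
#'
#' @param object a `jp_fit`.
#' @param nsim number of replicate cohorts.
#' @param seed optional seed, handled as in [stats::simulate()].
#' @param n cohort size per replicate (default: size of the fitted cohort).
#' @param ... unused.
#' @return a data frame (`nsim = 1`) or list of data frames with columns
#'   `time`, `event`.
#' @export
simulate.jp_fit <- function(object, nsim = 1, seed = NULL, n = object$n, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- replicate(nsim, simulate_survival(n, object$params,
                                           horizon = object$horizon),
                   simplify = FALSE)
  if (nsim == 1) out[[1]] else out
}

#' Plot a fitted join-point hazard against the empirical hazard
#'
#' Overlays the fitted model on the model-free daily summaries: either the
#' daily empirical hazard (points) with the fitted hazard line, or the
#' Nelson-Aalen cumulative hazard with pointwise confidence band and the
#' model's cumulative hazard.
#'
#' @param x a `jp_fit`.
#' @param type `"hazard"` or `"cumhaz"`.
#' @param level coverage of the pointwise Nelson-Aalen band.
#' @param ... passed to [graphics::plot()].
#' @export
plot.jp_fit <- function(x, type = c("hazard", "cumhaz"), level = 0.95, ...) {
  type <- match.arg(type)
  days <- seq(x$origin, x$horizon)
  if (type == "hazard") {
    emp <- daily_hazard(x$time, x$event, window = c(x$origin, x$horizon))
    graphics::plot(emp$day, emp$rate, pch = 16, cex = 0.5, col = "grey40",
                   xlab = "days since surgery",
                   ylab = "deaths per 1000 patients and day", ...)
    graphics::lines(days, predict(x, days, "hazard", per1000 = TRUE),
                    col = "red3", lwd = 2)
  } else {
    na <- nelson_aalen(x$time, x$event, horizon = x$horizon, level = level)
    na <- na[na$day >= x$origin, ]
    base <- na$cum_hazard[1] - na$rate[1] / 1000  # anchor both curves at origin
    graphics::plot(na$day, na$cum_hazard - base, type = "s", col = "grey40",
                   xlab = "days since surgery",
                   ylab = "cumulative hazard since origin", ...)
    graphics::lines(na$day, na$ci_low - base, lty = 2, col = "grey60")
    graphics::lines(na$day, na$ci_high - base, lty = 2, col = "grey60")
    graphics::lines(days, predict(x, days, "cumhaz"), col = "red3", lwd = 2)
  }
  invisible(x)
}
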