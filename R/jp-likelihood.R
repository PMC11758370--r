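# Likelihood machinery.
#
# The log-likelihood for right-censored data left-truncated at the origin is
#   sum_i [ d_i * log h(t_i) - H(t_i) ]
# with h the join-point hazard and H its integral from the origin.  For a
# fixed phase shift tau the hazard is linear in (acute, background):
#   h(t) = acute * w(t) + background * (1 - w(t)),
#   w(t) = max(0, tau - t) / (tau - origin),
# so  H(t) = acute * W(t) + background * V(t)  with W, V known integrals, and
# the log-likelihood is concave in the rates.  Fitting profiles over tau.

.jp_check_cohort <- function(time, event, origin) {
  if (length(time) != length(event))
    stop("'time' and 'event' must have the same length")
  if (any(!is.finite(time)) || any(!is.finite(event)))
    stop("'time' and 'event' must be finite")
  if (!all(event %in% c(0, 1)))
    stop("'event' must be 0 (censored) or 1 (death)")
  if (any(time < origin))
    stop("records with time before day ", origin, " found: apply the ",
         "modelling exclusions (drop follow-up ending before the ",
         "acute-phase origin) before fitting")
  invisible(TRUE)
}

# Sufficient pieces at a fixed tau: event weights we, and the cohort sums of
# W(t) and V(t).  All costs after this are O(#events) per likelihood call.
.tau_stats <- function(time, event, origin, tau) {
  L <- tau - origin
  te <- time[event == 1]
  we <- pmax(0, tau - te) / L
  tm <- pmin(time, tau)
  W <- (L^2 - (tau - tm)^2) / (2 * L)
  list(we = we, ce = 1 - we, sumW = sum(W), sumV = sum(time - origin) - sum(W),
       m = length(te), tau = tau, L = L)
}

.ll_ab <- function(a, b, st) {
  haz <- a * st$we + b * st$ce
  if (any(haz <= 0)) return(-Inf)
  sum(log(haz)) - a * st$sumW - b * st$sumV
}

# Maximize over (a, b) with a >= b >= 0 at fixed tau.  Parameterized as
# (d, b) with a = b + d, d >= 0; the objective is concave, L-BFGS-B with
# analytic gradient converges in a handful of steps from a warm start.
.inner_free <- function(st, start = NULL) {
  if (st$m == 0L) stop("no events: rates are unidentifiable")
  negll <- function(p) {
    haz <- p[2] + p[1] * st$we
    if (any(haz <= 0)) return(1e12)
    -(sum(log(haz)) - p[1] * st$sumW - p[2] * (st$sumW + st$sumV))
  }
  neggr <- function(p) {
    haz <- p[2] + p[1] * st$we
    if (any(haz <= 0)) return(c(0, 0))
    c(-(sum(st$we / haz) - st$sumW), -(sum(1 / haz) - st$sumW - st$sumV))
  }
  r0 <- st$m / (st$sumW + st$sumV)   # crude overall event rate
  # objective is concave, so the max is unique; a warm start alone suffices,
  # otherwise three deterministic moment-style starts guard against a poor
  # first bracket
  starts <- if (!is.null(start)) list(start) else
    list(c(r0, r0), c(2 * r0, r0 / 2), c(r0 / 2, 2 * r0))
  best <- NULL
  for (s in starts) {
    s <- pmax(s, c(0, 1e-12))
    opt <- stats::optim(s, negll, neggr, method = "L-BFGS-B",
                        lower = c(0, 1e-12),
                        control = list(factr = 1e4, maxit = 200))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  conv <- best$convergence
  if (conv != 0) {
    # L-BFGS-B occasionally aborts its line search right at the optimum
    # (code 52); if a restart cannot improve the value, the point is
    # stationary and the fit has converged
    opt <- stats::optim(pmax(best$par, c(0, 1e-12)), negll, neggr,
                        method = "L-BFGS-B", lower = c(0, 1e-12),
                        control = list(factr = 1e7, maxit = 200))
    if (opt$value <= best$value + 1e-8) {
      if (opt$convergence == 0 || opt$value > best$value - 1e-7) conv <- 0
      if (opt$value < best$value) best <- opt
    }
  }
  list(d = best$par[1], b = best$par[2], a = best$par[1] + best$par[2],
       ll = -best$value, convergence = conv)
}

# Maximize over b in [0, acute] at fixed (tau, acute): safeguarded Newton on
# the concave 1-D profile.
.inner_fix_acute <- function(st, acute, start = NULL) {
  ce <- st$ce; we <- st$we
  g <- function(b) sum(ce / (acute * we + b * ce)) - st$sumV
  gp <- function(b) -sum(ce^2 / (acute * we + b * ce)^2)
  lo <- if (any(we == 0)) 1e-14 else 0
  hi <- acute
  if (g(hi) >= 0) b <- hi
  else if (lo > 0 && !is.finite(g(lo))) b <- lo
  else if (g(max(lo, 1e-14)) <= 0) b <- lo
  else {
    b <- if (!is.null(start)) min(max(start, max(lo, 1e-14)), hi) else hi / 2
    blo <- max(lo, 1e-14); bhi <- hi
    for (it in 1:60) {
      gb <- g(b)
      if (gb > 0) blo <- b else bhi <- b
      step <- gb / gp(b)
      bn <- b - step
      if (!is.finite(bn) || bn <= blo || bn >= bhi) bn <- (blo + bhi) / 2
      if (abs(bn - b) < 1e-12 * max(b, 1e-8)) { b <- bn; break }
      b <- bn
    }
  }
  list(b = b, ll = .ll_ab(acute, b, st))
}

# Maximize over a in [background, inf) at fixed (tau, background).
.inner_fix_background <- function(st, background, start = NULL) {
  we <- st$we; ce <- st$ce
  g <- function(a) sum(we / (a * we + background * ce)) - st$sumW
  gp <- function(a) -sum(we^2 / (a * we + background * ce)^2)
  lo <- background
  if (all(we == 0) || st$sumW <= 0) a <- lo
  else if (g(lo + 1e-14) <= 0) a <- lo
  else {
    # bracket the root above lo
    ahi <- max(2 * (lo + 1e-8), 10 * st$m / max(st$sumW, 1e-12))
    while (g(ahi) > 0) ahi <- ahi * 4
    a <- if (!is.null(start)) min(max(start, lo + 1e-14), ahi) else
      (lo + ahi) / 2
    alo <- lo + 1e-14
    for (it in 1:60) {
      ga <- g(a)
      if (ga > 0) alo <- a else ahi <- a
      an <- a - ga / gp(a)
      if (!is.finite(an) || an <= alo || an >= ahi) an <- (alo + ahi) / 2
      if (abs(an - a) < 1e-12 * max(a, 1e-8)) { a <- an; break }
      a <- an
    }
  }
  list(a = a, ll = .ll_ab(a, background, st))
}

# Profile log-likelihood over a tau grid.  `fixed` optionally pins one rate.
# Returns the grid, profile values and the per-tau inner solutions.
.profile_tau <- function(time, event, origin, taus, fixed = NULL) {
  ll <- numeric(length(taus))
  A <- numeric(length(taus)); B <- numeric(length(taus))
  warm <- NULL
  for (i in seq_along(taus)) {
    st <- .tau_stats(time, event, origin, taus[i])
    if (is.null(fixed)) {
      sol <- .inner_free(st, start = warm)
      warm <- c(sol$d, sol$b)
      ll[i] <- sol$ll; A[i] <- sol$a; B[i] <- sol$b
    } else if (names(fixed) == "acute") {
      sol <- .inner_fix_acute(st, fixed[[1]], start = warm)
      warm <- sol$b
      ll[i] <- sol$ll; A[i] <- fixed[[1]]; B[i] <- sol$b
    } else {
      sol <- .inner_fix_background(st, fixed[[1]], start = warm)
      warm <- sol$a
      ll[i] <- sol$ll; A[i] <- sol$a; B[i] <- fixed[[1]]
    }
  }
  list(tau = taus, ll = ll, acute = A, background = B)
}

# Maximize a tau profile within a bracket.  The profile has kinks where tau
# crosses an event time, so golden-section alone can stall on a local
# wiggle; a fine scan locates the right sub-bracket first.
.refine_tau <- function(f, lo, hi, tol = 0.01) {
  fine <- seq(lo, hi, by = max(tol * 2, (hi - lo) / 80))
  vals <- vapply(fine, f, 0)
  j <- which.max(vals)
  flo <- fine[max(1L, j - 1L)]; fhi <- fine[min(length(fine), j + 1L)]
  opt <- stats::optimize(f, c(flo, fhi), maximum = TRUE, tol = tol / 3)
  if (opt$objective >= vals[j]) list(tau = opt$maximum, ll = opt$objective)
  else list(tau = fine[j], ll = vals[j])
}

# Continuous profile value at one tau (used for refinement / uniroot).
.pll_at_tau <- function(time, event, origin, tau, fixed = NULL) {
  st <- .tau_stats(time, event, origin, tau)
  if (is.null(fixed)) .inner_free(st)$ll
  else if (names(fixed) == "acute") .inner_fix_acute(st, fixed[[1]])$ll
  else .inner_fix_background(st, fixed[[1]])$ll
}

#' Join-point model log-likelihood
#'
#' Right-censored, left-truncated-at-origin log-likelihood of a cohort under
#' a join-point hazard: the sum over subjects of
#' `event * log(h(time)) - H(time)`, with the cumulative hazard `H` measured
#' from the acute-phase origin.  Records ending before the origin are a
#' validation error; apply [modeling_subset()] first.
#'
#' @param params a [jp_params()] object.
#' @param time follow-up day since surgery (death or censoring), `>= origin`.
#' @param event 1 = died, 0 = censored.
#' @return log-likelihood in nats; `-Inf` if any death occurs where the
#'   model hazard is zero.
#' @export
jp_loglik <- function(params, time, event) {
  params <- .check_params(params)
  .jp_check_cohort(time, event, params$origin)
  st <- .tau_stats(time, event, params$origin, params$shift)
  .ll_ab(params$acute, params$background, st)
}
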