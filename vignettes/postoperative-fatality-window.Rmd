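---
title: "A join-point hazard model for the postoperative fatality window"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A join-point hazard model for the postoperative fatality window}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(postopwindow)
```

## The model and its assumptions

Fixed 30- or 90-day windows for counting postoperative deaths are
conventions. `postopwindow` instead estimates the window from the shape of
the daily hazard. The model assumes that, from an acute-phase origin
$t_0$ (day 3 after surgery, where registry daily hazards peak), the hazard
declines *linearly on the hazard scale* to a join point $\tau$ — the
**phase shift time** — and is constant afterwards:

$$
h(t) \;=\; \begin{cases}
  b + (a - b)\,\dfrac{\tau - t}{\tau - t_0}, & t_0 \le t \le \tau,\\[4pt]
  b, & t > \tau,
\end{cases}
$$

with $a \ge b \ge 0$ (**acute phase death rate** and **background death
rate**, both per person-day internally and per 1000 patients and day in
all reports) and $\tau > t_0$. The hazard is continuous at $\tau$ by
construction and non-increasing everywhere. Implied quantities have
closed forms: the cumulative hazard from the origin is quadratic on the
declining segment and linear beyond it, and its inverse (used for
simulation) is a stable quadratic root.

Assumptions worth stating plainly:

* the decline is linear on the hazard scale (not log-linear); one could
  read "declining hazard" either way, and this package follows the
  plainer reading — a log-scale decline is a different model and out of
  scope;
* $t_0$ is *fixed*, not estimated. Day 3 is where empirical daily
  hazards peak in elective colorectal cohorts; it is a configuration
  value (`origin`) so other procedures can move it;
* integer registry days are treated as exact continuous event times;
  ties carry no correction (a continuous-hazard model applied to daily
  data);
* all deaths within the horizon count; there is no cause-of-death
  decomposition.

## Likelihood, truncation and censoring

Follow-up is administratively censored at a `horizon` (180 days by
default; 360 for the late-window diagnostic). Deaths before the origin
cannot be modelled by a hazard defined on $[t_0,\infty)$; the pipeline
removes them (`modeling_subset()`, reporting the count) and the
likelihood is *left-truncated* at the origin: with event indicator
$d_i$,

$$
\ell(a,b,\tau) = \sum_i \big[ d_i \log h(t_i) - H(t_i) \big],
\qquad H(t) = \int_{t_0}^{t} h(s)\,ds .
$$

Records with $t_i < t_0$ are a validation error, not silently dropped —
the caller must apply the exclusions first, so counts are auditable.

## Estimation

At fixed $\tau$ the hazard is linear in $(a,b)$:
$h(t) = a\,w(t) + b\,(1-w(t))$ with a known weight $w$, so
$\ell(\cdot,\cdot,\tau)$ is concave in the rates and the inner problem is
solved reliably by a bounded quasi-Newton step (parameterised as
$(a-b, b)$ with lower bounds, analytic gradient, warm starts along the
grid; without a warm start, three deterministic moment-style starts are
used). The outer problem profiles $\tau$ on a 0.5-day grid over
(`origin`, `horizon`], then refines near the grid argmax. Because the
profile has kinks wherever $\tau$ crosses an observed event time,
golden-section search alone can stall on a local wiggle; the refinement
therefore scans a fine (0.02-day) local grid first and then polishes to
0.01 days. A fit is flagged `boundary` when it lands on the $a = b$
constraint (flat hazard) or a grid end, and `all_events` (plateau weakly
identified) when nothing is censored. Estimates are invariant to subject
order and to consistent rescaling of the time unit; both are tested.

## Confidence intervals

Intervals invert the likelihood-ratio test: the 95% interval for a
parameter is the set of values whose profile log-likelihood is within
$\chi^2_1(0.95)/2 = 1.92$ of the maximum. For $\tau$ the profile is the
one already computed; for each rate the profile maximises over $\tau$
(cached per-tau sufficient statistics on a coarse 2-day grid plus a fine
0.5-day grid around $\hat\tau$) and the remaining rate (safeguarded
1-D Newton). Endpoints are found by scanning outward from the MLE and
root-finding the cutoff crossing. Profile intervals are asymmetric where
the likelihood is — typical for $\tau$. If the profile never drops below
the cutoff inside the search bounds (origin/horizon for $\tau$, zero and
a large multiple of the MLE for rates) the endpoint is reported at the
bound and flagged `unbounded`; flat-hazard data produce exactly this.

## Group comparisons and their gating

`jp_overall_test()` is the gate: all three parameters common versus all
free, $df = 3(k-1)$. Per-parameter contrasts (`jp_equality_test()`,
$df = k-1$) are run by `subgroup_fit()` only when the gate rejects at 5%
(an `gate = FALSE` override exists for exploration). Under a shared
phase shift the per-level rate problems separate at fixed $\tau$, so the
null fit is the maximiser of the *sum* of per-level profiles; under a
shared rate a 1-D outer optimisation wraps per-level $(\tau,$ other
rate$)$ profiles. Pairwise period comparisons are two-level refits, not
contrasts inside a three-level fit.

A caveat the package documents rather than hides: a change-point
parameter is not a regular MLE, so the $\chi^2$ reference for tests and
intervals on $\tau$ is an approximation. It is used as the default
because the simulation calibration supports it at these sample sizes —
the suite checks that the shared-shift null test holds its size (empirical
rejection ~0.055 at nominal 0.05 over 200 replicates) and that the
$\tau$ interval covers at the nominal rate — and a parametric-bootstrap
recalibration is available via
`jp_equality_test(..., p_method = "bootstrap")`.

## Model-free diagnostics

`daily_hazard()` counts deaths and at-risk subjects per day (a subject
whose follow-up ends on day $d$ is at risk on day $d$; continuous times
bin to the containing day), reporting `NA` — undefined, not zero — when
the risk set is empty; no smoothing is applied. `nelson_aalen()`
accumulates `deaths / at_risk` with pointwise intervals on the log scale
(variance $\sum d/n^2$); it matches `survival::survfit(ctype = 1)` to
numerical precision, which the suite asserts on 1000 random cohorts.
`peak_day()` locates the empirical maximum (ties reported, earliest
primary) — the basis for fixing the origin at day 3.
`late_window_rate()` fits a constant hazard on days 180–360 (events per
person-day) and checks constancy by a one-rate versus two-rates
(split at the midpoint) likelihood-ratio test; "approximately constant"
means that check does not reject.

## The cohort pipeline

`apply_exclusions()` keeps electively operated patients with known
status, censors follow-up at the horizon and reports the count chain;
`categorize_cohort()` adds the study groupings (ages 0–69 / 70–79 / 80+;
ASA I / II / III–IV, the top grades merged because ASA IV alone is too
sparse for stable estimates; periods 2007–2011 / 2012–2016 / 2017–2020,
other years flagged `"unknown"`). Missingness is handled complete-case
per analysis, with per-variable missing counts attached to the
descriptive table. The descriptive table reports both interval
conventions for late deaths (days 3–180 and days 0–180) because they
differ by exactly the day 0–2 deaths and published summaries have used
both. The 180-day horizon and day-3 origin are configuration values so
the same pipeline can benchmark other procedures and populations.

## The synthetic registry generator

`simulate_cohort()` emulates the raw registry table: strata (site, or
site × ASA group) carry their own join-point parameters; event times are
drawn by inverse-transform sampling conditional on surviving to the
origin, administratively censored at the horizon. The packaged presets
(`crc_preset()`) transcribe published subgroup estimates — e.g. colon
ASA III–IV at (1.55, 0.34, 38.7) — with site weights 0.67/0.33 and ASA
mixes from the registry's descriptive margins; the default planting
rates are the registry's: 12.7% emergency surgery (excluded by the
pipeline), 0.25% unknown status, 0.105% deaths on days 0–2 (drawn
uniformly over {0,1,2}, decoupled from the model, which starts at day
3), 2% missing ASA and ~0.02% missing age. A raw table of 64 433 rows
therefore yields ~56 100 analyzable subjects, the registry scale.

Two generator choices deserve explanation:

* **Day recording.** Latent continuous event times are recorded as the
  *nearest* whole day. Flooring (recording the day the death occurred
  in) would shift every event time down by half a day on average, and
  because the estimator reads recorded days as exact times, that
  systematically inflates the acute rate by several percent on a
  declining hazard. The midpoint convention makes the generator and the
  estimator's convention coherent to first order. Exact continuous
  times are kept in the ground-truth sidecar (`attr(tab, "truth")`)
  for distributional tests.
* **Reproducibility.** All per-subject draws come from one root seed in
  a fixed vectorised order, so a configuration and seed reproduce the
  table byte for byte. (Independent per-subject substreams would allow
  reproducible *subsetting* too, but base R's RNG offers no cheap
  substream API; the fixed-order design gives the same guarantee for a
  fixed cohort size, which is what the tests need.)

What the generator does *not* emulate: covariates within a stratum are
drawn from independent site-specific margins (no registry
cross-tabulations beyond the stratifying variables), stage carries no
hazard effect of its own unless it is a stratifying variable, there is
no recurrence process or cause-of-death structure, and nothing beyond
day 360 is meaningful. Passing tests on these cohorts therefore
demonstrate that the estimator and pipeline are correct *under the
model*, not that the model fits any particular registry; the empirical
diagnostics exist precisely for the latter question on real data.

## Numerical choices and problem sizes

Phase-shift grid 0.5 days with refinement to 0.01; inner optimiser
tolerance `factr = 1e4`; rate profiles on a 2-day coarse / 0.5-day local
grid; interval endpoints to ~0.1% of the estimate; LRT statistics
clamped at zero with a warning below −1e−6. The test suite uses cohort
sizes the package's own calibration work found informative: single
fits at 56 000 (registry scale), coverage at 200 × 20 000, test size at
200 × 2 × 10 000, convergence checks at 10⁴ versus 10⁵. The acceptance
script runs the full pipeline at registry scale in seconds.

## Known limitations

* One join point, linear decline: smooth or multi-phase declines show up
  as lack of fit (visible in the overlay plots), not as altered
  estimates of a richer model.
* $\chi^2$ inference on $\tau$ is asymptotic and non-regular; at small
  event counts prefer the bootstrap calibration.
* Sparse strata (no events after day 2) cannot be fitted and must be
  merged by the caller; the errors name the stratum.
* The generator's covariate structure is marginal; do not use it to
  study confounding.
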