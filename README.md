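# postopwindow

Estimation of the **postoperative fatality window** from registry-style
cohort data with a join-point hazard model.

## The problem

Postoperative mortality is conventionally benchmarked with fixed windows —
death within 30 or within 90 days of surgery — chosen by convention rather
than by the data. An alternative is to let the shape of the daily death
rate define the window: after major surgery the hazard of death is high but
falls steeply, and at some point it settles onto the stable rate expected
of the underlying patient population. The day at which the decline meets
the plateau is a data-driven "postoperative fatality window", and it can be
compared across operations, periods, age and fitness groups.

`postopwindow` implements this for elective colorectal-resection registry
cohorts (and any cohort with the same schema): model fitting and inference,
model-free hazard diagnostics, the descriptive/exclusion pipeline around
them, and a synthetic registry generator so the entire analysis runs
without access to restricted registry data.

## The model

For `t` days since surgery (with an acute-phase origin at day
`t0 = 3`, where the empirical daily hazard peaks), the hazard is

    h(t) = b + (a - b) * (tau - t) / (tau - t0)   for t0 <= t <= tau
    h(t) = b                                      for t > tau

* `a` — **acute phase death rate**, the hazard at day 3;
* `b` — **background death rate**, the plateau;
* `tau` — **phase shift time**, the join point (the fatality window).

Rates are reported as deaths per 1000 patients and day. Estimation is by
maximum likelihood for right-censored data left-truncated at the origin
(deaths on days 0–2 are excluded from modelling and reported
descriptively): the log-likelihood is `sum d_i log h(t_i) - H(t_i)` with
`H` the cumulative hazard from the origin. The likelihood is profiled over
`tau` (it is concave in the two rates at fixed `tau`); confidence
intervals invert the likelihood-ratio test (profile likelihood, so
intervals are typically asymmetric), and group comparisons use
likelihood-ratio tests — an overall 3-parameter gate followed by
per-parameter equality tests.

## Worked example

```r
library(postopwindow)

cfg    <- crc_preset("overall", n = 64433, seed = 1)  # synthetic registry
cohort <- simulate_cohort(cfg)

ex <- apply_exclusions(cohort, horizon = 180)
print(ex$report)
#> Exclusion chain (follow-up censored at day 180 ):
#>   total                            64433
#>   elective surgery                 56258
#>   known status and survival time   56107

ms  <- modeling_subset(ex$table, origin = 3)   # drops 64 early deaths
fit <- jp_fit(ms$table$time, ms$table$event, origin = 3, horizon = 180)
summary(fit)
#> Join-point postoperative hazard model
#>   n = 56043 subjects, 2233 deaths (origin day 3, horizon 180)
#>
#>                        estimate  lower  upper
#> acute rate (/1000/day)    0.868  0.784  0.965
#> background (/1000/day)    0.191  0.182  0.200
#> phase shift (days)       23.468 21.625 25.203
#>
#>   log-likelihood -20699.751; 95% profile-likelihood intervals
```

The generator drew this cohort from a hazard with acute rate 0.917,
background 0.185 (per 1000 and day) and a 23.8-day window; the fit
recovers all three inside its 95% profile intervals. `plot(fit)` overlays
the fitted hazard on the daily empirical hazard; `plot(fit, "cumhaz")`
overlays the cumulative model hazard on the Nelson–Aalen estimate and its
pointwise band. Subgroup comparisons follow the same pattern:

```r
ct <- categorize_cohort(ex$table)
subgroup_fit(ct, by = "site")          # overall gate + per-parameter tests
fit_without_stage_iv(ct)               # sensitivity refit
```

A command-line front end wrapping these functions is installed at
`inst/cli/postopwindow.R` with subcommands `simulate`, `describe`, `fit`,
`compare`, `sensitivity` and `diagnose`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","postopwindow.R",package="postopwindow"))')" \
    simulate --preset overall --n 20000 --seed 1 --output out/
```

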