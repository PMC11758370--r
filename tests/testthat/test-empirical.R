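test_that("daily rates are deaths over at-risk, per 1000", {
  # 10 subjects at risk on day 3, one dies that day
  time <- c(rep(10, 9), 3)
  event <- c(rep(0, 9), 1)
  s <- daily_hazard(time, event, window = c(0, 10))
  expect_equal(s$at_risk[s$day == 3], 10)
  expect_equal(s$rate[s$day == 3], 100)
  # the dying subject counts as at risk on its own day, then leaves
  expect_equal(s$at_risk[s$day == 4], 9)
  expect_equal(sum(s$deaths), 1)
})

test_that("daily counts equal a brute-force recount", {
  d <- sim_cohort(4000, seed = 60)
  s <- daily_hazard(d$time, d$event, window = c(0, 180))
  for (day in c(0, 3, 7, 23, 100, 180)) {
    expect_equal(s$deaths[s$day == day],
                 sum(d$event == 1 & floor(d$time) == day))
    expect_equal(s$at_risk[s$day == day], sum(d$time >= day))
  }
  # person-day bookkeeping conserved
  expect_equal(sum(s$deaths), sum(d$event))
})

test_that("a cohort with no deaths has zero rates and a flat risk set", {
  time <- rep(180, 25); event <- rep(0, 25)
  s <- daily_hazard(time, event, window = c(0, 180))
  expect_true(all(s$rate == 0))
  expect_true(all(s$at_risk == 25))
  # empty risk set is undefined, not zero
  s2 <- daily_hazard(c(5, 6), c(1, 1), window = c(0, 10))
  expect_true(all(is.na(s2$rate[s2$day > 6])))
  expect_error(daily_hazard(numeric(0), numeric(0)), "empty")
})

test_that("peak day finds the maximum and reports ties earliest-first", {
  s <- structure(data.frame(day = 3:8, deaths = c(5, 4, 3, 2, 1, 0),
                            at_risk = rep(100, 6),
                            rate = c(50, 40, 30, 20, 10, 0)),
                 class = c("hazard_series", "data.frame"))
  expect_equal(peak_day(s)$day, 3)
  s$rate <- c(10, 40, 40, 20, 10, 0)
  pk <- peak_day(s)
  expect_equal(pk$day, 4)
  expect_equal(pk$tied, c(4, 5))
  s$rate <- NA_real_
  expect_error(peak_day(s), "no defined")
})

test_that("the model's peak sits at the origin in simulated cohorts", {
  hits <- vapply(1:10, function(s) {
    d <- sim_cohort(100000, seed = 300 + s)
    pk <- peak_day(daily_hazard(floor(d$time), d$event,
                                window = c(3, 180)))
    pk$day >= 3 && pk$day <= 6
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("Nelson-Aalen reproduces hand-computed toy sums", {
  # deaths on day 3 (4 at risk) and day 5 (3 at risk after the first death)
  time <- c(3, 5, 9, 9)
  event <- c(1, 1, 0, 0)
  na <- nelson_aalen(time, event, horizon = 9)
  expect_equal(na$cum_hazard[na$day == 3], 1 / 4)
  expect_equal(na$cum_hazard[na$day == 4], 1 / 4)   # nobody dies on day 4
  expect_equal(na$cum_hazard[na$day == 5], 1 / 4 + 1 / 3)
  expect_equal(na$cum_hazard[na$day == 9], 1 / 4 + 1 / 3)
  expect_true(all(diff(na$cum_hazard) >= 0))
  expect_true(all(na$ci_low <= na$cum_hazard + 1e-12 &
                    na$cum_hazard <= na$ci_high + 1e-12))
  # no events: flat zero with degenerate intervals
  na0 <- nelson_aalen(rep(8, 5), rep(0, 5), horizon = 8)
  expect_true(all(na0$cum_hazard == 0 & na0$ci_low == 0 & na0$ci_high == 0))
})

test_that("Nelson-Aalen agrees with the survival package", {
  set.seed(61)
  for (i in 1:50) {
    n <- sample(20:200, 1)
    time <- sample(1:60, n, replace = TRUE)
    event <- rbinom(n, 1, 0.6)
    if (sum(event) == 0) next
    na <- nelson_aalen(time, event, horizon = 60)
    sf <- survival::survfit(survival::Surv(time, event) ~ 1, ctype = 1)
    ours <- na$cum_hazard[match(sf$time, na$day)]
    expect_lt(max(abs(ours - sf$cumhaz)), 1e-10)
  }
})

# empirical cumulative hazard measured from the origin: the day-k increment
# approximates the hazard mass of [k, k+1), so summing increments over days
# origin..(d-1) estimates the model's H(d)
.emp_from_origin <- function(na, origin = 3) {
  keep <- na$day >= origin
  inc <- ifelse(na$at_risk > 0, na$deaths / na$at_risk, 0)[keep]
  data.frame(day = na$day[keep], H = cumsum(c(0, inc[-length(inc)])))
}

test_that("empirical cumulative hazard converges to the model's", {
  p <- overall_params()
  sup <- vapply(c(10000, 100000), function(n) {
    d <- sim_cohort(n, p, seed = 62)
    na <- nelson_aalen(d$time, d$event, horizon = 180)
    emp <- .emp_from_origin(na)
    max(abs(emp$H - jp_cum_hazard(emp$day, p)))
  }, 0)
  expect_lt(sup[2], sup[1])
  expect_lt(sup[2], 0.005)
})

test_that("the model curve stays inside the pointwise band when well
           specified", {
  d <- sim_cohort(50000, seed = 63)
  na <- nelson_aalen(d$time, d$event, horizon = 180)
  emp <- .emp_from_origin(na)
  model <- jp_cum_hazard(emp$day, overall_params())
  hw <- ((na$ci_high - na$ci_low) / 2)[na$day >= 3]
  covered <- abs(emp$H - model) <= pmax(hw, 1e-6)
  expect_gte(mean(covered), 0.9)
})

test_that("late-window rate is events per person-day with a constancy
           check", {
  # 10 subjects contributing 100 days each in [180, 360], 2 deaths
  time <- c(rep(280, 10))
  event <- c(1, 1, rep(0, 8))
  lw <- late_window_rate(time, event, window = c(180, 360))
  expect_equal(lw$person_days, 1000)
  expect_equal(lw$events, 2)
  expect_equal(lw$rate, 2.0)
  expect_error(late_window_rate(c(100, 150), c(0, 0)), "person-time")
})

test_that("the constancy check is calibrated under a constant late
           hazard and detects a trend", {
  pc <- jp_params(0.9e-3, 0.2e-3, 24)
  rej <- vapply(1:40, function(s) {
    d <- sim_cohort(20000, pc, seed = 400 + s, horizon = 360)
    late_window_rate(d$time, d$event, window = c(180, 360))$check$p_value <
      0.05
  }, TRUE)
  expect_lte(mean(rej), 0.15)
  # a doubling of the hazard mid-window must be caught at these sizes
  rej2 <- vapply(1:10, function(s) {
    set.seed(500 + s)
    t1 <- 180 + rexp(40000, 2e-4)   # rate doubles after day 270
    t2 <- ifelse(t1 > 270, 270 + rexp(40000, 4e-4), t1)
    event <- as.integer(t2 < 360)
    time <- pmin(t2, 360)
    late_window_rate(time, event, window = c(180, 360))$check$p_value < 0.05
  }, TRUE)
  expect_gte(mean(rej2), 0.7)
})
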