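# Shared fixtures: parameter sets, small simulated cohorts and toy registry
# tables built in code.

overall_params <- function() jp_params(0.917e-3, 0.185e-3, 23.8, origin = 3)

# published subgroup parameter sets (per 1000 and day) used as draws for
# property-style tests
param_rows <- function() {
  list(
    jp_params(0.917e-3, 0.185e-3, 23.8),
    jp_params(0.84e-3, 0.14e-3, 22.9),
    jp_params(0.90e-3, 0.20e-3, 27.3),
    jp_params(1.55e-3, 0.34e-3, 38.7),
    jp_params(0.24e-3, 0.04e-3, 24.4),
    jp_params(2.31e-3, 0.45e-3, 39.8))
}

sim_cohort <- function(n, params = overall_params(), seed = 1,
                       horizon = 180) {
  set.seed(seed)
  simulate_survival(n, params, horizon = horizon)
}

# deterministic raw registry table with exact exclusion margins
raw_table <- function(n_total, n_emergency, n_unknown, n_early_dead = 0,
                      horizon_deaths = 0) {
  n <- n_total
  tab <- data.frame(
    id = seq_len(n),
    age = rep(c(55, 72, 84), length.out = n),
    sex = rep(c("male", "female"), length.out = n),
    asa = rep(c("I", "II", "III", "IV"), length.out = n),
    year = rep(2007:2020, length.out = n),
    site = rep(c("colon", "rectal"), length.out = n),
    stage = rep(c("I", "II", "III", "IV"), length.out = n),
    urgency = "elective",
    survival_time = 400,
    vital_status = "alive",
    status_known = 1L,
    stringsAsFactors = FALSE)
  if (n_emergency > 0) tab$urgency[seq_len(n_emergency)] <- "emergency"
  if (n_unknown > 0)
    tab$status_known[n_emergency + seq_len(n_unknown)] <- 0L
  i0 <- n_emergency + n_unknown
  if (n_early_dead > 0) {
    idx <- i0 + seq_len(n_early_dead)
    tab$survival_time[idx] <- 1
    tab$vital_status[idx] <- "dead"
  }
  if (horizon_deaths > 0) {
    idx <- i0 + n_early_dead + seq_len(horizon_deaths)
    tab$survival_time[idx] <- 30
    tab$vital_status[idx] <- "dead"
  }
  tab
}
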