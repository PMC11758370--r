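test_that("generation is byte-identical under a fixed seed", {
  cfg <- crc_preset("site_asa", n = 2000, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  attr(a, "config") <- attr(b, "config") <- NULL
  expect_identical(a, b)
  c2 <- simulate_cohort(cfg, seed = 43)
  expect_false(identical(a$survival_time, c2$survival_time))
})

test_that("death fraction matches the closed-form survival probability", {
  cfg <- cohort_config(
    n = 100000,
    strata = data.frame(site = "colon", weight = 1, acute = 0.917e-3,
                        background = 0.185e-3, shift = 23.8),
    seed = 5, early_death_prob = 0, emergency_prob = 0,
    unknown_status_prob = 0, missing_asa_prob = 0, missing_age_prob = 0)
  tab <- simulate_cohort(cfg)
  p_dead <- 1 - exp(-jp_cum_hazard(180, overall_params()))
  se <- sqrt(p_dead * (1 - p_dead) / cfg$n)
  expect_lt(abs(mean(tab$vital_status == "dead") - p_dead), 3 * se)
  # all deaths fall in [origin, horizon), censoring exactly at the horizon
  expect_true(all(tab$survival_time[tab$vital_status == "dead"] >= 3))
  expect_true(all(tab$survival_time[tab$vital_status == "alive"] == 180))
})

test_that("a flat stratum generates exponential waiting times", {
  cfg <- cohort_config(
    n = 10000,
    strata = data.frame(site = "colon", weight = 1, acute = 4e-3,
                        background = 4e-3, shift = 30),
    seed = 6, early_death_prob = 0, emergency_prob = 0,
    unknown_status_prob = 0, missing_asa_prob = 0, missing_age_prob = 0,
    horizon = 2000)
  tab <- simulate_cohort(cfg, days = "continuous")
  dead <- tab$vital_status == "dead"
  ks <- ks.test(tab$survival_time[dead] - 3, "pexp", 4e-3)
  expect_gte(ks$p.value, 0.01)
})

test_that("planted fractions are recovered by pipeline bookkeeping", {
  cfg <- crc_preset("site_asa", n = 60000, seed = 9)
  tab <- simulate_cohort(cfg)
  tol <- function(p, n) 4 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(tab$urgency == "emergency") - cfg$emergency_prob),
            tol(cfg$emergency_prob, cfg$n))
  expect_lt(abs(mean(tab$status_known == 0) - cfg$unknown_status_prob),
            tol(cfg$unknown_status_prob, cfg$n))
  expect_lt(abs(mean(is.na(tab$asa)) - cfg$missing_asa_prob),
            tol(cfg$missing_asa_prob, cfg$n))
  ex <- apply_exclusions(tab)
  ms <- modeling_subset(ex$table)
  early_frac <- ms$dropped_deaths / nrow(ex$table)
  expect_lt(abs(early_frac - cfg$early_death_prob),
            tol(cfg$early_death_prob, nrow(ex$table)))
  # site mix close to the configured weights
  expect_lt(abs(mean(tab$site == "colon") - 0.67), 0.01)
})

test_that("per-stratum empirical hazards converge to their generators", {
  cfg <- crc_preset("site_asa", n = 100000, seed = 10,
                    early_death_prob = 0, emergency_prob = 0,
                    unknown_status_prob = 0)
  tab <- simulate_cohort(cfg)
  truth <- attr(tab, "truth")
  # largest stratum: colon ASA II
  for (j in c(2, 3)) {
    rows <- truth$stratum == j
    p <- jp_params(cfg$strata$acute[j], cfg$strata$background[j],
                   cfg$strata$shift[j])
    na <- nelson_aalen(tab$survival_time[rows],
                       as.integer(tab$vital_status[rows] == "dead"),
                       horizon = 180)
    keep <- na$day >= 3
    inc <- ifelse(na$at_risk > 0, na$deaths / na$at_risk, 0)[keep]
    emp <- cumsum(c(0, inc[-length(inc)]))
    expect_lt(max(abs(emp - jp_cum_hazard(na$day[keep], p))), 0.012)
  }
})

test_that("configuration invariants are enforced before any sampling", {
  st <- data.frame(site = "colon", weight = 1, acute = 1e-3,
                   background = 2e-4, shift = 20)
  expect_error(cohort_config(100, st, early_death_prob = 1.5), "\\[0, 1\\]")
  st2 <- st; st2$weight <- 0.5
  expect_error(cohort_config(100, st2), "sum to 1")
  st3 <- st; st3$background <- 2e-3
  expect_error(cohort_config(100, st3), "acute")
  expect_error(cohort_config(100, st[, -1]), "columns")
})

test_that("the standard preset carries the published structure", {
  cfg <- crc_preset("site_asa")
  expect_equal(cfg$n, 56096L)
  expect_equal(sum(cfg$strata$weight[cfg$strata$site == "colon"]), 0.67)
  expect_equal(sum(cfg$strata$weight[cfg$strata$site == "rectal"]), 0.33)
  iv <- cfg$strata$site == "colon" & cfg$strata$asa_group == "III-IV"
  expect_equal(cfg$strata$shift[iv], 38.7)
  expect_equal(cfg$strata$acute[iv], 1.55e-3)
  ov <- crc_preset("overall")
  expect_equal(1000 * ov$strata$acute, 0.917)
  expect_equal(1000 * ov$strata$background, 0.185)
  expect_equal(ov$strata$shift, 23.8)
})

test_that("the ground-truth sidecar aligns with the table", {
  cfg <- crc_preset("site_asa", n = 3000, seed = 11)
  tab <- simulate_cohort(cfg)
  truth <- attr(tab, "truth")
  expect_equal(truth$id, tab$id)
  expect_equal(truth$event, as.integer(tab$vital_status == "dead"))
  expect_equal(round(truth$time_exact), tab$survival_time)
  f <- file.path(tempdir(), "cohort.csv")
  write_cohort_with_truth(tab, f)
  expect_true(file.exists(paste0(f, ".truth.json")))
  side <- jsonlite::read_json(paste0(f, ".truth.json"),
                              simplifyVector = TRUE)
  expect_equal(side$stratum, truth$stratum)
  unlink(c(f, paste0(f, ".truth.json")))
})
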