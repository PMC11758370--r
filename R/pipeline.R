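# Registry-style cohort pipeline: schema, exclusions, categorisation,
# descriptive tables, subgroup fits and the stage-IV sensitivity analysis.

.cohort_cols <- c("id", "age", "sex", "asa", "year", "site", "stage",
                  "urgency", "survival_time", "vital_status", "status_known")

.cohort_levels <- list(
  sex = c("male", "female"),
  asa = c("I", "II", "III", "IV"),
  site = c("colon", "rectal"),
  stage = c("I", "II", "III", "IV", "complete_response"),
  urgency = c("elective", "emergency"),
  vital_status = c("dead", "alive"))

#' Read or write a registry-style cohort table
#'
#' CSV dialect: one header row with columns exactly
#' `id, age, sex, asa, year, site, stage, urgency, survival_time,
#' vital_status, status_known`; missing values are empty fields; days are
#' non-negative integers with day 0 the day of surgery.
#'
#' @param path CSV file path.
#' @param drop_invalid drop rows with out-of-enumeration values (reported
#'   via a warning) instead of erroring.
#' @return the validated cohort data frame.
#' @export
read_cohort <- function(path, drop_invalid = FALSE) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  validate_cohort(tab, drop_invalid = drop_invalid)
}

#' @rdname read_cohort
#' @param table a cohort data frame.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(table[, .cohort_cols], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname read_cohort
#' @export
validate_cohort <- function(table, drop_invalid = FALSE) {
  missing_cols <- setdiff(.cohort_cols, names(table))
  if (length(missing_cols))
    stop("cohort table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  table <- table[, .cohort_cols]
  bad <- rep(FALSE, nrow(table))
  msgs <- character()
  for (col in names(.cohort_levels)) {
    v <- table[[col]]
    off <- !is.na(v) & !(v %in% .cohort_levels[[col]])
    if (any(off)) {
      bad <- bad | off
      msgs <- c(msgs, sprintf("column '%s': invalid value(s) %s in row(s) %s",
                              col, paste(unique(v[off]), collapse = ", "),
                              paste(utils::head(which(off), 5),
                                    collapse = ", ")))
    }
  }
  off <- !is.na(table$survival_time) & table$survival_time < 0
  if (any(off)) {
    bad <- bad | off
    msgs <- c(msgs, "column 'survival_time': negative value(s)")
  }
  if (length(msgs)) {
    if (!drop_invalid)
      stop("cohort validation failed:\n  ", paste(msgs, collapse = "\n  "))
    warning("dropping ", sum(bad), " invalid row(s):\n  ",
            paste(msgs, collapse = "\n  "))
    table <- table[!bad, ]
  }
  table
}

#' Apply the study exclusions
#'
#' Keeps electively operated patients with known survival status, then
#' administratively censors follow-up at the horizon (survival beyond
#' `horizon` days becomes censored at `horizon`).  Adds analysis columns
#' `time` (truncated follow-up day) and `event` (1 = death within the
#' horizon).
#'
#' @param table validated cohort table.
#' @param horizon administrative follow-up horizon, days.
#' @return list with `table` (the analysis table) and `report` (class
#'   `"exclusion_report"`: counts at each step).
#' @export
apply_exclusions <- function(table, horizon = 180) {
  n0 <- nrow(table)
  elective <- table[!is.na(table$urgency) & table$urgency == "elective", ]
  n1 <- nrow(elective)
  known <- elective[!is.na(elective$status_known) &
                      elective$status_known == 1 &
                      !is.na(elective$vital_status) &
                      !is.na(elective$survival_time), ]
  n2 <- nrow(known)
  over <- known$survival_time > horizon
  known$time <- ifelse(over, horizon, known$survival_time)
  known$event <- as.integer(known$vital_status == "dead" & !over)
  report <- structure(
    data.frame(step = c("total", "elective surgery",
                        "known status and survival time"),
               n = c(n0, n1, n2)),
    class = c("exclusion_report", "data.frame"), horizon = horizon)
  list(table = known, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion chain (follow-up censored at day",
      attr(x, "horizon"), "):\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-32s %d\n", x$step[i], x$n[i]))
  invisible(x)
}

#' Modelling subset: drop follow-up ending before the acute-phase origin
#'
#' The join-point model is left-truncated at the origin (day 3), so
#' subjects whose follow-up ends earlier (chiefly deaths on days 0-2)
#' cannot contribute and are removed; their count is reported.
#'
#' @param table analysis table from [apply_exclusions()].
#' @param origin acute-phase start day; must be positive.
#' @return list with `table`, `dropped_deaths` (early deaths removed) and
#'   `dropped` (all rows removed).
#' @export
modeling_subset <- function(table, origin = 3) {
  if (origin <= 0) stop("origin must be a positive day")
  if (!all(c("time", "event") %in% names(table)))
    stop("run apply_exclusions() first")
  early <- table$time < origin
  list(table = table[!early, ],
       dropped_deaths = sum(early & table$event == 1),
       dropped = sum(early))
}

#' Add the study's categorical groupings
#'
#' Adds `age_group` (0-69, 70-79, 80+), `asa_group` (I, II, III-IV; grades
#' III and IV merged) and `period` (2007-2011, 2012-2016, 2017-2020; other
#' years flagged `"unknown"`).  Missing inputs stay missing.
#'
#' @param table cohort or analysis table.
#' @return the table with the three derived columns.
#' @export
categorize_cohort <- function(table) {
  table$age_group <- ifelse(is.na(table$age), NA_character_,
                            ifelse(table$age <= 69, "0-69",
                                   ifelse(table$age <= 79, "70-79", "80+")))
  table$asa_group <- ifelse(is.na(table$asa), NA_character_,
                            ifelse(table$asa %in% c("III", "IV"), "III-IV",
                                   table$asa))
  table$period <- ifelse(is.na(table$year), NA_character_,
                         ifelse(table$year >= 2007 & table$year <= 2011,
                                "2007-2011",
                         ifelse(table$year >= 2012 & table$year <= 2016,
                                "2012-2016",
                         ifelse(table$year >= 2017 & table$year <= 2020,
                                "2017-2020", "unknown"))))
  table
}

.pct <- function(n, d, digits = 1) {
  ifelse(d > 0, round(100 * n / d, digits), 0)
}

#' Descriptive summary table by tumour site
#'
#' Counts and percentages per site and overall for sex, ASA group, age
#' group, period of surgery and pathological stage, followed by fatality
#' rows (dead by day 30, by day 90, days 0-2, days 3-180, days 0-180, and
#' censored).  Demographic percentages use complete-case denominators (the
#' non-missing count for that variable); fatality percentages use the full
#' group size.  Missingness is reported per variable.
#'
#' @param table categorized analysis table (with `time`/`event`).
#' @param digits decimals for the percentage cells.
#' @return a data frame with columns `variable`, `level`, and `_n`/`_pct`
#'   pairs for colon, rectal and total; missing counts in
#'   `attr(, "missing")`.
#' @export
descriptive_table <- function(table, digits = 1) {
  stopifnot(all(c("time", "event") %in% names(table)))
  groups <- list(colon = table[!is.na(table$site) & table$site == "colon", ],
                 rectal = table[!is.na(table$site) & table$site == "rectal", ],
                 total = table)
  vars <- c("sex", "asa_group", "age_group", "period", "stage")
  lev <- list(sex = c("male", "female"),
              asa_group = c("I", "II", "III-IV"),
              age_group = c("0-69", "70-79", "80+"),
              period = c("2007-2011", "2012-2016", "2017-2020"),
              stage = c("I", "II", "III", "IV", "complete_response"))
  rows <- list(); miss <- list()
  for (v in vars) {
    for (l in lev[[v]]) {
      r <- list(variable = v, level = l)
      for (g in names(groups)) {
        x <- groups[[g]][[v]]
        n <- sum(!is.na(x) & x == l)
        r[[paste0(g, "_n")]] <- n
        r[[paste0(g, "_pct")]] <- .pct(n, sum(!is.na(x)), digits)
      }
      rows[[length(rows) + 1L]] <- r
    }
    miss[[v]] <- vapply(groups, function(g) sum(is.na(g[[v]])), 0)
  }
  fatal <- list(
    "dead day 0-30" = function(d) d$event == 1 & d$time <= 30,
    "dead day 0-90" = function(d) d$event == 1 & d$time <= 90,
    "dead day 0-2" = function(d) d$event == 1 & d$time <= 2,
    "dead day 3-180" = function(d) d$event == 1 & d$time >= 3,
    "dead day 0-180" = function(d) d$event == 1,
    "censored" = function(d) d$event == 0)
  for (f in names(fatal)) {
    r <- list(variable = "fatality", level = f)
    for (g in names(groups)) {
      n <- sum(fatal[[f]](groups[[g]]))
      r[[paste0(g, "_n")]] <- n
      r[[paste0(g, "_pct")]] <- .pct(n, nrow(groups[[g]]), digits)
    }
    rows[[length(rows) + 1L]] <- r
  }
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  attr(out, "missing") <- do.call(rbind, miss)
  out
}

#' Subgroup analysis: fits and comparisons within levels of one factor
#'
#' Splits the modelling cohort by a grouping factor, runs the overall
#' likelihood-ratio gate (all three parameters common vs all free), and -
#' when the gate rejects at `alpha` - the per-parameter equality tests plus
#' per-level fits with profile-likelihood intervals, formatted on the
#' per-1000 reporting scale.
#'
#' @param table categorized analysis table (with `time`/`event`).
#' @param by grouping column, one of the table's categorical columns
#'   (e.g. `"site"`, `"age_group"`, `"asa_group"`, `"period"`).
#' @param within optional named filter, e.g. `c(asa_group = "II")`,
#'   applied before splitting (the nested-subgroup pattern).
#' @param origin,horizon,tau_step as in [jp_fit()].
#' @param level coverage for the profile intervals.
#' @param alpha significance level of the overall gate.
#' @param gate if `FALSE`, run the post-hoc comparisons regardless of the
#'   overall test (exploration override).
#' @param ci if `FALSE`, skip the per-level profile intervals.
#' @return an object of class `"jp_subgroup"`: the overall test, the
#'   per-parameter tests (when run), per-level fits and a formatted
#'   results table.
#' @export
subgroup_fit <- function(table, by, within = NULL, origin = 3,
                         horizon = 180, tau_step = 0.5, level = 0.95,
                         alpha = 0.05, gate = TRUE, ci = TRUE) {
  if (!by %in% names(table)) stop("unknown grouping column '", by, "'")
  if (!is.null(within)) {
    for (k in names(within))
      table <- table[!is.na(table[[k]]) & table[[k]] == within[[k]], ]
  }
  n_missing <- sum(is.na(table[[by]]))
  table <- table[!is.na(table[[by]]), ]   # complete case on the factor
  ms <- modeling_subset(table, origin)
  sp <- split(ms$table[, c("time", "event")], ms$table[[by]])
  sp <- sp[vapply(sp, nrow, 0L) > 0]
  if (length(sp) == 1L) {
    fit <- jp_fit(sp[[1]]$time, sp[[1]]$event, origin = origin,
                  horizon = horizon, tau_step = tau_step)
    return(structure(list(by = by, overall = NULL, tests = NULL,
                          fits = stats::setNames(list(fit), names(sp)),
                          table = .subgroup_table(
                            stats::setNames(list(fit), names(sp)),
                            level, ci),
                          n_missing = n_missing, gated_out = FALSE),
                     class = "jp_subgroup"))
  }
  events <- vapply(sp, function(d) sum(d$event), 0)
  if (any(events == 0))
    stop("stratum '", names(sp)[which(events == 0)[1]],
         "' has no deaths on or after day ", origin,
         ": merge it with a neighbouring stratum")
  overall <- jp_overall_test(sp, origin = origin, horizon = horizon,
                             tau_step = tau_step)
  gated_out <- gate && overall$p_value >= alpha
  tests <- NULL
  if (!gated_out) {
    tests <- lapply(stats::setNames(nm = c("acute", "background", "shift")),
                    function(p) jp_equality_test(sp, p, origin = origin,
                                                 horizon = horizon,
                                                 tau_step = tau_step))
  }
  structure(list(by = by, overall = overall, tests = tests,
                 fits = overall$fits,
                 table = .subgroup_table(overall$fits, level,
                                         ci && !gated_out),
                 n_missing = n_missing, gated_out = gated_out),
            class = "jp_subgroup")
}

.subgroup_table <- function(fits, level, ci) {
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    est <- coef(f, per1000 = TRUE)
    r <- data.frame(level = nm, n = f$n, deaths = f$n_events,
                    acute = round(est[["acute"]], 2),
                    background = round(est[["background"]], 2),
                    shift = round(est[["shift"]], 1),
                    stringsAsFactors = FALSE)
    if (ci) {
      cm <- confint(f, level = level)
      r$acute_ci <- sprintf("%.2f-%.2f", 1000 * cm["acute", 1],
                            1000 * cm["acute", 2])
      r$background_ci <- sprintf("%.2f-%.2f", 1000 * cm["background", 1],
                                 1000 * cm["background", 2])
      r$shift_ci <- sprintf("%.1f-%.1f", cm["shift", 1], cm["shift", 2])
      r$acute_lo <- 1000 * cm["acute", 1]; r$acute_hi <- 1000 * cm["acute", 2]
      r$background_lo <- 1000 * cm["background", 1]
      r$background_hi <- 1000 * cm["background", 2]
      r$shift_lo <- cm["shift", 1]; r$shift_hi <- cm["shift", 2]
    }
    r
  })
  do.call(rbind, rows)
}

#' @export
print.jp_subgroup <- function(x, ...) {
  cat("Subgroup analysis by '", x$by, "'\n", sep = "")
  if (!is.null(x$overall)) {
    cat(sprintf("  overall test: chi-square = %.2f, df = %d, p = %.4g\n",
                x$overall$statistic, x$overall$df, x$overall$p_value))
    if (x$gated_out)
      cat("  gate not passed: per-parameter comparisons withheld\n")
  }
  if (!is.null(x$tests))
    for (nm in names(x$tests))
      cat(sprintf("  equal %s: p = %.4g\n", nm, x$tests[[nm]]$p_value))
  cat("\nRates per 1000 patients and day; days for the phase shift:\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Sensitivity analysis excluding metastatic disease
#'
#' Removes patients with pathological stage IV (and, per the complete-case
#' rule, those with missing stage), rebuilds the modelling subset and
#' refits the overall join-point model.
#'
#' @param table categorized analysis table.
#' @param origin,horizon,tau_step as in [jp_fit()].
#' @return list with the refitted `fit`, `n_excluded` (stage IV) and
#'   `n_missing_stage`.
#' @export
fit_without_stage_iv <- function(table, origin = 3, horizon = 180,
                                 tau_step = 0.5) {
  if (!"stage" %in% names(table)) stop("no 'stage' column")
  iv <- !is.na(table$stage) & table$stage == "IV"
  ms <- modeling_subset(table[!iv & !is.na(table$stage), ], origin)
  fit <- jp_fit(ms$table$time, ms$table$event, origin = origin,
                horizon = horizon, tau_step = tau_step)
  list(fit = fit, n_excluded = sum(iv),
       n_missing_stage = sum(is.na(table$stage)))
}
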