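#' Covariate metadata for the sleep-diary panel model
#'
#' Returns the default covariate specification: 35 covariates in six factor
#' categories (6 stress items, 5 bedtime conditions, 5 weather conditions,
#' 3 physical attributes, 4 exercise dummies, 12 dietary densities).
#' For each covariate the table records whether it varies over diary days,
#' the lag with which it enters each outcome channel, and whether the
#' intervention endpoints are overridden to (0, 1) (the caffeine rule:
#' a rare binary habit has an interquartile range of zero, so its
#' "improvement width" is the full 0 to 1 move).
#'
#' Lag convention: a lag of 0 means the covariate value recorded on the same
#' diary row as the outcome; a lag of 1 means the value from the previous
#' row.  A diary row covers one waking-to-waking cycle, so the bedtime and
#' weather variables on row `t` describe the night/day leading into the
#' morning of row `t`: they act with lag 0 on ease of waking up (`y3`) and
#' with lag 1 on daytime sleepiness (`y1`) and ease of falling asleep
#' (`y2`).  Stress items are recorded at awakening of the same cycle and
#' enter all channels with lag 0.  Time-invariant covariates are constant,
#' so their lag is irrelevant.
#'
#' @return A tibble with columns `name`, `category`, `time_varying`,
#'   `lag_y1`, `lag_y2`, `lag_y3`, `override`.
#' @export
#' @examples
#' sleep_covariates() |> dplyr::count(category)
sleep_covariates <- function() {
  stress  <- paste0("stress", 1:6)
  bedtime <- c("bedtime_hr", "time_in_bed_hr", "caffeine", "alcohol", "ict")
  weather <- c("precip_mm", "temp_mean", "temp_range", "wind_mean", "sunshine_hr")
  physical <- c("age", "bmi", "sbp")
  exercise <- paste0("exercise", 1:4)
  dietary  <- paste0("diet", 1:12)

  tv_lag <- function(names, category, l1, l2, l3) {
    tibble::tibble(name = names, category = category, time_varying = TRUE,
                   lag_y1 = l1, lag_y2 = l2, lag_y3 = l3)
  }
  ti <- function(names, category) {
    tibble::tibble(name = names, category = category, time_varying = FALSE,
                   lag_y1 = 0L, lag_y2 = 0L, lag_y3 = 0L)
  }

  out <- dplyr::bind_rows(
    tv_lag(stress,  "stress",  0L, 0L, 0L),
    tv_lag(bedtime, "bedtime", 1L, 1L, 0L),
    tv_lag(weather, "weather", 1L, 1L, 0L),
    ti(physical, "physical"),
    ti(exercise, "exercise"),
    ti(dietary,  "dietary")
  )
  out$category <- factor(out$category, levels = sleep_categories())
  out$override <- out$name == "caffeine"
  out
}

#' Factor-category names in reporting order
#' @return Character vector of the six covariate categories.
#' @export
sleep_categories <- function() {
  c("stress", "bedtime", "weather", "physical", "exercise", "dietary")
}

validate_covariate_spec <- function(spec) {
  needed <- c("name", "category", "time_varying", "lag_y1", "lag_y2", "lag_y3",
              "override")
  missing <- setdiff(needed, names(spec))
  if (length(missing) > 0) {
    abort_sleepdmpm(paste0("Covariate spec lacks columns: ",
                           paste(missing, collapse = ", ")),
                    "sleepdmpm_schema_error")
  }
  sizes <- table(factor(as.character(spec$category), levels = sleep_categories()))
  expected <- c(stress = 6L, bedtime = 5L, weather = 5L, physical = 3L,
                exercise = 4L, dietary = 12L)
  if (!identical(as.integer(sizes[names(expected)]), unname(expected))) {
    abort_sleepdmpm("Covariate categories must have sizes 6/5/5/3/4/12.",
                    "sleepdmpm_schema_error")
  }
  if (anyDuplicated(spec$name) > 0) {
    abort_sleepdmpm("Covariate names must be unique.", "sleepdmpm_schema_error")
  }
  invisible(spec)
}

#' Convert a clock-time bedtime to hours relative to midnight
#'
#' Diary bedtimes are recorded as "HH:MM" with the evening-to-morning range
#' written on a 24-hour-extended clock (18:00 through 30:00, where 25:30
#' means 1:30 a.m.).  The model uses the signed offset from midnight in
#' hours: positive after midnight, negative before, so a larger value is a
#' later bedtime.
#'
#' @param clock Character vector of "HH:MM" times, HH in 18..30.
#' @return Numeric vector of signed hours relative to 24:00.
#' @export
#' @examples
#' bedtime_to_relative_hours(c("23:30", "24:00", "25:30"))
bedtime_to_relative_hours <- function(clock) {
  clock <- as.character(clock)
  m <- regmatches(clock, regexec("^([0-9]{1,2}):([0-9]{2})$", clock))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    abort_sleepdmpm(paste0("Unparseable bedtime(s): ",
                           paste(unique(clock[bad]), collapse = ", ")),
                    "sleepdmpm_parse_error")
  }
  hh <- vapply(m, function(x) as.numeric(x[2]), numeric(1))
  mm <- vapply(m, function(x) as.numeric(x[3]), numeric(1))
  if (any(hh < 18 | hh > 30) || any(mm >= 60)) {
    abort_sleepdmpm("Bedtime hours must lie in 18:00..30:59 on the extended clock.",
                    "sleepdmpm_parse_error")
  }
  hh + mm / 60 - 24
}

#' Exercise-habit dummy from monthly activity hours
#'
#' Self-reported monthly activity amounts are strongly right-skewed with a
#' median of zero, so each exercise type is entered as an indicator of any
#' activity at all.
#'
#' @param monthly_hours Numeric vector of monthly activity hours (>= 0).
#' @return Integer vector, 1 where activity is strictly positive.
#' @export
exercise_dummy <- function(monthly_hours) {
  if (!is.numeric(monthly_hours) || any(!is.finite(monthly_hours))) {
    abort_sleepdmpm("`monthly_hours` must be finite numeric.", "sleepdmpm_domain_error")
  }
  if (any(monthly_hours < 0)) {
    abort_sleepdmpm("`monthly_hours` must be non-negative.", "sleepdmpm_domain_error")
  }
  as.integer(monthly_hours > 0)
}

#' Energy-standardized dietary density
#'
#' Food-group intakes are expressed per 1000 kcal of daily energy intake so
#' that dietary composition, not total consumption, is compared.
#'
#' @param intake_g_per_day Daily intake of the food group in grams (>= 0).
#' @param energy_kcal_per_day Daily energy intake in kcal (> 0).
#' @return Intake density in g per 1000 kcal.
#' @export
#' @examples
#' standardize_diet(200, 2000)  # 100 g / 1000 kcal
standardize_diet <- function(intake_g_per_day, energy_kcal_per_day) {
  if (any(!is.finite(intake_g_per_day)) || any(intake_g_per_day < 0)) {
    abort_sleepdmpm("`intake_g_per_day` must be finite and non-negative.",
                    "sleepdmpm_domain_error")
  }
  if (any(!is.finite(energy_kcal_per_day)) || any(energy_kcal_per_day <= 0)) {
    abort_sleepdmpm("`energy_kcal_per_day` must be strictly positive.",
                    "sleepdmpm_domain_error")
  }
  intake_g_per_day / energy_kcal_per_day * 1000
}

#' Interquartile intervention endpoints for a covariate
#'
#' The do-intervention contrast moves a covariate between its first and
#' third sample quartiles (linear-interpolation quantiles, type 7).  For a
#' binary covariate whose interquartile range collapses to zero — or when
#' the override flag is set, as for pre-bed caffeine whose sample mean is
#' below 0.25 — the endpoints are the full (0, 1) move instead.
#'
#' @param values Numeric sample of the covariate (>= 4 non-missing values).
#' @param override Use (0, 1) endpoints regardless of the sample quartiles.
#' @return Named numeric vector `c(shift_low = Q1, shift_high = Q3)`.
#' @export
#' @examples
#' compute_shift_endpoints(c(1, 2, 3, 4))
compute_shift_endpoints <- function(values, override = FALSE) {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    abort_sleepdmpm("All values are missing.", "sleepdmpm_domain_error")
  }
  if (length(values) < 4) {
    abort_sleepdmpm("Need at least 4 non-missing values.", "sleepdmpm_domain_error")
  }
  binary <- all(values %in% c(0, 1))
  if (isTRUE(override)) {
    return(c(shift_low = 0, shift_high = 1))
  }
  q <- stats::quantile(values, probs = c(0.25, 0.75), type = 7, names = FALSE)
  if (q[1] == q[2]) {
    if (binary) {
      return(c(shift_low = 0, shift_high = 1))
    }
    abort_sleepdmpm(
      "Degenerate interquartile range on a non-binary covariate.",
      "sleepdmpm_degenerate_iqr")
  }
  c(shift_low = q[1], shift_high = q[2])
}
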