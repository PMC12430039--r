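#' @title Sleep-diary panels
#' @description
#' A sleep panel is a long-format tibble with one row per subject-day:
#' `subject_id`, `day` (1..T, T <= 6 consecutive), the three outcomes
#' `y1` (binary daytime sleepiness), `y2` and `y3` (3-level ease of falling
#' asleep / ease of waking up, 3 = best), the 35 covariates of
#' [sleep_covariates()], and a `subsample` label (gender crossed with
#' season).
#' @name sleep_panel
NULL

#' Gender-by-season subsample labels
#'
#' The four analysis strata: each subsample is modelled separately.
#'
#' @return Character vector of the four labels.
#' @export
subsample_levels <- function() {
  c("male-summer", "male-winter", "female-summer", "female-winter")
}

panel_columns <- function(spec = sleep_covariates()) {
  c("subject_id", "day", "y1", "y2", "y3", spec$name, "subsample")
}

new_sleep_panel <- function(x) {
  class(x) <- unique(c("sleep_panel", class(tibble::as_tibble(x))))
  x
}

#' Validate a sleep panel
#'
#' Checks the schema and the panel invariants: outcome codings, consecutive
#' days starting at 1 with at most six days per subject, constant
#' time-invariant covariates within subject, and known subsample labels.
#'
#' @param panel A data frame of subject-day records.
#' @param spec Covariate specification, see [sleep_covariates()].
#' @return The validated panel (invisibly), with class `sleep_panel`.
#' @export
validate_sleep_panel <- function(panel, spec = sleep_covariates()) {
  validate_covariate_spec(spec)
  cols <- panel_columns(spec)
  missing <- setdiff(cols, names(panel))
  if (length(missing) > 0) {
    abort_sleepdmpm(paste0("Panel lacks columns: ", paste(missing, collapse = ", ")),
                    "sleepdmpm_schema_error")
  }
  panel <- tibble::as_tibble(panel)[cols]

  bad_rows <- function(ok, what) {
    if (!all(ok)) {
      abort_sleepdmpm(
        sprintf("%s (rows: %s)", what,
                paste(utils::head(which(!ok), 10), collapse = ", ")),
        "sleepdmpm_validation_error")
    }
  }
  bad_rows(panel$y1 %in% c(0L, 1L), "y1 must be 0/1")
  bad_rows(panel$y2 %in% 1:3, "y2 must be in {1,2,3}")
  bad_rows(panel$y3 %in% 1:3, "y3 must be in {1,2,3}")
  bad_rows(panel$subsample %in% subsample_levels(),
           "subsample must be gender-season label")

  if (anyDuplicated(panel[c("subject_id", "day")]) > 0) {
    abort_sleepdmpm("Duplicated (subject_id, day) rows.", "sleepdmpm_validation_error")
  }

  by_subj <- split(panel$day, panel$subject_id)
  ok_days <- vapply(by_subj, function(d) {
    d <- sort(d)
    length(d) <= 6 && identical(as.integer(d), seq_len(length(d)))
  }, logical(1))
  if (!all(ok_days)) {
    abort_sleepdmpm(
      paste0("Days must be consecutive 1..T (T <= 6); offending subjects: ",
             paste(utils::head(names(by_subj)[!ok_days], 5), collapse = ", ")),
      "sleepdmpm_validation_error")
  }

  ti_names <- spec$name[!spec$time_varying]
  for (nm in c(ti_names, "subsample")) {
    n_distinct <- vapply(split(panel[[nm]], panel$subject_id),
                         function(v) length(unique(v)), integer(1))
    if (any(n_distinct > 1)) {
      abort_sleepdmpm(
        sprintf("Time-invariant column `%s` varies within a subject.", nm),
        "sleepdmpm_validation_error")
    }
  }
  invisible(new_sleep_panel(panel))
}

#' Read a sleep panel from CSV
#'
#' @param path Path to a UTF-8 comma-separated file with a header row and
#'   one row per subject-day (see [sleep_panel] for the column contract).
#' @param spec Covariate specification.
#' @return A validated `sleep_panel` tibble.
#' @export
read_sleep_panel <- function(path, spec = sleep_covariates()) {
  panel <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (nm in c("day", "y1", "y2", "y3")) {
    if (nm %in% names(panel)) panel[[nm]] <- as.integer(panel[[nm]])
  }
  if ("subject_id" %in% names(panel)) {
    panel$subject_id <- as.character(panel$subject_id)
  }
  validate_sleep_panel(panel, spec)
}

#' Write a sleep panel to CSV
#'
#' @param panel A `sleep_panel` (validated on the way out).
#' @param path Output file path.
#' @param spec Covariate specification.
#' @return `path`, invisibly.
#' @export
write_sleep_panel <- function(panel, path, spec = sleep_covariates()) {
  panel <- validate_sleep_panel(panel, spec)
  readr::write_csv(panel, path, progress = FALSE)
  invisible(path)
}
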