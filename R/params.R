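#' Model parameter sets
#'
#' A `dmpm_params` object collects, for each outcome channel, the intercept
#' (Bernoulli channel) or two ordered cutpoints (cumulative channels), the
#' coefficients of the lagged / same-day outcome terms, and the 35 covariate
#' coefficients.  A `feedback` block (used only by the synthetic-data
#' generator) holds the coefficients through which yesterday's outcomes
#' shift today's stress items.
#'
#' @name dmpm_params
NULL

#' Construct a dmpm_params object
#'
#' @param y1,y2,y3 Per-channel lists.  `y1` has `intercept`, `beta_lag`,
#'   `beta_x`; `y2` and `y3` have `cutpoints` (length 2, strictly
#'   increasing), `beta_lag`, `beta_x`.  `beta_lag` must be named after the
#'   channel's expanded lag terms and `beta_x` after the covariates.
#' @param feedback Optional 6 x 3 matrix (stress items x previous-day
#'   outcome terms `y1`, `y2_score`, `y3_score`) used by the generator.
#' @param channels Channel specification used to check names.
#' @param spec Covariate specification used to check names.
#' @return A validated `dmpm_params` object.
#' @export
dmpm_params <- function(y1, y2, y3, feedback = NULL,
                        channels = channel_spec(), spec = sleep_covariates()) {
  params <- list(y1 = y1, y2 = y2, y3 = y3, feedback = feedback)
  for (ch in c("y1", "y2", "y3")) {
    p <- params[[ch]]
    terms <- channels[[ch]]$lag_terms
    if (!identical(names(p$beta_lag), terms)) {
      abort_sleepdmpm(sprintf("`%s$beta_lag` must be named: %s", ch,
                              paste(terms, collapse = ", ")),
                      "sleepdmpm_config_error")
    }
    if (!identical(names(p$beta_x), spec$name)) {
      abort_sleepdmpm(sprintf("`%s$beta_x` must cover the %d covariates in order.",
                              ch, nrow(spec)), "sleepdmpm_config_error")
    }
    if (channels[[ch]]$family == "cumulative") {
      if (length(p$cutpoints) != 2 || !(p$cutpoints[1] < p$cutpoints[2])) {
        abort_sleepdmpm(sprintf("`%s$cutpoints` must be two strictly increasing values.", ch),
                        "sleepdmpm_config_error")
      }
    } else if (!is.numeric(p$intercept) || length(p$intercept) != 1) {
      abort_sleepdmpm(sprintf("`%s$intercept` must be a scalar.", ch),
                      "sleepdmpm_config_error")
    }
  }
  structure(params, class = "dmpm_params")
}

named_beta <- function(values, names) {
  out <- rep(0, length(names))
  names(out) <- names
  if (!is.null(values)) {
    unknown <- setdiff(names(values), names)
    if (length(unknown) > 0) {
      abort_sleepdmpm(paste0("Unknown coefficient names: ",
                             paste(unknown, collapse = ", ")),
                      "sleepdmpm_config_error")
    }
    out[names(values)] <- values
  }
  out
}

#' Documented ground-truth parameters for simulation studies
#'
#' A fixed, documented parameter set used by the synthetic-data generator:
#' every factor category contains active items and at least one null item
#' (`stress6`, `ict`, `wind_mean`, `sbp`, `exercise4` and `diet7` carry no
#' effect in any channel), outcome persistence (AR(1)) coefficients are
#' positive, and coefficient magnitudes are sized so that interquartile
#' category contrasts land in the single-digit percentage-point range.
#' Intercepts and cutpoints are set so the stationary outcome marginals are
#' plausible (about 30% daytime-sleepiness days; ordinal outcomes
#' concentrated on the middle and top levels).
#'
#' @return A `dmpm_params` object including the generator feedback block.
#' @export
default_true_params <- function() {
  channels <- channel_spec()
  spec <- sleep_covariates()
  nm <- spec$name

  beta_x_y1 <- named_beta(c(
    stress1 = -0.08, stress2 = 0.10, stress4 = -0.06, stress5 = 0.05,
    bedtime_hr = 0.10, time_in_bed_hr = -0.08, caffeine = 0.15,
    precip_mm = 0.02, temp_mean = 0.015, temp_range = 0.04, sunshine_hr = -0.02,
    age = -0.006, bmi = 0.02,
    exercise1 = -0.12, exercise2 = 0.10, exercise3 = -0.10,
    diet1 = 0.0006, diet3 = -0.002, diet4 = -0.0015, diet5 = 0.001,
    diet6 = -0.0015, diet8 = -0.010, diet9 = -0.002, diet10 = 0.0015,
    diet11 = -0.003, diet12 = -0.001), nm)

  beta_x_y2 <- named_beta(c(
    stress1 = 0.08, stress2 = -0.06, stress5 = -0.10,
    bedtime_hr = -0.08, time_in_bed_hr = -0.06, caffeine = -0.20, alcohol = 0.10,
    precip_mm = -0.015, temp_mean = -0.01, temp_range = -0.03,
    age = 0.004, bmi = -0.01,
    exercise2 = 0.08, exercise3 = 0.06,
    diet2 = -0.002, diet4 = 0.002, diet5 = 0.0012, diet6 = 0.001,
    diet9 = 0.0015, diet10 = -0.001, diet12 = 0.0005), nm)

  beta_x_y3 <- named_beta(c(
    stress1 = 0.10, stress3 = 0.06, stress5 = -0.07,
    bedtime_hr = -0.06, time_in_bed_hr = 0.10, caffeine = -0.08, alcohol = -0.10,
    precip_mm = -0.02, temp_mean = 0.01, sunshine_hr = 0.02,
    age = -0.004, bmi = -0.015,
    exercise1 = 0.08, exercise3 = 0.06,
    diet1 = -0.0005, diet2 = 0.002, diet4 = -0.001, diet6 = 0.001,
    diet8 = 0.012, diet9 = 0.0015, diet10 = 0.001, diet12 = 0.001), nm)

  feedback <- rbind(
    stress1 = c(-0.4,  0.2,  0.3),
    stress2 = c( 0.5, -0.2, -0.3),
    stress3 = c(-0.3,  0.0,  0.2),
    stress4 = c(-0.2,  0.0,  0.0),
    stress5 = c( 0.3, -0.2,  0.0),
    stress6 = c( 0.2,  0.0,  0.0))
  colnames(feedback) <- c("y1", "y2_score", "y3_score")

  dmpm_params(
    y1 = list(
      intercept = -0.17,
      beta_lag = named_beta(c(y1_lag1 = 0.8, y2_lag1_2 = -0.2, y2_lag1_3 = -0.4,
                              y3_lag0_2 = -0.3, y3_lag0_3 = -0.5),
                            channels$y1$lag_terms),
      beta_x = beta_x_y1),
    y2 = list(
      cutpoints = c(-1.56, 0.10),
      beta_lag = named_beta(c(y2_lag1_2 = 0.3, y2_lag1_3 = 0.7, y3_lag0_2 = 0.2,
                              y3_lag0_3 = 0.4, y1_lag0 = -0.3),
                            channels$y2$lag_terms),
      beta_x = beta_x_y2),
    y3 = list(
      cutpoints = c(-0.54, 1.25),
      beta_lag = named_beta(c(y3_lag1_2 = 0.3, y3_lag1_3 = 0.6, y1_lag1 = -0.3,
                              y2_lag1_2 = 0.2, y2_lag1_3 = 0.4),
                            channels$y3$lag_terms),
      beta_x = beta_x_y3),
    feedback = feedback,
    channels = channels, spec = spec)
}

#' All-zero parameter variant for null testing
#'
#' Every covariate and lag coefficient is zero; intercept 0 and symmetric
#' cutpoints keep the channels at their family baselines.  Useful for null
#' checks: with these parameters any intervention contrast is exactly zero.
#'
#' @param cutpoints Cutpoints shared by the two cumulative channels.
#' @return A `dmpm_params` object with no feedback block.
#' @export
null_params <- function(cutpoints = c(-0.7, 0.7)) {
  channels <- channel_spec()
  spec <- sleep_covariates()
  zero_ch <- function(ch) {
    p <- list(beta_lag = named_beta(NULL, channels[[ch]]$lag_terms),
              beta_x = named_beta(NULL, spec$name))
    if (channels[[ch]]$family == "bernoulli") p$intercept <- 0
    else p$cutpoints <- cutpoints
    p
  }
  dmpm_params(y1 = zero_ch("y1"), y2 = zero_ch("y2"), y3 = zero_ch("y3"),
              channels = channels, spec = spec)
}

#' Flatten parameters to a named vector (and back)
#'
#' The flat layout is the column layout of posterior draws: per channel
#' (`y1`, `y2`, `y3`) the intercept or `cut1`, `cut2`, then lag terms, then
#' covariates, with names like `"y1:intercept"`, `"y2:cut1"`,
#' `"y1:y1_lag1"`, `"y3:stress1"`.
#'
#' @param params A `dmpm_params` object.
#' @return `params_to_draw`: a named numeric vector. `draw_to_params`: a
#'   `dmpm_params` object (feedback block is not part of the flat layout).
#' @export
params_to_draw <- function(params) {
  out <- c()
  for (ch in c("y1", "y2", "y3")) {
    p <- params[[ch]]
    head <- if (!is.null(p$intercept)) c(intercept = p$intercept)
            else c(cut1 = p$cutpoints[1], cut2 = p$cutpoints[2])
    v <- c(head, p$beta_lag, p$beta_x)
    names(v) <- paste0(ch, ":", names(v))
    out <- c(out, v)
  }
  out
}

#' @rdname params_to_draw
#' @param draw Named numeric vector in the flat layout.
#' @param channels Channel specification.
#' @param spec Covariate specification.
#' @export
draw_to_params <- function(draw, channels = channel_spec(),
                           spec = sleep_covariates()) {
  get <- function(keys) unname(draw[keys])
  chs <- list()
  for (ch in c("y1", "y2", "y3")) {
    terms <- channels[[ch]]$lag_terms
    p <- list(
      beta_lag = stats::setNames(get(paste0(ch, ":", terms)), terms),
      beta_x = stats::setNames(get(paste0(ch, ":", spec$name)), spec$name))
    if (channels[[ch]]$family == "bernoulli") {
      p$intercept <- get(paste0(ch, ":intercept"))
    } else {
      p$cutpoints <- get(paste0(ch, ":", c("cut1", "cut2")))
    }
    chs[[ch]] <- p
  }
  dmpm_params(y1 = chs$y1, y2 = chs$y2, y3 = chs$y3,
              channels = channels, spec = spec)
}
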