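#' Generator configuration
#'
#' Describes the synthetic diary-panel generator: panel size, the
#' ground-truth model parameters, the strength of the feedback from
#' yesterday's outcomes into today's stress items, and the marginal
#' distributions of all covariates.  Defaults are fixture choices meant to
#' be plausible for a healthy adult cohort in a northern-Japan climate:
#' weather is drawn once per (season, day) and shared by all subjects
#' observed in that season (they share a location); summer and winter
#' differ in temperature and sunshine; pre-bed caffeine is rare
#' (Bernoulli p = 0.15, so its sample mean sits below 0.25 and its
#' interquartile range collapses — the case the (0,1) override exists for).
#'
#' @param n_subjects Number of subjects (> 0).
#' @param n_days Diary days per subject (2..6).
#' @param seed Integer seed.
#' @param params Ground-truth `dmpm_params` (with feedback block), see
#'   [default_true_params()].
#' @param feedback_strength Scale applied to the feedback block (0 switches
#'   feedback off).
#' @param subsamples Subsample labels to generate (subjects are split
#'   evenly across them).
#' @param burn_in Pre-days simulated and discarded so that day-1 outcomes
#'   come from the model's stationary-ish marginal.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_subjects = 400, n_days = 6, seed = 1,
                             params = default_true_params(),
                             feedback_strength = 0.3,
                             subsamples = subsample_levels(),
                             burn_in = 10) {
  n_subjects <- assert_scalar_count(n_subjects, "n_subjects")
  n_days <- assert_scalar_count(n_days, "n_days")
  if (n_days < 2 || n_days > 6) {
    abort_sleepdmpm("`n_days` must be in 2..6.", "sleepdmpm_config_error")
  }
  if (!inherits(params, "dmpm_params")) {
    abort_sleepdmpm("`params` must be a dmpm_params object.",
                    "sleepdmpm_config_error")
  }
  if (is.null(params$feedback) && feedback_strength != 0) {
    abort_sleepdmpm("`params` has no feedback block; set feedback_strength = 0.",
                    "sleepdmpm_config_error")
  }
  bad <- setdiff(subsamples, subsample_levels())
  if (length(bad) > 0) {
    abort_sleepdmpm(paste0("Unknown subsample(s): ", paste(bad, collapse = ", ")),
                    "sleepdmpm_config_error")
  }
  structure(list(n_subjects = n_subjects, n_days = n_days, seed = seed,
                 params = params, feedback_strength = feedback_strength,
                 subsamples = subsamples, burn_in = burn_in),
            class = "generator_config")
}

# baseline cumulative-logit cutpoints for the 4-point stress items,
# matching level probabilities (.25, .40, .25, .10)
stress_cutpoints <- function() stats::qlogis(c(0.25, 0.65, 0.90))

rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

# season-dependent shared weather for one day
draw_weather_day <- function(season) {
  wet <- stats::runif(1) < 0.5
  c(precip_mm = if (wet) stats::rlnorm(1, 1, 1) else 0,
    temp_mean = if (season == "summer") stats::rnorm(1, 18, 3) else stats::rnorm(1, -3, 4),
    temp_range = rtrunc_norm(1, 8, 2, lo = 0.5),
    wind_mean = rtrunc_norm(1, 3, 1.2, lo = 0),
    sunshine_hr = if (season == "summer") rtrunc_norm(1, 6, 3, 0, 14)
                  else rtrunc_norm(1, 3, 2, 0, 9))
}

draw_time_invariant <- function(n, gender) {
  diet_means <- c(220, 25, 35, 60, 90, 60, 10, 5, 45, 50, 25, 80)
  diet <- matrix(0, n, 12, dimnames = list(NULL, paste0("diet", 1:12)))
  for (j in 1:12) diet[, j] <- stats::rlnorm(n, log(diet_means[j]) - 0.35^2 / 2, 0.35)
  ex_p <- c(0.5, 0.35, 0.3, 0.2)
  ex <- matrix(0L, n, 4, dimnames = list(NULL, paste0("exercise", 1:4)))
  for (j in 1:4) ex[, j] <- stats::rbinom(n, 1, ex_p[j])
  tibble::as_tibble(cbind(
    age = round(rtrunc_norm(n, 50, 12, 20, 79)),
    bmi = round(rtrunc_norm(n, if (gender == "male") 23.5 else 22, 3, 16, 35), 1),
    sbp = round(rtrunc_norm(n, if (gender == "male") 128 else 122, 15, 90, 180)),
    ex, diet))
}

# stress items as cumulative-logit draws shifted by outcome feedback
draw_stress <- function(prev, fb, strength) {
  n <- length(prev$y1)
  out <- matrix(0L, n, 6, dimnames = list(NULL, paste0("stress", 1:6)))
  z <- cbind(prev$y1, prev$y2 - 2, prev$y3 - 2)
  cp <- stress_cutpoints()
  for (j in 1:6) {
    eta <- if (is.null(fb) || strength == 0) numeric(n)
           else strength * drop(z %*% fb[j, ])
    u <- stats::runif(n)
    q <- vapply(cp, function(ck) stats::plogis(ck - eta), numeric(n))
    out[, j] <- 1L + (u > q[, 1]) + (u > q[, 2]) + (u > q[, 3])
  }
  out
}

draw_bedtime <- function(n) {
  cbind(bedtime_hr = stats::rnorm(n, 0, 1),
        time_in_bed_hr = rtrunc_norm(n, 7.5, 0.8, lo = 4),
        caffeine = stats::rbinom(n, 1, 0.15),
        alcohol = stats::rbinom(n, 1, 0.3),
        ict = stats::rbinom(n, 1, 0.5))
}

#' Generate a synthetic sleep-diary panel
#'
#' Runs the causal system forward under known parameters: time-varying
#' covariates are drawn day by day (stress items receive feedback from the
#' previous day's outcomes; weather is exogenous and shared across subjects
#' within a season-day; bedtime conditions are exogenous), and outcomes are
#' drawn channel by channel in the within-day order `y3 -> y1 -> y2`.  A
#' burn-in of discarded pre-days supplies the day-1 initial condition.
#'
#' @param config A [generator_config()].
#' @return A list of class `sleep_sim` with `panel` (a validated
#'   `sleep_panel`) and `params` (the ground truth used).
#' @export
#' @examples
#' sim <- generate_panel(generator_config(n_subjects = 8, n_days = 3))
#' dim(sim$panel)
generate_panel <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  params <- config$params
  channels <- channel_spec()
  spec <- sleep_covariates()
  B <- config$burn_in
  Tall <- B + config$n_days

  n_sub <- length(config$subsamples)
  sizes <- diff(round(seq(0, config$n_subjects, length.out = n_sub + 1)))
  panels <- vector("list", n_sub)

  for (g in seq_len(n_sub)) {
    lab <- config$subsamples[g]
    n <- sizes[g]
    if (n == 0) next
    gender <- sub("-.*", "", lab)
    season <- sub(".*-", "", lab)

    weather <- t(vapply(seq_len(Tall), function(t) draw_weather_day(season),
                        numeric(5)))
    ti <- draw_time_invariant(n, gender)

    # pre-initial outcome state, washed out by the burn-in
    state <- list(y1 = stats::rbinom(n, 1, 0.3),
                  y2 = sample(1:3, n, replace = TRUE, prob = c(0.2, 0.35, 0.45)),
                  y3 = sample(1:3, n, replace = TRUE, prob = c(0.2, 0.35, 0.45)))

    tv_names <- spec$name[spec$time_varying]
    tv <- array(NA_real_, c(n, Tall, length(tv_names)),
                dimnames = list(NULL, NULL, tv_names))
    outc <- list(y1 = matrix(NA_integer_, n, Tall),
                 y2 = matrix(NA_integer_, n, Tall),
                 y3 = matrix(NA_integer_, n, Tall))

    for (t in seq_len(Tall)) {
      st <- draw_stress(state, params$feedback, config$feedback_strength)
      bt <- draw_bedtime(n)
      tv[, t, colnames(st)] <- st
      tv[, t, colnames(bt)] <- bt
      tv[, t, colnames(weather)] <- matrix(weather[t, ], n, 5, byrow = TRUE)

      cov_now <- function(channel_name) {
        lags <- covariate_lag_column(spec, channel_name)
        x <- matrix(0, n, nrow(spec), dimnames = list(NULL, spec$name))
        for (j in seq_len(nrow(spec))) {
          nm <- spec$name[j]
          if (!spec$time_varying[j]) {
            x[, j] <- ti[[nm]]
          } else {
            l <- lags[j]
            tt <- t - l
            x[, j] <- if (tt >= 1) tv[, tt, nm] else tv[, t, nm]
          }
        }
        x
      }

      if (t == 1) {
        # no lagged record exists yet at the very first pre-day: keep the
        # pre-initial state as that day's outcomes
        outc$y1[, t] <- state$y1
        outc$y2[, t] <- state$y2
        outc$y3[, t] <- state$y3
        next
      }

      cur <- list()
      for (ch in names(channels)) {
        channel <- channels[[ch]]
        pch <- params[[ch]]
        x <- cov_now(ch)
        eta <- drop(x %*% pch$beta_x)
        for (i in seq_len(nrow(channel$parents))) {
          v <- channel$parents$var[i]; l <- channel$parents$lag[i]
          val <- if (l == 0L) cur[[v]] else state[[v]]
          base <- sprintf("%s_lag%d", v, l)
          if (v == "y1") {
            eta <- eta + pch$beta_lag[[base]] * val
          } else {
            eta <- eta + pch$beta_lag[[paste0(base, "_2")]] * (val == 2) +
              pch$beta_lag[[paste0(base, "_3")]] * (val == 3)
          }
        }
        u <- stats::runif(n)
        if (channel$family == "bernoulli") {
          cur[[ch]] <- as.integer(u < stats::plogis(pch$intercept + eta))
        } else {
          q1 <- stats::plogis(pch$cutpoints[1] - eta)
          q2 <- stats::plogis(pch$cutpoints[2] - eta)
          cur[[ch]] <- 1L + (u > q1) + (u > q2)
        }
      }
      outc$y1[, t] <- cur$y1; outc$y2[, t] <- cur$y2; outc$y3[, t] <- cur$y3
      state <- cur
    }

    keep <- (B + 1):Tall
    id0 <- sum(sizes[seq_len(g - 1)])
    rows <- expand.grid(s = seq_len(n), day = seq_along(keep))
    pan <- tibble::tibble(
      subject_id = sprintf("S%04d", id0 + rows$s),
      day = as.integer(rows$day),
      y1 = outc$y1[cbind(rows$s, keep[rows$day])],
      y2 = outc$y2[cbind(rows$s, keep[rows$day])],
      y3 = outc$y3[cbind(rows$s, keep[rows$day])])
    for (nm in tv_names) {
      pan[[nm]] <- tv[cbind(rows$s, keep[rows$day],
                            match(nm, tv_names))]
    }
    for (nm in spec$name[!spec$time_varying]) pan[[nm]] <- ti[[nm]][rows$s]
    pan$subsample <- lab
    panels[[g]] <- pan
  }

  panel <- validate_sleep_panel(dplyr::bind_rows(panels), spec)
  structure(list(panel = panel, params = params, config = config),
            class = "sleep_sim")
}

#' @export
print.sleep_sim <- function(x, ...) {
  cat(sprintf("<sleep_sim> %d subjects x %d days (%d rows), subsamples: %s\n",
              x$config$n_subjects, x$config$n_days, nrow(x$panel),
              paste(x$config$subsamples, collapse = ", ")))
  invisible(x)
}
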