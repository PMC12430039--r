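#' Forward simulation of the outcome system
#'
#' Simulates outcomes for days `t = 2..T` given each subject's day-1
#' outcomes and the observed covariate paths, in the within-day generative
#' order `y3 -> y1 -> y2`.  An optional intervention `policy` implements
#' do-semantics: named covariates are held at fixed values on every day and
#' for every subject (any feedback into them is thereby severed), while all
#' other covariates stay at their observed values.  A `lag_clamp` policy
#' replaces the previous-day outcome vector entering each day's channels
#' with a fixed configuration (used for the AR(1) serial-dependence
#' contrast).
#'
#' Level probabilities are accumulated alongside the sampled outcomes
#' (Rao–Blackwellised means), which estimate the same marginal frequencies
#' with less Monte-Carlo noise.
#'
#' @param params A `dmpm_params` object.
#' @param panel A `sleep_panel` supplying day-1 outcomes and the covariate
#'   path for every subject-day.
#' @param policy `NULL`, or a list with optional elements `covariates`
#'   (named numeric vector of do-values) and `lag_clamp` (named vector
#'   `c(y1 =, y2 =, y3 =)`).
#' @param n_rep Number of Monte-Carlo replicates of the whole panel.
#' @param seed Integer seed.
#' @param channels,spec Model specifications.
#' @return A tibble with columns `day`, `channel`, `level`, `freq`
#'   (empirical frequency of simulated outcomes), `prob` (mean level
#'   probability) and `mc_se`; the attribute `"period_rep"` holds the
#'   per-replicate matrix of level probabilities averaged over subjects and
#'   days 2..T (rows `y1=0`, `y1=1`, `y2=1`..`y3=3`).
#' @export
simulate_forward <- function(params, panel, policy = NULL, n_rep = 100,
                             seed = 1, channels = channel_spec(),
                             spec = sleep_covariates()) {
  n_rep <- assert_scalar_count(n_rep, "n_rep")
  set.seed(seed)
  sim_engine(params, panel, policy, n_rep, channels, spec)
}

# ---- engine (assumes the RNG is already seeded) -------------------------

sim_engine <- function(params, panel, policy, n_rep, channels, spec) {
  panel <- panel[order(panel$subject_id, panel$day), ]
  subjects <- unique(panel$subject_id)
  S <- length(subjects)
  Tmax <- max(panel$day)
  if (Tmax < 2) {
    abort_sleepdmpm("Need at least 2 days to simulate forward.",
                    "sleepdmpm_domain_error")
  }
  si <- match(panel$subject_id, subjects)

  # subject x day arrays; NA where a subject has no such day
  arr <- function(values) {
    m <- matrix(NA_real_, S, Tmax)
    m[cbind(si, panel$day)] <- values
    m
  }
  active <- matrix(FALSE, S, Tmax)
  active[cbind(si, panel$day)] <- TRUE

  do_cov <- policy$covariates
  if (!is.null(do_cov)) {
    bad <- setdiff(names(do_cov), spec$name)
    if (length(bad) > 0) {
      abort_sleepdmpm(paste0("Policy covariate(s) not in the model: ",
                             paste(bad, collapse = ", ")),
                      "sleepdmpm_key_error")
    }
  }
  lag_clamp <- policy$lag_clamp

  X <- lapply(stats::setNames(spec$name, spec$name), function(nm) {
    if (!is.null(do_cov) && nm %in% names(do_cov)) {
      matrix(do_cov[[nm]], S, Tmax)
    } else {
      arr(panel[[nm]])
    }
  })

  # covariate part of each channel's linear predictor, per subject-day
  eta_cov <- lapply(channels, function(channel) {
    lags <- covariate_lag_column(spec, channel$name)
    e <- matrix(0, S, Tmax)
    for (j in seq_len(nrow(spec))) {
      b <- params[[channel$name]]$beta_x[[spec$name[j]]]
      if (b == 0) next
      l <- if (spec$time_varying[j]) lags[j] else 0L
      v <- X[[spec$name[j]]]
      if (l > 0) v <- cbind(matrix(NA_real_, S, l), v[, seq_len(Tmax - l), drop = FALSE])
      e <- e + b * v
    }
    e
  })

  rep_mat <- function(v) matrix(v, S, n_rep)
  y1 <- rep_mat(arr(panel$y1)[, 1])
  y2 <- rep_mat(arr(panel$y2)[, 1])
  y3 <- rep_mat(arr(panel$y3)[, 1])

  level_keys <- c("y1=0", "y1=1", "y2=1", "y2=2", "y2=3",
                  "y3=1", "y3=2", "y3=3")
  # per-day accumulators: subject-mean per rep, then summarised
  day_prob <- array(0, c(length(level_keys), Tmax, n_rep),
                    dimnames = list(level_keys, NULL, NULL))
  day_freq <- day_prob
  n_active_day <- integer(Tmax)

  lag_val <- function(var, lag, cur, prev) {
    if (lag == 0L) return(cur[[var]])
    if (!is.null(lag_clamp)) {
      return(matrix(lag_clamp[[var]], nrow(prev[[var]]), ncol(prev[[var]])))
    }
    prev[[var]]
  }

  for (t in 2:Tmax) {
    act <- which(active[, t])
    n_active_day[t] <- length(act)
    if (length(act) == 0) next
    prev <- list(y1 = y1[act, , drop = FALSE], y2 = y2[act, , drop = FALSE],
                 y3 = y3[act, , drop = FALSE])
    cur <- list()
    for (ch in names(channels)) {  # generative order y3, y1, y2
      channel <- channels[[ch]]
      p <- params[[ch]]
      eta <- matrix(eta_cov[[ch]][act, t], length(act), n_rep)
      for (i in seq_len(nrow(channel$parents))) {
        v <- channel$parents$var[i]; l <- channel$parents$lag[i]
        val <- lag_val(v, l, cur, prev)
        base <- sprintf("%s_lag%d", v, l)
        if (v == "y1") {
          eta <- eta + p$beta_lag[[base]] * val
        } else {
          eta <- eta + p$beta_lag[[paste0(base, "_2")]] * (val == 2) +
            p$beta_lag[[paste0(base, "_3")]] * (val == 3)
        }
      }
      u <- matrix(stats::runif(length(eta)), nrow(eta), ncol(eta))
      if (channel$family == "bernoulli") {
        pr1 <- stats::plogis(p$intercept + eta)
        ynew <- (u < pr1) * 1
        probs <- list(`y1=0` = 1 - pr1, `y1=1` = pr1)
        freqs <- list(`y1=0` = 1 - ynew, `y1=1` = ynew)
      } else {
        q1 <- stats::plogis(p$cutpoints[1] - eta)
        q2 <- stats::plogis(p$cutpoints[2] - eta)
        ynew <- 1 + (u > q1) + (u > q2)
        probs <- stats::setNames(
          list(q1, q2 - q1, 1 - q2), paste0(ch, "=", 1:3))
        freqs <- stats::setNames(
          list((ynew == 1) * 1, (ynew == 2) * 1, (ynew == 3) * 1),
          paste0(ch, "=", 1:3))
      }
      for (key in names(probs)) {
        day_prob[key, t, ] <- colSums(probs[[key]]) / length(act)
        day_freq[key, t, ] <- colSums(freqs[[key]]) / length(act)
      }
      cur[[ch]] <- ynew
    }
    y3[act, ] <- cur$y3; y1[act, ] <- cur$y1; y2[act, ] <- cur$y2
  }

  days <- which(n_active_day > 0)
  by_day <- purrr::map_dfr(days, function(t) {
    tibble::tibble(
      day = t,
      channel = sub("=.*", "", level_keys),
      level = sub(".*=", "", level_keys),
      freq = rowMeans(day_freq[, t, , drop = FALSE]),
      prob = rowMeans(day_prob[, t, , drop = FALSE]),
      mc_se = apply(day_prob[, t, , drop = FALSE], 1, stats::sd) / sqrt(n_rep))
  })

  # period mean over subject-days 2..T, weighting days by active subjects
  w <- n_active_day[days] / sum(n_active_day[days])
  period_rep <- matrix(0, length(level_keys), n_rep,
                       dimnames = list(level_keys, NULL))
  for (i in seq_along(days)) {
    period_rep <- period_rep + w[i] * day_prob[, days[i], ]
  }
  attr(by_day, "period_rep") <- period_rep
  by_day
}

# mean over subjects/days 2..T and reps of Pr(outcome level), with MC SE
period_estimate <- function(sim, outcome) {
  rep_means <- attr(sim, "period_rep")[outcome, ]
  c(mean = mean(rep_means), se = stats::sd(rep_means) / sqrt(length(rep_means)))
}
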