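#' Channel probabilities
#'
#' Evaluates the outcome distribution of one channel given its linear
#' predictor inputs.  The Bernoulli channel returns `(1 - p, p)` with
#' `p = logistic(eta)`; the cumulative-logit channels use
#' `P(y <= k) = logistic(c_k - eta)` and return the three category
#' probabilities by differencing, so a larger `eta` shifts mass towards the
#' top (best) level.
#'
#' @param channel A channel object from [channel_spec()].
#' @param params A `dmpm_params` object.
#' @param parent_values Named list/vector of the channel's parent outcome
#'   values (names as in `channel$parents$var`, values on the outcome
#'   codings; lags resolved by the caller).
#' @param covariates Named numeric vector of the 35 covariates, already
#'   aligned at the channel's lags.
#' @return Numeric vector of level probabilities (length 2 or 3, sums to 1).
#' @export
#' @examples
#' ch <- channel_spec()
#' channel_prob(ch$y1, null_params(), list(y1 = 0, y2 = 1, y3 = 1),
#'              rep(0, 35))
channel_prob <- function(channel, params, parent_values, covariates) {
  p <- params[[channel$name]]
  miss <- setdiff(channel$parents$var, names(parent_values))
  if (length(miss) > 0) {
    abort_sleepdmpm(paste0("Missing parent value(s): ", paste(miss, collapse = ", ")),
                    "sleepdmpm_contract_error")
  }
  z <- numeric(length(channel$lag_terms))
  names(z) <- channel$lag_terms
  for (i in seq_len(nrow(channel$parents))) {
    v <- channel$parents$var[i]; l <- channel$parents$lag[i]
    val <- parent_values[[v]]
    base <- sprintf("%s_lag%d", v, l)
    if (v == "y1") z[base] <- as.numeric(val)
    else {
      z[paste0(base, "_2")] <- as.numeric(val == 2)
      z[paste0(base, "_3")] <- as.numeric(val == 3)
    }
  }
  if (!is.null(names(covariates))) {
    covariates <- unname(unlist(covariates)[names(p$beta_x)])
  }
  eta <- sum(p$beta_lag * z) + sum(p$beta_x * covariates)
  drop(channel_prob_eta(channel$family, p, eta))
}

# vectorized family evaluation: eta vector -> probability matrix
channel_prob_eta <- function(family, p, eta) {
  if (family == "bernoulli") {
    pr <- stats::plogis(p$intercept + eta)
    cbind(`0` = 1 - pr, `1` = pr)
  } else {
    q1 <- stats::plogis(p$cutpoints[1] - eta)
    q2 <- stats::plogis(p$cutpoints[2] - eta)
    cbind(`1` = q1, `2` = q2 - q1, `3` = 1 - q2)
  }
}

# linear predictor (excluding intercept/cutpoints) from a design matrix
channel_eta <- function(p, X, lag_terms) {
  beta <- c(p$beta_lag[lag_terms], p$beta_x)
  drop(X[, names(beta), drop = FALSE] %*% beta)
}

#' Conditional log-likelihood of the panel model
#'
#' Sums, over subjects, days `t = 2..T` and the three channels, the log
#' probability of the observed outcome given its parents — the first diary
#' day is conditioned on as the initial state of the vector autoregression.
#' A zero-probability observation under degenerate parameters yields
#' `-Inf` with attribute `degenerate = TRUE`.
#'
#' @param params A `dmpm_params` object.
#' @param panel A validated `sleep_panel` with at least 2 days per subject.
#' @param channels Channel specification.
#' @param spec Covariate specification.
#' @return Scalar log-likelihood.
#' @export
dmpm_loglik <- function(params, panel, channels = channel_spec(),
                        spec = sleep_covariates()) {
  total <- 0
  for (ch in names(channels)) {
    d <- build_design(panel, channels[[ch]], spec)
    eta <- channel_eta(params[[ch]], d$X, channels[[ch]]$lag_terms)
    pr <- channel_prob_eta(channels[[ch]]$family, params[[ch]], eta)
    obs <- pr[cbind(seq_along(d$y),
                    if (channels[[ch]]$family == "bernoulli") d$y + 1L else d$y)]
    if (any(obs <= 0)) {
      out <- -Inf
      attr(out, "degenerate") <- TRUE
      return(out)
    }
    total <- total + sum(log(obs))
  }
  total
}
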