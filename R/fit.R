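#' Weakly informative default priors
#'
#' Normal(0, 2.5) on all slope coefficients, Normal(0, 5) on the Bernoulli
#' intercept, and Normal(0, 5) on each (order-constrained) cutpoint.
#'
#' @param slope_sd,intercept_sd,cutpoint_sd Prior standard deviations.
#' @return A list of prior standard deviations.
#' @export
dmpm_priors <- function(slope_sd = 2.5, intercept_sd = 5, cutpoint_sd = 5) {
  list(slope_sd = slope_sd, intercept_sd = intercept_sd,
       cutpoint_sd = cutpoint_sd)
}

#' Fit the dynamic multivariate panel model
#'
#' Samples the posterior of all channel parameters with Hamiltonian Monte
#' Carlo.  Conditional on the observed data the three channels factorize,
#' so they are sampled as three independent blocks; draws are returned on
#' the original covariate scale in the flat layout of [params_to_draw()].
#' Convergence is summarised per parameter (split across chains) with
#' R-hat and effective sample size; if more than 5% of parameters have
#' R-hat above 1.05 a convergence warning is attached to the fit (and
#' raised as an R warning), never silently dropped.
#'
#' The paper-style workflow fits one model per gender-season subsample;
#' pass a pre-filtered panel (or use [run_pipeline()]).
#'
#' @param panel A validated `sleep_panel` with at least 2 days per subject.
#' @param spec Covariate specification.
#' @param channels Channel specification.
#' @param chains,warmup,iter MCMC geometry (chains x (warmup + iter)).
#' @param seed Integer seed; fits are bit-reproducible given the seed.
#' @param priors See [dmpm_priors()].
#' @param prior_only Sample from the priors alone (likelihood switched
#'   off), for prior-predictive checks.
#' @return A `dmpm_fit` object: `draws` (tibble with `.chain`,
#'   `.iteration` and one column per parameter), `diagnostics`,
#'   `param_index`, sampler settings and the specifications used.
#' @export
fit_dmpm <- function(panel, spec = sleep_covariates(),
                     channels = channel_spec(),
                     chains = 4, warmup = 500, iter = 500, seed = 1,
                     priors = dmpm_priors(), prior_only = FALSE) {
  panel <- validate_sleep_panel(panel, spec)
  chains <- assert_scalar_count(chains, "chains")
  warmup <- assert_scalar_count(warmup, "warmup")
  iter <- assert_scalar_count(iter, "iter")
  set.seed(seed)

  all_draws <- list()
  accept <- c()
  divergences <- 0L
  n_obs <- c()

  for (ch in c("y1", "y2", "y3")) {
    channel <- channels[[ch]]
    d <- build_design(panel, channel, spec)
    std <- standardize_design(d$X)
    model <- list(family = channel$family, y = d$y, Xs = std$Xs,
                  m = std$m, s = std$s, prior = priors)
    target <- make_channel_target(model, likelihood_weight = if (prior_only) 0 else 1)
    n_extra <- if (channel$family == "bernoulli") 1L else 2L
    p_tot <- ncol(d$X) + n_extra

    ch_draws <- vector("list", chains)
    for (k in seq_len(chains)) {
      init <- stats::rnorm(p_tot, 0, 0.1)
      if (channel$family == "cumulative") {
        init[1] <- -0.5 + stats::rnorm(1, 0, 0.1)
        init[2] <- 0  # log cutpoint gap
      }
      res <- hmc_chain(target, init, n_warmup = warmup, n_iter = iter)
      accept <- c(accept, res$accept_rate)
      divergences <- divergences + res$divergences
      ch_draws[[k]] <- destandardize_draws(res$draws, channel$family, std)
    }
    mat <- do.call(rbind, ch_draws)
    head_names <- if (channel$family == "bernoulli") "intercept" else c("cut1", "cut2")
    colnames(mat) <- paste0(ch, ":", c(head_names, colnames(d$X)))
    all_draws[[ch]] <- mat
    n_obs[ch] <- length(d$y)
  }

  draws_mat <- do.call(cbind, all_draws)
  draws <- tibble::tibble(
    .chain = rep(seq_len(chains), each = iter),
    .iteration = rep(seq_len(iter), times = chains))
  draws <- dplyr::bind_cols(draws, tibble::as_tibble(draws_mat))

  diagnostics <- mcmc_diagnostics(draws_mat, chains, iter)

  fit <- structure(list(
    draws = draws,
    diagnostics = diagnostics,
    param_index = param_index(channels, spec),
    channels = channels,
    spec = spec,
    priors = priors,
    mcmc = list(chains = chains, warmup = warmup, iter = iter, seed = seed),
    n_obs = n_obs,
    n_subjects = length(unique(panel$subject_id)),
    accept_rate = mean(accept),
    divergences = divergences,
    prior_only = prior_only,
    convergence_warning = NULL
  ), class = "dmpm_fit")

  n_bad <- sum(diagnostics$rhat > 1.05, na.rm = TRUE)
  if (chains > 1 && n_bad > 0.05 * nrow(diagnostics)) {
    msg <- sprintf("Convergence warning: %d/%d parameters have R-hat > 1.05.",
                   n_bad, nrow(diagnostics))
    fit$convergence_warning <- msg
    rlang::warn(msg)
  }
  fit
}

# map standardized-scale draws back to the original covariate scale
destandardize_draws <- function(draws, family, std) {
  if (family == "bernoulli") {
    b <- draws[, -1, drop = FALSE]
    b_orig <- sweep(b, 2, std$s, "/")
    a_orig <- draws[, 1] - drop(b %*% (std$m / std$s))
    cbind(a_orig, b_orig)
  } else {
    b <- draws[, -(1:2), drop = FALSE]
    b_orig <- sweep(b, 2, std$s, "/")
    off <- drop(b %*% (std$m / std$s))
    c1 <- draws[, 1] + off
    c2 <- draws[, 1] + exp(draws[, 2]) + off
    cbind(c1, c2, b_orig)
  }
}

param_index <- function(channels, spec) {
  purrr::map_dfr(c("y1", "y2", "y3"), function(ch) {
    head <- if (channels[[ch]]$family == "bernoulli") {
      tibble::tibble(term = "intercept", type = "intercept")
    } else {
      tibble::tibble(term = c("cut1", "cut2"), type = "cutpoint")
    }
    lag <- tibble::tibble(term = channels[[ch]]$lag_terms, type = "lag")
    cov <- tibble::tibble(term = spec$name, type = "covariate")
    out <- dplyr::bind_rows(head, lag, cov)
    out$channel <- ch
    out$parameter <- paste0(ch, ":", out$term)
    out[c("parameter", "channel", "term", "type")]
  })
}

mcmc_diagnostics <- function(draws_mat, chains, iter) {
  per_param <- function(j) {
    x <- draws_mat[, j]
    chains_list <- lapply(seq_len(chains), function(k) {
      coda::mcmc(x[((k - 1) * iter + 1):(k * iter)])
    })
    rhat <- if (chains < 2) NA_real_ else {
      tryCatch(
        coda::gelman.diag(coda::as.mcmc.list(chains_list),
                          autoburnin = FALSE)$psrf[1, 1],
        error = function(e) NA_real_)
    }
    ess <- tryCatch(min(sum(vapply(chains_list, coda::effectiveSize, numeric(1))),
                        chains * iter),
                    error = function(e) NA_real_)
    c(rhat = rhat, ess = ess)
  }
  vals <- vapply(seq_len(ncol(draws_mat)), per_param,
                 c(rhat = 0, ess = 0))
  tibble::tibble(
    parameter = colnames(draws_mat),
    rhat = vals["rhat", ],
    ess = vals["ess", ],
    flag = dplyr::case_when(
      is.na(vals["rhat", ]) ~ "rhat-unavailable",
      vals["rhat", ] > 1.05 ~ "high-rhat",
      TRUE ~ "ok"))
}

#' Machine-readable convergence report
#'
#' @param fit A `dmpm_fit`.
#' @return Tibble of per-parameter R-hat, effective sample size and flags;
#'   with a single chain R-hat is reported as `NA` and flagged.
#' @export
diagnostics_report <- function(fit) {
  stopifnot(inherits(fit, "dmpm_fit"))
  fit$diagnostics
}

#' Extract one posterior draw as a parameter object
#'
#' @param fit A `dmpm_fit`.
#' @param i Row index into the combined draws.
#' @return A `dmpm_params` object.
#' @export
fit_draw_params <- function(fit, i) {
  row <- fit$draws[i, , drop = FALSE]
  v <- unlist(row[, setdiff(names(row), c(".chain", ".iteration"))])
  draw_to_params(v, fit$channels, fit$spec)
}

#' @export
print.dmpm_fit <- function(x, ...) {
  cat(sprintf("<dmpm_fit> %d chains x %d draws (+%d warmup), %d parameters\n",
              x$mcmc$chains, x$mcmc$iter, x$mcmc$warmup,
              nrow(x$param_index)))
  cat(sprintf("  subjects: %d; observations/channel: %s\n", x$n_subjects,
              paste(x$n_obs, collapse = "/")))
  cat(sprintf("  mean acceptance %.2f; divergences %d; max R-hat %.3f\n",
              x$accept_rate, x$divergences,
              suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE))))
  if (!is.null(x$convergence_warning)) cat(" ", x$convergence_warning, "\n")
  invisible(x)
}

#' Tidy posterior summary of a fitted panel model
#'
#' @param x A `dmpm_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: posterior mean, sd, 90%
#'   equal-tailed interval, R-hat and ESS.
#' @exportS3Method generics::tidy
#' @export
tidy.dmpm_fit <- function(x, ...) {
  mat <- as.matrix(x$draws[, x$param_index$parameter])
  qs <- apply(mat, 2, stats::quantile, probs = ci_probs, names = FALSE)
  out <- tibble::tibble(
    parameter = colnames(mat),
    estimate = colMeans(mat),
    std.error = apply(mat, 2, stats::sd),
    conf.low = qs[1, ],
    conf.high = qs[2, ])
  out <- dplyr::left_join(out, x$param_index, by = "parameter")
  dplyr::left_join(out, x$diagnostics[c("parameter", "rhat", "ess")],
                   by = "parameter")
}

#' One-line fit summary
#'
#' @param x A `dmpm_fit`.
#' @param ... Unused.
#' @return A one-row tibble of fit-level facts (size, sampler geometry,
#'   worst diagnostics, convergence flag).
#' @exportS3Method generics::glance
#' @export
glance.dmpm_fit <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects,
    n_obs = sum(x$n_obs),
    chains = x$mcmc$chains,
    iter = x$mcmc$iter,
    warmup = x$mcmc$warmup,
    max_rhat = suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE)),
    min_ess = suppressWarnings(min(x$diagnostics$ess, na.rm = TRUE)),
    divergences = x$divergences,
    converged = is.null(x$convergence_warning))
}
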