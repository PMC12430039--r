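#' Outcome targets of the intervention contrasts
#'
#' The binary channel is summarised at `y1 = 1` (a sleepy day); the two
#' ordinal channels at both ends of their scale (`= 1` worst, `= 3` best).
#'
#' @return Character vector of the five outcome targets.
#' @export
contrast_outcomes <- function() c("y1=1", "y2=1", "y2=3", "y3=1", "y3=3")

# one interquartile do-contrast under fixed parameters: simulate the whole
# panel forward under both endpoint policies (common random numbers) and
# average Pr(outcome) over subjects, days 2..T and replicates
policy_pair_contrast <- function(params, panel, policy_lo, policy_hi,
                                 outcomes, n_rep, seed, channels, spec) {
  set.seed(seed)
  seed_lo <- sample.int(2^31 - 2, 2)
  sim_lo <- simulate_forward(params, panel, policy_lo, n_rep, seed_lo[1],
                             channels, spec)
  sim_hi <- simulate_forward(params, panel, policy_hi, n_rep, seed_lo[1],
                             channels, spec)
  rep_lo <- attr(sim_lo, "period_rep")[outcomes, , drop = FALSE]
  rep_hi <- attr(sim_hi, "period_rep")[outcomes, , drop = FALSE]
  diff_rep <- rep_lo - rep_hi
  tibble::tibble(
    outcome = outcomes,
    delta = unname(abs(rowMeans(diff_rep))),
    raw = unname(rowMeans(diff_rep)),
    mc_se = unname(apply(diff_rep, 1, stats::sd) / sqrt(n_rep)))
}

resolve_draw_list <- function(fit, draw_ids) {
  if (inherits(fit, "dmpm_params")) {
    return(list(ids = 1L, get = function(i) fit))
  }
  if (!inherits(fit, "dmpm_fit")) {
    abort_sleepdmpm("`fit` must be a dmpm_fit or dmpm_params object.",
                    "sleepdmpm_contract_error")
  }
  total <- nrow(fit$draws)
  ids <- draw_ids %||% seq_len(total)
  if (any(ids < 1 | ids > total)) {
    abort_sleepdmpm("`draw_ids` out of range.", "sleepdmpm_domain_error")
  }
  list(ids = ids, get = function(i) fit_draw_params(fit, i))
}

#' Per-item interquartile do-intervention contrast
#'
#' Implements the per-item term of the category improvement metric: for
#' each posterior draw, the panel is simulated forward from every subject's
#' day-1 outcomes twice — once with the item held at its first quartile and
#' once at its third quartile (all other covariates at observed values) —
#' and the absolute change in the mean outcome probability over subjects
#' and days 2..T is recorded.  Endpoints are the item's sample quartiles on
#' this panel; items with the override flag (pre-bed caffeine) use the
#' (0, 1) improvement width instead.  An item whose interquartile range is
#' degenerate (non-binary) is skipped with a warning and contributes zeros.
#'
#' @param fit A `dmpm_fit` (posterior contrast) or a `dmpm_params` object
#'   (single evaluation under known parameters).
#' @param panel The `sleep_panel` the contrast is evaluated on.
#' @param item Covariate name.
#' @param outcomes Outcome targets, see [contrast_outcomes()].
#' @param n_rep Monte-Carlo replicates per policy evaluation.
#' @param seed Integer seed.
#' @param draw_ids Optional subset of posterior draw indices (thinning).
#' @param spec,channels Model specifications.
#' @return Tibble with one row per draw and outcome: `.draw`, `outcome`,
#'   `delta` (the absolute probability change), `raw` (signed, first minus
#'   third quartile policy) and `mc_se`.
#' @export
item_contrast <- function(fit, panel, item, outcomes = contrast_outcomes(),
                          n_rep = 50, seed = 1, draw_ids = NULL,
                          spec = sleep_covariates(),
                          channels = channel_spec()) {
  if (!item %in% spec$name || !item %in% names(panel)) {
    abort_sleepdmpm(sprintf("Unknown item `%s`.", item), "sleepdmpm_key_error")
  }
  override <- spec$override[spec$name == item]
  endpoints <- tryCatch(
    compute_shift_endpoints(panel[[item]], override = override),
    sleepdmpm_degenerate_iqr = function(e) NULL)
  dl <- resolve_draw_list(fit, draw_ids)
  if (is.null(endpoints)) {
    rlang::warn(sprintf(
      "Item `%s` has a degenerate interquartile range; contrast skipped (zeros).",
      item))
    return(tidyr::expand_grid(.draw = dl$ids, outcome = outcomes) |>
             dplyr::mutate(delta = 0, raw = 0, mc_se = 0))
  }
  purrr::map_dfr(seq_along(dl$ids), function(k) {
    res <- policy_pair_contrast(
      dl$get(dl$ids[k]), panel,
      policy_lo = list(covariates = c(endpoints[["shift_low"]]) |>
                         stats::setNames(item)),
      policy_hi = list(covariates = c(endpoints[["shift_high"]]) |>
                         stats::setNames(item)),
      outcomes, n_rep, seed = seed + k, channels = channels, spec = spec)
    res$.draw <- dl$ids[k]
    res[c(".draw", "outcome", "delta", "raw", "mc_se")]
  })
}

#' Serial-dependence (AR(1)) contrast
#'
#' Quantifies how much improving the previous day's outcome vector moves
#' today's outcomes: the lagged outcome values entering every channel are
#' clamped to the best configuration (`y1 = 0, y2 = 3, y3 = 3`) versus the
#' worst (`y1 = 1, y2 = 1, y3 = 1`); same-day outcome edges stay simulated.
#' Averaging and absolute value as in [item_contrast()].
#'
#' @inheritParams item_contrast
#' @param best,worst Clamped lagged-outcome configurations.
#' @return Tibble as in [item_contrast()].
#' @export
ar1_effect <- function(fit, panel, outcomes = contrast_outcomes(),
                       n_rep = 50, seed = 1, draw_ids = NULL,
                       best = c(y1 = 0, y2 = 3, y3 = 3),
                       worst = c(y1 = 1, y2 = 1, y3 = 1),
                       spec = sleep_covariates(), channels = channel_spec()) {
  dl <- resolve_draw_list(fit, draw_ids)
  purrr::map_dfr(seq_along(dl$ids), function(k) {
    res <- policy_pair_contrast(
      dl$get(dl$ids[k]), panel,
      policy_lo = list(lag_clamp = best),
      policy_hi = list(lag_clamp = worst),
      outcomes, n_rep, seed = seed + k, channels = channels, spec = spec)
    res$.draw <- dl$ids[k]
    res[c(".draw", "outcome", "delta", "raw", "mc_se")]
  })
}

#' Category effects by draw-wise summation
#'
#' Sums the per-item absolute probability changes over the items of each
#' factor category, draw by draw, and summarises the sums with the
#' posterior-predictive mean and equal-tailed 90% credibility interval.
#'
#' @param item_samples Tibble of per-item samples (columns `item`,
#'   `.draw`, `outcome`, `delta`), e.g. rows of [item_contrast()] bound
#'   together.
#' @param spec Covariate specification mapping items to categories.
#' @return List with `samples` (category x outcome x draw sums) and
#'   `summary` (mean and 90% interval per category and outcome).
#' @export
category_effect <- function(item_samples, spec = sleep_covariates()) {
  if (nrow(item_samples) == 0) {
    abort_sleepdmpm("Empty item sample set.", "sleepdmpm_domain_error")
  }
  map <- stats::setNames(as.character(spec$category), spec$name)
  bad <- setdiff(unique(item_samples$item), names(map))
  if (length(bad) > 0) {
    abort_sleepdmpm(paste0("Unknown item(s): ", paste(bad, collapse = ", ")),
                    "sleepdmpm_key_error")
  }
  samples <- item_samples |>
    dplyr::mutate(category = map[.data$item]) |>
    dplyr::group_by(.data$category, .data$outcome, .data$.draw) |>
    dplyr::summarise(total = sum(.data$delta), n_items = dplyr::n(),
                     .groups = "drop")
  summary <- samples |>
    dplyr::group_by(.data$category, .data$outcome) |>
    dplyr::summarise(
      mean = mean(.data$total),
      ci_low = stats::quantile(.data$total, ci_probs[1], names = FALSE),
      ci_high = stats::quantile(.data$total, ci_probs[2], names = FALSE),
      .groups = "drop")
  list(samples = samples, summary = summary)
}

#' Full contrast analysis of a fitted model
#'
#' Runs [item_contrast()] for every covariate, [ar1_effect()] for the
#' serial-dependence row, and aggregates category sums — the
#' machine-readable analogue of a per-subsample improvement figure.
#'
#' @inheritParams item_contrast
#' @return A `dmpm_contrast` object: `items` (per-item posterior samples),
#'   `categories` (draw-wise category sums), `summary` (per category and
#'   outcome posterior mean and 90% interval, AR(1) row included) and
#'   `settings`.
#' @export
sleep_contrast <- function(fit, panel, outcomes = contrast_outcomes(),
                           n_rep = 50, seed = 1, draw_ids = NULL,
                           spec = sleep_covariates(),
                           channels = channel_spec()) {
  items <- purrr::imap_dfr(
    stats::setNames(spec$name, spec$name),
    function(item, nm) {
      out <- item_contrast(fit, panel, item, outcomes, n_rep,
                           seed = seed + 1000L * match(nm, spec$name),
                           draw_ids = draw_ids, spec = spec,
                           channels = channels)
      out$item <- item
      out
    })
  ar1 <- ar1_effect(fit, panel, outcomes, n_rep, seed = seed + 900000L,
                    draw_ids = draw_ids, spec = spec, channels = channels)
  cats <- category_effect(items, spec)
  ar1_summary <- ar1 |>
    dplyr::group_by(.data$outcome) |>
    dplyr::summarise(
      mean = mean(.data$delta),
      ci_low = stats::quantile(.data$delta, ci_probs[1], names = FALSE),
      ci_high = stats::quantile(.data$delta, ci_probs[2], names = FALSE),
      .groups = "drop") |>
    dplyr::mutate(category = "ar1", .before = 1)
  summary <- dplyr::bind_rows(cats$summary, ar1_summary) |>
    dplyr::mutate(category = factor(.data$category,
                                    levels = c(sleep_categories(), "ar1"))) |>
    dplyr::arrange(.data$category, .data$outcome)
  structure(list(items = items, categories = cats$samples, ar1 = ar1,
                 summary = summary,
                 settings = list(n_rep = n_rep, seed = seed,
                                 draw_ids = draw_ids, outcomes = outcomes)),
            class = "dmpm_contrast")
}

#' @export
print.dmpm_contrast <- function(x, ...) {
  cat("<dmpm_contrast> category-level interquartile improvement effects\n")
  print(x$summary, n = Inf)
  invisible(x)
}

#' Tidy a contrast result
#'
#' @param x A `dmpm_contrast`.
#' @param ... Unused.
#' @return The category-level summary tibble (posterior mean and 90%
#'   interval per outcome, AR(1) row included).
#' @exportS3Method generics::tidy
#' @export
tidy.dmpm_contrast <- function(x, ...) x$summary

#' Exact interquartile contrast by path enumeration
#'
#' Verification oracle for the Monte-Carlo contrast: on a tiny panel it
#' computes the intervention probabilities exactly, by exhaustive summation
#' over all `(2*3*3)^(T-1)` outcome trajectories per subject, weighted by
#' the channel probabilities.  Limited to `T <= 4` and at most 5 subjects.
#'
#' @param params A `dmpm_params` object (known/true parameters).
#' @param panel Tiny `sleep_panel`.
#' @param item Covariate name; the policy endpoints are its sample
#'   quartiles on this panel (respecting the override flag).
#' @param outcomes Outcome targets.
#' @param spec,channels Model specifications.
#' @return Tibble with `outcome`, `delta` (exact absolute change), `raw`.
#' @export
exact_contrast <- function(params, panel, item,
                           outcomes = contrast_outcomes(),
                           spec = sleep_covariates(),
                           channels = channel_spec()) {
  if (!item %in% spec$name) {
    abort_sleepdmpm(sprintf("Unknown item `%s`.", item), "sleepdmpm_key_error")
  }
  override <- spec$override[spec$name == item]
  endpoints <- compute_shift_endpoints(panel[[item]], override = override)
  lo <- exact_policy_means(params, panel,
                           list(covariates = stats::setNames(
                             c(endpoints[["shift_low"]]), item)),
                           outcomes, spec, channels)
  hi <- exact_policy_means(params, panel,
                           list(covariates = stats::setNames(
                             c(endpoints[["shift_high"]]), item)),
                           outcomes, spec, channels)
  tibble::tibble(outcome = outcomes, delta = unname(abs(lo - hi)),
                 raw = unname(lo - hi))
}

# exact mean Pr(outcome) over subjects and days 2..T under a do-policy
exact_policy_means <- function(params, panel, policy, outcomes,
                               spec = sleep_covariates(),
                               channels = channel_spec()) {
  panel <- panel[order(panel$subject_id, panel$day), ]
  subjects <- unique(panel$subject_id)
  Tmax <- max(panel$day)
  if (Tmax > 4 || length(subjects) > 5) {
    abort_sleepdmpm("Exact enumeration limited to T <= 4 and <= 5 subjects.",
                    "sleepdmpm_size_error")
  }

  # states are full outcome triples in generative order
  states <- expand.grid(y3 = 1:3, y1 = 0:1, y2 = 1:3)
  n_state <- nrow(states)

  lag_terms_eta <- function(ch, prev, cur_partial) {
    channel <- channels[[ch]]
    p <- params[[ch]]
    eta <- 0
    for (i in seq_len(nrow(channel$parents))) {
      v <- channel$parents$var[i]; l <- channel$parents$lag[i]
      val <- if (l == 0L) cur_partial[[v]] else prev[[v]]
      base <- sprintf("%s_lag%d", v, l)
      if (v == "y1") eta <- eta + p$beta_lag[[base]] * val
      else eta <- eta + p$beta_lag[[paste0(base, "_2")]] * (val == 2) +
          p$beta_lag[[paste0(base, "_3")]] * (val == 3)
    }
    eta
  }

  key_mat <- matrix(0, n_state, 8,
                    dimnames = list(NULL, c("y1=0", "y1=1", paste0("y2=", 1:3),
                                            paste0("y3=", 1:3))))
  for (s in seq_len(n_state)) {
    key_mat[s, paste0("y2=", states$y2[s])] <- 1
    key_mat[s, paste0("y3=", states$y3[s])] <- 1
    key_mat[s, paste0("y1=", states$y1[s])] <- 1
  }

  acc <- stats::setNames(numeric(length(outcomes)), outcomes)
  n_subj_days <- 0

  for (sid in subjects) {
    rows <- panel[panel$subject_id == sid, ]
    Ts <- max(rows$day)
    if (Ts < 2) next

    cov_at <- function(day, ch) {
      lags <- covariate_lag_column(spec, ch)
      vapply(seq_len(nrow(spec)), function(j) {
        nm <- spec$name[j]
        if (!is.null(policy$covariates) && nm %in% names(policy$covariates)) {
          return(policy$covariates[[nm]])
        }
        l <- if (spec$time_varying[j]) lags[j] else 0L
        rows[[nm]][rows$day == day - l]
      }, numeric(1))
    }

    # transition matrix prev-state -> new-state for day t
    trans_at <- function(t) {
      tr <- matrix(0, n_state, n_state)
      for (a in seq_len(n_state)) {
        prev <- as.list(states[a, ])
        for (b in seq_len(n_state)) {
          new <- as.list(states[b, ])
          pr <- 1
          for (ch in names(channels)) {
            eta_cov <- sum(params[[ch]]$beta_x * cov_at(t, ch))
            eta <- eta_cov + lag_terms_eta(ch, prev, new)
            probs <- channel_prob_eta(channels[[ch]]$family, params[[ch]], eta)
            idx <- if (ch == "y1") new$y1 + 1L else new[[ch]]
            pr <- pr * probs[1, idx]
          }
          tr[a, b] <- pr
        }
      }
      tr
    }

    init_state <- which(states$y3 == rows$y3[rows$day == 1] &
                          states$y1 == rows$y1[rows$day == 1] &
                          states$y2 == rows$y2[rows$day == 1])

    # exhaustive sum over outcome paths for days 2..Ts
    paths <- as.matrix(expand.grid(rep(list(seq_len(n_state)), Ts - 1)))
    pr_path <- rep(1, nrow(paths))
    trans <- lapply(2:Ts, function(t) trans_at(t))
    for (d in seq_len(Ts - 1)) {
      from <- if (d == 1) rep(init_state, nrow(paths)) else paths[, d - 1]
      pr_path <- pr_path * trans[[d]][cbind(from, paths[, d])]
    }
    for (d in seq_len(Ts - 1)) {
      w <- key_mat[paths[, d], outcomes, drop = FALSE] * pr_path
      acc <- acc + colSums(w)
    }
    n_subj_days <- n_subj_days + (Ts - 1)
  }
  acc / n_subj_days
}
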