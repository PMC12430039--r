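#' Outcome-channel specification
#'
#' The three sleep-quality outcomes form a cross-lagged system with a fixed
#' temporal ordering over one waking-to-waking cycle: ease of waking up
#' (`y3`) is realised first, then daytime sleepiness (`y1`), then ease of
#' falling asleep (`y2`).  Each channel regresses on lagged and same-day
#' outcomes:
#'
#' * `y3` (cumulative logit): previous day's `y3`, `y1`, `y2`;
#' * `y1` (Bernoulli logit): previous day's `y1` and `y2`, same day's `y3`;
#' * `y2` (cumulative logit): previous day's `y2`, same day's `y3` and `y1`.
#'
#' Ordinal parents enter as two indicator contrasts (levels 2 and 3 versus
#' level 1).  The same-day edges (`y3 -> y1`, `y3 -> y2`, `y1 -> y2`) are
#' acyclic and admit the unique topological order `y3, y1, y2`, which is
#' asserted on construction.
#'
#' @return A named list of three channel objects (in generative order
#'   `y3`, `y1`, `y2`), each with `name`, `family`, `parents` (tibble of
#'   `var`, `lag`) and `lag_terms` (expanded coefficient names).
#' @export
channel_spec <- function() {
  ch <- function(name, family, vars, lags) {
    parents <- tibble::tibble(var = vars, lag = as.integer(lags))
    list(name = name, family = family, parents = parents,
         lag_terms = expand_parent_terms(parents))
  }
  spec <- list(
    y3 = ch("y3", "cumulative", c("y3", "y1", "y2"), c(1, 1, 1)),
    y1 = ch("y1", "bernoulli",  c("y1", "y2", "y3"), c(1, 1, 0)),
    y2 = ch("y2", "cumulative", c("y2", "y3", "y1"), c(1, 0, 0))
  )
  assert_acyclic(spec)
  spec
}

# two dummy contrasts for ordinal parents, single column for binary y1
expand_parent_terms <- function(parents) {
  unlist(lapply(seq_len(nrow(parents)), function(i) {
    v <- parents$var[i]; l <- parents$lag[i]
    base <- sprintf("%s_lag%d", v, l)
    if (v == "y1") base else paste0(base, "_", 2:3)
  }), use.names = FALSE)
}

# unique topological order over same-day (lag 0) edges must exist
assert_acyclic <- function(spec) {
  nodes <- names(spec)
  edges <- do.call(rbind, lapply(spec, function(ch) {
    p <- ch$parents[ch$parents$lag == 0L, , drop = FALSE]
    if (nrow(p) == 0) return(NULL)
    cbind(from = p$var, to = ch$name)
  }))
  order <- character(0)
  remaining <- nodes
  while (length(remaining) > 0) {
    indeg <- vapply(remaining, function(n) {
      sum(edges[, "to"] == n & edges[, "from"] %in% remaining)
    }, integer(1))
    free <- remaining[indeg == 0]
    if (length(free) == 0) {
      abort_sleepdmpm("Same-day outcome edges contain a cycle.",
                      "sleepdmpm_dag_error")
    }
    if (length(free) > 1) {
      abort_sleepdmpm("Same-day outcome order is not unique.",
                      "sleepdmpm_dag_error")
    }
    order <- c(order, free)
    remaining <- setdiff(remaining, free)
  }
  if (!identical(order, c("y3", "y1", "y2"))) {
    abort_sleepdmpm("Within-day order must be y3, y1, y2.", "sleepdmpm_dag_error")
  }
  invisible(order)
}

covariate_lag_column <- function(spec, channel_name) {
  spec[[paste0("lag_", channel_name)]]
}

#' Build the regression design for one outcome channel
#'
#' Rows are subject-days with `day >= 2` (day 1 is the initial condition of
#' the vector-autoregression).  Columns are the expanded lagged/same-day
#' outcome terms followed by the 35 covariates, each aligned at its
#' channel-specific lag: lag 0 takes the covariate from the outcome's own
#' row, lag 1 from the previous row.
#'
#' @param panel A validated `sleep_panel`.
#' @param channel A channel object from [channel_spec()].
#' @param spec Covariate specification.
#' @return List with `y` (integer outcomes), `X` (numeric design matrix)
#'   and `rows` (tibble of `subject_id`, `day` for each design row).
#' @export
build_design <- function(panel, channel, spec = sleep_covariates()) {
  panel <- panel[order(panel$subject_id, panel$day), ]
  idx <- which(panel$day >= 2L)
  if (length(idx) == 0) {
    abort_sleepdmpm("Panel needs days >= 2 to build a design.",
                    "sleepdmpm_validation_error")
  }
  # consecutive days within subject make (row - lag) the day - lag record
  lag_row <- function(var, lag) {
    if (lag == 0L) panel[[var]][idx] else panel[[var]][idx - lag]
  }

  lag_cols <- list()
  for (i in seq_len(nrow(channel$parents))) {
    v <- channel$parents$var[i]; l <- channel$parents$lag[i]
    vals <- lag_row(v, l)
    base <- sprintf("%s_lag%d", v, l)
    if (v == "y1") {
      lag_cols[[base]] <- as.numeric(vals)
    } else {
      lag_cols[[paste0(base, "_2")]] <- as.numeric(vals == 2L)
      lag_cols[[paste0(base, "_3")]] <- as.numeric(vals == 3L)
    }
  }

  lags <- covariate_lag_column(spec, channel$name)
  cov_cols <- lapply(seq_len(nrow(spec)), function(j) {
    l <- if (spec$time_varying[j]) lags[j] else 0L
    as.numeric(lag_row(spec$name[j], l))
  })
  names(cov_cols) <- spec$name

  X <- do.call(cbind, c(lag_cols, cov_cols))
  list(y = as.integer(panel[[channel$name]][idx]), X = X,
       rows = tibble::tibble(subject_id = panel$subject_id[idx],
                             day = panel$day[idx]))
}
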