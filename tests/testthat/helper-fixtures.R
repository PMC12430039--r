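# shared fixtures; heavyweight objects are computed once per test run

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

tiny_panel <- function(n_subjects = 6, n_days = 3, seed = 1,
                       subsamples = "male-summer") {
  generate_panel(generator_config(n_subjects = n_subjects, n_days = n_days,
                                  seed = seed, subsamples = subsamples))$panel
}

# hand-built 2-subject panel with fully controlled covariates
manual_panel <- function(n_days = 2, stress1 = NULL) {
  spec <- sleep_covariates()
  rows <- expand.grid(day = seq_len(n_days), subject_id = c("A", "B"))
  panel <- tibble::tibble(
    subject_id = rows$subject_id, day = as.integer(rows$day),
    y1 = rep(c(0L, 1L), length.out = nrow(rows)),
    y2 = rep(c(2L, 3L), length.out = nrow(rows)),
    y3 = rep(c(3L, 1L), length.out = nrow(rows)))
  for (nm in spec$name) panel[[nm]] <- 0
  panel$time_in_bed_hr <- seq(6, 9, length.out = nrow(rows))
  if (!is.null(stress1)) panel$stress1 <- stress1
  panel$subsample <- "male-summer"
  validate_sleep_panel(panel, spec)
}

# the parameter-recovery fit shared by the fit and acceptance tests:
# panel from the documented ground truth (200 subjects x 6 days), sampled
# with 4 chains x (500 warmup + 500 draws)
recovery_fixture <- function() {
  cached("recovery", {
    sim <- generate_panel(generator_config(n_subjects = 200, n_days = 6,
                                           seed = 11))
    fit <- fit_dmpm(sim$panel, chains = 4, warmup = 500, iter = 500,
                    seed = 5)
    list(sim = sim, fit = fit)
  })
}
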