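# a lightweight posterior stand-in: a few draws jittered around the truth
fake_fit <- function(n_draws = 4, sd = 0.05, seed = 71) {
  set.seed(seed)
  flat <- params_to_draw(default_true_params())
  draws <- t(vapply(seq_len(n_draws), function(i) {
    v <- flat + rnorm(length(flat), 0, sd)
    v[c("y2:cut2", "y3:cut2")] <- pmax(v[c("y2:cut2", "y3:cut2")],
                                       v[c("y2:cut1", "y3:cut1")] + 0.05)
    v
  }, flat))
  tib <- dplyr::bind_cols(tibble::tibble(.chain = 1L,
                                         .iteration = seq_len(n_draws)),
                          tibble::as_tibble(draws))
  sleepdmpm:::fit_from_draws(tib)
}

test_that("the static single-channel contrast matches the logistic closed form", {
  # no dynamics, intercept 0, unit coefficient, endpoints (0, 1):
  # |logistic(0) - logistic(1)| = 0.2310586
  p <- null_params()
  p$y1$beta_x[["stress1"]] <- 1
  panel <- manual_panel(n_days = 2, stress1 = c(0, 1, 1, 0))
  ex <- exact_contrast(p, panel, "stress1")
  expect_equal(ex$delta[ex$outcome == "y1=1"],
               abs(plogis(0) - plogis(1)), tolerance = 1e-10)
  mc <- item_contrast(p, panel, "stress1", n_rep = 200, seed = 5)
  expect_equal(mc$delta[mc$outcome == "y1=1"],
               abs(plogis(0) - plogis(1)), tolerance = 1e-4)
})

test_that("Monte-Carlo contrasts agree with exhaustive enumeration", {
  tp <- default_true_params()
  panel <- tiny_panel(n_subjects = 2, n_days = 3, seed = 72,
                      subsamples = "male-winter")
  for (item in c("bedtime_hr", "temp_mean", "time_in_bed_hr")) {
    ex <- exact_contrast(tp, panel, item)
    mc <- item_contrast(tp, panel, item, n_rep = 3000, seed = 6)
    z <- abs(ex$raw - mc$raw) / pmax(mc$mc_se, 1e-8)
    expect_true(all(z <= 3), label = paste(item, "within 3 MC SEs"))
  }
})

test_that("null items contrast to exactly zero under the truth", {
  tp <- default_true_params()
  panel <- tiny_panel(n_subjects = 3, n_days = 3, seed = 73)
  ex <- exact_contrast(tp, panel, "diet7")
  expect_identical(ex$delta, rep(0, 5))
  mc <- item_contrast(tp, panel, "diet7", n_rep = 50, seed = 7)
  expect_identical(mc$delta, rep(0, 5))  # common random numbers: exact null
})

test_that("enumeration contrast is monotone in the coefficient magnitude", {
  # symmetric endpoints around zero keep the logistic away from its
  # saturating range, where monotonicity in |beta| holds
  panel <- manual_panel(n_days = 3, stress1 = c(-3, -1, 1, 3, -2, 2))
  deltas <- vapply(c(0, 0.2, 0.5, 1, 2), function(b) {
    p <- null_params()
    p$y1$beta_x[["stress1"]] <- b
    exact_contrast(p, panel, "stress1")$delta[1]
  }, numeric(1))
  expect_true(all(diff(deltas) >= 0))
  expect_equal(deltas[1], 0)
})

test_that("enumeration guard rejects oversized instances", {
  tp <- default_true_params()
  big <- tiny_panel(n_subjects = 8, n_days = 3, seed = 74)
  expect_error(exact_contrast(tp, big, "stress1"),
               class = "sleepdmpm_size_error")
  long <- tiny_panel(n_subjects = 2, n_days = 5, seed = 74)
  expect_error(exact_contrast(tp, long, "stress1"),
               class = "sleepdmpm_size_error")
})

test_that("category sums are draw-wise additive with percentile intervals", {
  set.seed(75)
  items <- tidyr::expand_grid(item = c("stress1", "stress2", "exercise1"),
                              .draw = 1:50, outcome = "y1=1")
  items$delta <- runif(nrow(items), 0, 0.05)
  ce <- category_effect(items)
  by_hand <- items |>
    dplyr::filter(.data$item %in% c("stress1", "stress2")) |>
    dplyr::group_by(.data$.draw) |>
    dplyr::summarise(total = sum(.data$delta))
  got <- ce$samples[ce$samples$category == "stress", ]
  expect_equal(got$total[order(got$.draw)], by_hand$total[order(by_hand$.draw)])
  s <- ce$summary[ce$summary$category == "stress", ]
  expect_equal(s$ci_low, quantile(by_hand$total, 0.05, names = FALSE))
  expect_equal(s$ci_high, quantile(by_hand$total, 0.95, names = FALSE))
  expect_equal(s$mean, mean(by_hand$total))
  # constant samples add exactly
  const <- tidyr::expand_grid(item = c("diet1", "diet2"), .draw = 1:3,
                              outcome = "y2=3")
  const$delta <- ifelse(const$item == "diet1", 0.02, 0.03)
  expect_equal(unique(category_effect(const)$samples$total), 0.05)
  expect_error(category_effect(items[0, ]), class = "sleepdmpm_domain_error")
})

test_that("AR(1) clamping behaves as a serial-dependence contrast", {
  panel <- tiny_panel(n_subjects = 5, n_days = 4, seed = 76)
  nolag <- default_true_params()
  for (cc in c("y1", "y2", "y3")) nolag[[cc]]$beta_lag[] <- 0
  z <- ar1_effect(nolag, panel, n_rep = 30, seed = 8)
  # clamping only touches lag-1 values, so with zero lag coefficients
  # every channel is unmoved
  expect_true(all(z$delta == 0))
  # positive persistence: improving yesterday helps in every draw
  ff <- fake_fit(n_draws = 4)
  pos <- ar1_effect(ff, panel, n_rep = 60, seed = 9)
  expect_true(all(pos$delta > 0))
  # identical clamp configurations cancel exactly
  same <- ar1_effect(default_true_params(), panel, n_rep = 20, seed = 10,
                     best = c(y1 = 0, y2 = 3, y3 = 3),
                     worst = c(y1 = 0, y2 = 3, y3 = 3))
  expect_true(all(same$delta == 0))
})

test_that("contrasts are bounded and stable across seeds", {
  tp <- default_true_params()
  panel <- tiny_panel(n_subjects = 20, n_days = 4, seed = 77)
  a <- item_contrast(tp, panel, "caffeine", n_rep = 400, seed = 11)
  b <- item_contrast(tp, panel, "caffeine", n_rep = 400, seed = 12)
  expect_true(all(a$delta >= 0 & a$delta <= 1))
  comb <- sqrt(a$mc_se^2 + b$mc_se^2)
  expect_true(all(abs(a$raw - b$raw) <= 3 * pmax(comb, 1e-8)))
})

test_that("the caffeine override forces (0,1) endpoints", {
  panel <- tiny_panel(n_subjects = 30, n_days = 4, seed = 78)
  expect_lt(mean(panel$caffeine), 0.25)
  spec <- sleep_covariates()
  expect_true(spec$override[spec$name == "caffeine"])
  ep <- compute_shift_endpoints(panel$caffeine,
                                override = spec$override[spec$name == "caffeine"])
  expect_equal(unname(ep), c(0, 1))
  # and even without the flag the degenerate binary rule applies
  expect_equal(unname(compute_shift_endpoints(panel$caffeine)), c(0, 1))
})

test_that("degenerate non-binary items are skipped with zero contribution", {
  tp <- default_true_params()
  panel <- tiny_panel(n_subjects = 6, n_days = 3, seed = 79)
  panel$temp_range <- 5  # constant within file -> no interquartile move
  expect_warning(
    res <- item_contrast(tp, panel, "temp_range", n_rep = 10, seed = 13),
    "degenerate")
  expect_true(all(res$delta == 0))
})

test_that("full contrast objects tidy into the category summary", {
  ff <- fake_fit(n_draws = 3)
  panel <- tiny_panel(n_subjects = 8, n_days = 3, seed = 80)
  res <- suppressWarnings(
    sleep_contrast(ff, panel, n_rep = 10, seed = 14))
  expect_s3_class(res, "dmpm_contrast")
  expect_setequal(as.character(unique(res$summary$category)),
                  c(sleep_categories(), "ar1"))
  expect_equal(tidy(res), res$summary)
  # draw-wise additivity holds inside the assembled object
  stress_items <- sleep_covariates()$name[
    sleep_covariates()$category == "stress"]
  one <- res$items[res$items$item %in% stress_items &
                     res$items$outcome == "y1=1", ]
  manual <- tapply(one$delta, one$.draw, sum)
  got <- res$categories[res$categories$category == "stress" &
                          res$categories$outcome == "y1=1", ]
  expect_equal(as.numeric(manual[as.character(got$.draw)]), got$total)
})
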