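test_that("simulated level frequencies normalize and reproduce", {
  panel <- tiny_panel(n_subjects = 6, n_days = 4, seed = 51)
  tp <- default_true_params()
  sim <- simulate_forward(tp, panel, n_rep = 40, seed = 7)
  sums <- sim |>
    dplyr::group_by(.data$day, .data$channel) |>
    dplyr::summarise(freq = sum(.data$freq), prob = sum(.data$prob),
                     .groups = "drop")
  expect_equal(sums$freq, rep(1, nrow(sums)))
  expect_equal(sums$prob, rep(1, nrow(sums)))
  sim2 <- simulate_forward(tp, panel, n_rep = 40, seed = 7)
  expect_equal(sim, sim2)
  expect_error(simulate_forward(tp, panel, n_rep = 0),
               class = "sleepdmpm_domain_error")
})

test_that("a do-policy on a null covariate changes nothing", {
  panel <- tiny_panel(n_subjects = 6, n_days = 4, seed = 52)
  tp <- default_true_params()  # diet7 carries no effect in any channel
  base <- simulate_forward(tp, panel, n_rep = 30, seed = 9)
  pol <- simulate_forward(tp, panel, policy = list(covariates = c(diet7 = 99)),
                          n_rep = 30, seed = 9)
  expect_equal(base, pol)
  expect_error(
    simulate_forward(tp, panel, policy = list(covariates = c(nope = 1)),
                     n_rep = 5),
    class = "sleepdmpm_key_error")
})

test_that("one-step frequencies match the analytic channel probabilities", {
  # single subject, one transition: the marginal of day 2 is available in
  # closed form from the channel families given day-1 values
  panel <- manual_panel(n_days = 2)
  panel <- panel[panel$subject_id == "A", ]
  tp <- default_true_params()
  sim <- simulate_forward(tp, panel, n_rep = 1e5, seed = 13)
  ch <- channel_spec()
  spec <- sleep_covariates()
  row1 <- panel[panel$day == 1, ]
  row2 <- panel[panel$day == 2, ]
  # y3 depends only on day-1 outcomes; enumerate the rest
  cov_for <- function(cc) {
    lags <- spec[[paste0("lag_", cc)]]
    vapply(seq_len(nrow(spec)), function(j) {
      l <- if (spec$time_varying[j]) lags[j] else 0L
      src <- if (l == 1) row1 else row2
      src[[spec$name[j]]]
    }, numeric(1))
  }
  p_y3 <- channel_prob(ch$y3, tp, list(y3 = row1$y3, y1 = row1$y1,
                                       y2 = row1$y2), cov_for("y3"))
  # marginal of y1 integrates over today's y3
  p_y1 <- Reduce(`+`, lapply(1:3, function(k) {
    p_y3[[k]] * channel_prob(ch$y1, tp, list(y1 = row1$y1, y2 = row1$y2,
                                             y3 = k), cov_for("y1"))
  }))
  got <- sim[sim$day == 2, ]
  exp_y3 <- unname(p_y3)
  mc <- got$freq[got$channel == "y3"]
  se <- sqrt(exp_y3 * (1 - exp_y3) / 1e5)
  expect_true(all(abs(mc - exp_y3) <= 3 * pmax(se, 1e-6)))
  mc1 <- got$freq[got$channel == "y1"]
  se1 <- sqrt(p_y1 * (1 - p_y1) / 1e5)
  expect_true(all(abs(mc1 - unname(p_y1)) <= 3 * pmax(se1, 1e-6)))
})

test_that("clamping the lagged outcome vector identically is a no-op", {
  panel <- tiny_panel(n_subjects = 5, n_days = 4, seed = 54)
  tp <- default_true_params()
  a <- simulate_forward(tp, panel,
                        policy = list(lag_clamp = c(y1 = 0, y2 = 3, y3 = 3)),
                        n_rep = 25, seed = 3)
  b <- simulate_forward(tp, panel,
                        policy = list(lag_clamp = c(y1 = 0, y2 = 3, y3 = 3)),
                        n_rep = 25, seed = 3)
  expect_equal(a, b)
})

test_that("with zero covariate effects, covariates are exchangeable", {
  # outcomes then depend on lagged outcomes only: permuting covariate paths
  # across subjects leaves the distribution of simulated statistics alone
  panel <- tiny_panel(n_subjects = 30, n_days = 4, seed = 55)
  p <- default_true_params()
  for (cc in c("y1", "y2", "y3")) p[[cc]]$beta_x[] <- 0
  perm <- panel
  spec <- sleep_covariates()
  set.seed(99)
  reorder <- sample(unique(panel$subject_id))
  for (nm in spec$name) {
    src <- split(panel[[nm]], panel$subject_id)
    perm[[nm]] <- unsplit(src[reorder], perm$subject_id)
  }
  a <- simulate_forward(p, panel, n_rep = 200, seed = 61)
  b <- simulate_forward(p, perm, n_rep = 200, seed = 62)
  ks <- suppressWarnings(stats::ks.test(attr(a, "period_rep")["y1=1", ],
                                        attr(b, "period_rep")["y1=1", ]))
  expect_gt(ks$p.value, 0.01)
})
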