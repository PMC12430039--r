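test_that("channel probabilities follow the logistic families", {
  ch <- channel_spec()
  zero <- null_params()
  pv <- list(y1 = 0, y2 = 1, y3 = 1)
  expect_equal(channel_prob(ch$y1, zero, pv, rep(0, 35)),
               c(`0` = 0.5, `1` = 0.5))
  # cutpoints at logit(1/3), logit(2/3) and eta = 0 give equal thirds
  p3 <- null_params(cutpoints = qlogis(c(1 / 3, 2 / 3)))
  expect_equal(channel_prob(ch$y2, p3, pv, rep(0, 35)),
               c(`1` = 1 / 3, `2` = 1 / 3, `3` = 1 / 3))
  # a huge linear predictor saturates the bernoulli channel
  big <- null_params()
  big$y1$intercept <- 500
  expect_equal(channel_prob(ch$y1, big, pv, rep(0, 35)), c(`0` = 0, `1` = 1))
  expect_error(channel_prob(ch$y1, zero, list(y1 = 0), rep(0, 35)),
               class = "sleepdmpm_contract_error")
  # probabilities sum to one for random parameters
  set.seed(41)
  for (i in 1:10) {
    flat <- params_to_draw(p3) + rnorm(125, 0, 0.5)
    flat[c("y2:cut2", "y3:cut2")] <-
      pmax(flat[c("y2:cut2", "y3:cut2")],
           flat[c("y2:cut1", "y3:cut1")] + 0.1)
    pr <- draw_to_params(flat)
    pv2 <- list(y1 = rbinom(1, 1, 0.5), y2 = sample(1:3, 1), y3 = sample(1:3, 1))
    for (cc in c("y1", "y2", "y3")) {
      expect_equal(sum(channel_prob(ch[[cc]], pr, pv2, rnorm(35))), 1)
    }
  }
})

test_that("log-likelihood matches the closed form on a minimal panel", {
  panel <- manual_panel(n_days = 2)
  p3 <- null_params(cutpoints = qlogis(c(1 / 3, 2 / 3)))
  # one transition: bernoulli at 1/2, two cumulative channels at 1/3 each
  expect_equal(dmpm_loglik(p3, panel),
               2 * (log(1 / 2) + 2 * log(1 / 3)))
})

test_that("log-likelihood agrees with a naive per-row oracle", {
  set.seed(42)
  ch <- channel_spec()
  spec <- sleep_covariates()
  for (rep in 1:5) {
    panel <- tiny_panel(n_subjects = 4, n_days = 4, seed = 42 + rep)
    flat <- params_to_draw(default_true_params())
    flat <- flat + rnorm(length(flat), 0, 0.02)
    flat[c("y2:cut2", "y3:cut2")] <-
      pmax(flat[c("y2:cut2", "y3:cut2")],
           flat[c("y2:cut1", "y3:cut1")] + 0.1)
    pr <- draw_to_params(flat)
    # oracle: loop rows and channels, evaluate channel_prob directly
    ordered <- panel[order(panel$subject_id, panel$day), ]
    naive <- 0
    for (i in which(ordered$day >= 2)) {
      prev <- ordered[i - 1, ]
      cur <- ordered[i, ]
      for (cc in c("y1", "y2", "y3")) {
        pv <- list()
        for (k in seq_len(nrow(ch[[cc]]$parents))) {
          v <- ch[[cc]]$parents$var[k]
          l <- ch[[cc]]$parents$lag[k]
          pv[[v]] <- if (l == 1) prev[[v]] else cur[[v]]
        }
        lags <- spec[[paste0("lag_", cc)]]
        x <- vapply(seq_len(nrow(spec)), function(j) {
          l <- if (spec$time_varying[j]) lags[j] else 0L
          src <- if (l == 1) prev else cur
          src[[spec$name[j]]]
        }, numeric(1))
        probs <- channel_prob(ch[[cc]], pr, pv, x)
        lev <- if (cc == "y1") cur$y1 + 1 else cur[[cc]]
        naive <- naive + log(probs[[lev]])
      }
    }
    expect_equal(dmpm_loglik(pr, panel), naive, tolerance = 1e-10)
  }
})

test_that("log-likelihood is additive over channels and exchangeable", {
  panel <- tiny_panel(n_subjects = 5, n_days = 3, seed = 44)
  pr <- default_true_params()
  ch <- channel_spec()
  per_channel <- vapply(c("y1", "y2", "y3"), function(cc) {
    d <- build_design(panel, ch[[cc]])
    eta <- sleepdmpm:::channel_eta(pr[[cc]], d$X, ch[[cc]]$lag_terms)
    prm <- sleepdmpm:::channel_prob_eta(ch[[cc]]$family, pr[[cc]], eta)
    sum(log(prm[cbind(seq_along(d$y),
                      if (cc == "y1") d$y + 1L else d$y)]))
  }, numeric(1))
  expect_equal(dmpm_loglik(pr, panel), sum(per_channel))
  shuffled <- panel[sample(nrow(panel)), ]
  expect_equal(dmpm_loglik(pr, shuffled), dmpm_loglik(pr, panel))
})

test_that("posterior gradients match central finite differences", {
  set.seed(45)
  panel <- tiny_panel(n_subjects = 8, n_days = 3, seed = 45)
  ch <- channel_spec()
  for (cc in c("y1", "y2")) {
    d <- build_design(panel, ch[[cc]])
    std <- sleepdmpm:::standardize_design(d$X)
    model <- list(family = ch[[cc]]$family, y = d$y, Xs = std$Xs,
                  m = std$m, s = std$s, prior = dmpm_priors())
    tgt <- sleepdmpm:::make_channel_target(model)
    p <- ncol(d$X) + if (ch[[cc]]$family == "bernoulli") 1 else 2
    th <- rnorm(p, 0, 0.3)
    g <- tgt(th)$grad
    gn <- vapply(seq_len(p), function(j) {
      e <- rep(0, p); e[j] <- 1e-5
      (tgt(th + e)$lp - tgt(th - e)$lp) / 2e-5
    }, numeric(1))
    expect_equal(unname(g), gn, tolerance = 1e-6)
  }
})
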