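test_that("fitting is deterministic given the seed", {
  panel <- tiny_panel(n_subjects = 12, n_days = 3, seed = 61)
  a <- suppressWarnings(fit_dmpm(panel, chains = 2, warmup = 120, iter = 60,
                                 seed = 42))
  b <- suppressWarnings(fit_dmpm(panel, chains = 2, warmup = 120, iter = 60,
                                 seed = 42))
  expect_identical(a$draws, b$draws)
  c <- suppressWarnings(fit_dmpm(panel, chains = 2, warmup = 120, iter = 60,
                                 seed = 43))
  expect_false(identical(a$draws, c$draws))
})

test_that("cutpoint ordering holds in every posterior draw", {
  panel <- tiny_panel(n_subjects = 12, n_days = 3, seed = 62)
  fit <- suppressWarnings(fit_dmpm(panel, chains = 2, warmup = 120, iter = 80,
                                   seed = 1))
  expect_true(all(fit$draws[["y2:cut2"]] > fit$draws[["y2:cut1"]]))
  expect_true(all(fit$draws[["y3:cut2"]] > fit$draws[["y3:cut1"]]))
  td <- tidy(fit)
  expect_equal(nrow(td), 125)
  expect_true(all(is.finite(td$estimate)))
  g <- glance(fit)
  expect_true(all(td$ess <= g$chains * g$iter))
})

test_that("prior-predictive draws respect constraints without degeneracy", {
  panel <- tiny_panel(n_subjects = 8, n_days = 3, seed = 63)
  fit <- suppressWarnings(
    fit_dmpm(panel, chains = 2, warmup = 150, iter = 150, seed = 2,
             prior_only = TRUE))
  expect_true(all(fit$draws[["y2:cut2"]] > fit$draws[["y2:cut1"]]))
  # implied baseline level-1 probabilities cover (0,1) non-degenerately
  base <- plogis(fit$draws[["y2:cut1"]])
  expect_lt(quantile(base, 0.1), 0.25)
  expect_gt(quantile(base, 0.9), 0.75)
  # prior sd on slopes is respected roughly (weakly informative scale)
  expect_gt(sd(fit$draws[["y1:caffeine"]]), 1)
})

test_that("diagnostics flag degenerate and single-chain cases", {
  diag1 <- sleepdmpm:::mcmc_diagnostics(
    matrix(rnorm(100), 100, 1, dimnames = list(NULL, "p")), chains = 1,
    iter = 100)
  expect_true(is.na(diag1$rhat))
  expect_equal(diag1$flag, "rhat-unavailable")
  # two identical constant chains: R-hat undefined, flagged
  diag2 <- sleepdmpm:::mcmc_diagnostics(
    matrix(1, 80, 1, dimnames = list(NULL, "p")), chains = 2, iter = 40)
  expect_true(is.na(diag2$rhat) || !is.finite(diag2$rhat))
  expect_true(diag2$flag != "ok")
})

test_that("the sampler matches an independent Gibbs implementation", {
  skip_if_not_installed("rjags")
  # Bayesian logistic regression, p = 4: sample the same posterior with
  # the package's Hamiltonian sampler and with JAGS, compare moments
  set.seed(64)
  n <- 300
  X <- cbind(rnorm(n), rbinom(n, 1, 0.4), rnorm(n, 0, 2))
  beta_true <- c(0.8, -0.6, 0.3)
  y <- rbinom(n, 1, plogis(-0.4 + X %*% beta_true))

  std <- sleepdmpm:::standardize_design(X)
  colnames(std$Xs) <- paste0("x", 1:3)
  model <- list(family = "bernoulli", y = y, Xs = std$Xs, m = std$m,
                s = std$s, prior = dmpm_priors())
  tgt <- sleepdmpm:::make_channel_target(model)
  set.seed(65)
  draws <- do.call(rbind, lapply(1:2, function(k) {
    sleepdmpm:::hmc_chain(tgt, rnorm(4, 0, 0.1), n_warmup = 400,
                          n_iter = 600)$draws
  }))
  mine <- sleepdmpm:::destandardize_draws(draws, "bernoulli", std)

  jm <- rjags::jags.model(
    textConnection("
      model {
        for (i in 1:n) {
          y[i] ~ dbern(ilogit(a + inprod(X[i,], b[])))
        }
        a ~ dnorm(0, 1 / 25)
        for (j in 1:3) { b[j] ~ dnorm(0, 1 / 6.25) }
      }"),
    data = list(y = y, X = X, n = n),
    inits = list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 66),
    n.chains = 1, n.adapt = 500, quiet = TRUE)
  js <- rjags::coda.samples(jm, c("a", "b"), n.iter = 4000)[[1]]

  ref <- colMeans(js)[c("a", "b[1]", "b[2]", "b[3]")]
  got <- colMeans(mine)
  expect_equal(unname(got), unname(ref), tolerance = 0.03)
  ref_sd <- apply(js, 2, sd)[c("a", "b[1]", "b[2]", "b[3]")]
  got_sd <- apply(mine, 2, sd)
  expect_equal(unname(got_sd), unname(ref_sd), tolerance = 0.1)
})

test_that("posterior intervals contract as the panel grows", {
  width <- function(n, seed) {
    sim <- generate_panel(generator_config(n_subjects = n, n_days = 5,
                                           seed = seed))
    fit <- suppressWarnings(fit_dmpm(sim$panel, chains = 2, warmup = 300,
                                     iter = 300, seed = seed))
    td <- tidy(fit)
    td$conf.high - td$conf.low
  }
  w_small <- width(60, 67)
  w_large <- width(240, 67)
  expect_lt(median(w_large / w_small), 0.75)
})

test_that("large panels recover the serial-dependence coefficients", {
  sim <- generate_panel(generator_config(n_subjects = 2000, n_days = 6,
                                         seed = 68))
  fit <- fit_dmpm(sim$panel, chains = 2, warmup = 250, iter = 250, seed = 3)
  td <- tidy(fit)
  truth <- params_to_draw(default_true_params())
  ar <- td[td$type == "lag", ]
  err <- abs(ar$estimate - truth[ar$parameter])
  expect_lt(max(err), 0.1)
  expect_true(is.null(fit$convergence_warning))
})
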