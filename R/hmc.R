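# Hamiltonian Monte Carlo over a single channel's posterior.
#
# Each channel is a Bernoulli- or cumulative-logit regression, so its
# posterior is log-concave and well suited to gradient-based sampling.
# Design columns are standardized internally (priors stay on the original
# scale); cutpoints are sampled as (c1, log(c2 - c1)) with the log-Jacobian
# included so the ordering constraint holds in every draw.

# ---- per-channel log posterior and gradient (standardized scale) --------

# model: list(family, y, Xs, m, s, prior) where Xs is the standardized
# design, m/s the column centers/scales, prior = list(slope_sd,
# intercept_sd, cutpoint_sd).  likelihood_weight 0 gives a prior-only
# target (prior-predictive checks).
make_channel_target <- function(model, likelihood_weight = 1) {
  family <- model$family
  y <- model$y
  Xs <- model$Xs
  m <- model$m
  s <- model$s
  pr <- model$prior
  p <- ncol(Xs)
  force(likelihood_weight)

  if (family == "bernoulli") {
    function(theta) {
      alpha <- theta[1]
      b <- theta[-1]
      lp <- 0; ga <- 0; gb <- numeric(p)
      if (likelihood_weight > 0) {
        eta <- alpha + drop(Xs %*% b)
        ll <- sum(ifelse(y == 1L, stats::plogis(eta, log.p = TRUE),
                         stats::plogis(-eta, log.p = TRUE)))
        r <- y - stats::plogis(eta)
        lp <- lp + likelihood_weight * ll
        ga <- ga + likelihood_weight * sum(r)
        gb <- gb + likelihood_weight * drop(crossprod(Xs, r))
      }
      b_orig <- b / s
      a_orig <- alpha - sum(b * m / s)
      lp <- lp + sum(stats::dnorm(b_orig, 0, pr$slope_sd, log = TRUE)) +
        stats::dnorm(a_orig, 0, pr$intercept_sd, log = TRUE)
      d_borig <- -b_orig / pr$slope_sd^2
      d_aorig <- -a_orig / pr$intercept_sd^2
      gb <- gb + d_borig / s + d_aorig * (-m / s)
      ga <- ga + d_aorig
      list(lp = lp, grad = c(ga, gb))
    }
  } else {
    function(theta) {
      c1 <- theta[1]
      d <- theta[2]
      c2 <- c1 + exp(d)
      b <- theta[-(1:2)]
      lp <- 0; g1 <- 0; g2 <- 0; gb <- numeric(p)
      if (likelihood_weight > 0) {
        eta <- drop(Xs %*% b)
        a1 <- c1 - eta
        a2 <- c2 - eta
        F1 <- stats::plogis(a1)
        F2 <- stats::plogis(a2)
        k1 <- y == 1L; k2 <- y == 2L; k3 <- y == 3L
        p2 <- pmax(F2 - F1, 1e-300)
        ll <- sum(stats::plogis(a1[k1], log.p = TRUE)) +
          sum(log(p2[k2])) +
          sum(stats::plogis(-a2[k3], log.p = TRUE))
        gc1 <- numeric(length(y)); gc2 <- numeric(length(y))
        gc1[k1] <- 1 - F1[k1]
        f1 <- F1 * (1 - F1); f2 <- F2 * (1 - F2)
        gc1[k2] <- -f1[k2] / p2[k2]
        gc2[k2] <- f2[k2] / p2[k2]
        gc2[k3] <- -F2[k3]
        lp <- lp + likelihood_weight * ll
        g1 <- g1 + likelihood_weight * sum(gc1 + gc2)
        g2 <- g2 + likelihood_weight * sum(gc2) * exp(d)
        gb <- gb + likelihood_weight * drop(crossprod(Xs, -(gc1 + gc2)))
      }
      off <- sum(b * m / s)
      b_orig <- b / s
      c_orig <- c(c1, c2) + off
      lp <- lp + sum(stats::dnorm(b_orig, 0, pr$slope_sd, log = TRUE)) +
        sum(stats::dnorm(c_orig, 0, pr$cutpoint_sd, log = TRUE)) + d
      d_borig <- -b_orig / pr$slope_sd^2
      d_corig <- -c_orig / pr$cutpoint_sd^2
      gb <- gb + d_borig / s + sum(d_corig) * (m / s)
      g1 <- g1 + sum(d_corig)
      g2 <- g2 + d_corig[2] * exp(d) + 1
      list(lp = lp, grad = c(g1, g2, gb))
    }
  }
}

standardize_design <- function(X) {
  m <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  fixed <- !is.finite(s) | s < 1e-12
  m[fixed] <- 0
  s[fixed] <- 1
  Xs <- sweep(sweep(X, 2, m, "-"), 2, s, "/")
  list(Xs = Xs, m = m, s = s)
}

# ---- sampler -------------------------------------------------------------

leapfrog <- function(theta, r, eps, grad, minv) {
  r <- r + 0.5 * eps * grad(theta)
  theta <- theta + eps * (minv * r)
  r <- r + 0.5 * eps * grad(theta)
  list(theta = theta, r = r)
}

find_epsilon <- function(target, theta, minv) {
  eps <- 0.1
  t0 <- target(theta)
  r <- stats::rnorm(length(theta)) / sqrt(minv)
  h0 <- t0$lp - 0.5 * sum(minv * r^2)
  step <- function(eps) {
    r1 <- r + 0.5 * eps * t0$grad
    th1 <- theta + eps * (minv * r1)
    t1 <- target(th1)
    if (!is.finite(t1$lp)) return(-Inf)
    r1 <- r1 + 0.5 * eps * t1$grad
    t1$lp - 0.5 * sum(minv * r1^2) - h0
  }
  a <- if (step(eps) > log(0.5)) 1 else -1
  for (i in 1:40) {
    eps2 <- eps * 2^a
    if (a * step(eps2) <= a * log(0.5)) break
    eps <- eps2
  }
  eps
}

# static-trajectory HMC with dual-averaging step size and a diagonal mass
# matrix estimated during a middle warmup window (Stan-like schedule).
hmc_chain <- function(target, init, n_warmup, n_iter, L_base = 12,
                      accept_target = 0.8) {
  p <- length(init)
  theta <- init
  minv <- rep(1, p)
  cur <- target(theta)
  if (!is.finite(cur$lp)) {
    abort_sleepdmpm("Non-finite log posterior at the initial point.",
                    "sleepdmpm_fit_error")
  }
  grad_only <- function(th) target(th)$grad

  w1 <- min(75L, max(10L, floor(n_warmup * 0.15)))
  w3 <- min(50L, max(10L, floor(n_warmup * 0.1)))
  w2 <- n_warmup - w1 - w3
  window_draws <- matrix(0, max(w2, 1), p)

  draws <- matrix(0, n_iter, p)
  accept <- 0
  divergences <- 0

  # dual averaging state
  da_init <- function(eps) list(mu = log(10 * eps), log_eps = log(eps),
                                log_eps_bar = 0, h_bar = 0, count = 0)
  da_update <- function(da, a) {
    da$count <- da$count + 1
    frac <- 1 / (da$count + 10)
    da$h_bar <- (1 - frac) * da$h_bar + frac * (accept_target - a)
    da$log_eps <- da$mu - sqrt(da$count) / 0.05 * da$h_bar
    w <- da$count^(-0.75)
    da$log_eps_bar <- w * da$log_eps + (1 - w) * da$log_eps_bar
    da
  }

  eps <- find_epsilon(target, theta, minv)
  da <- da_init(eps)
  phase_end_adapt <- function() exp(da$log_eps_bar)

  total <- n_warmup + n_iter
  for (i in seq_len(total)) {
    adapting <- i <= n_warmup
    eps_i <- if (adapting) exp(da$log_eps) else eps
    L <- sample(max(1L, floor(L_base * 0.7)):ceiling(L_base * 1.3), 1)
    r0 <- stats::rnorm(p) / sqrt(minv)
    h0 <- cur$lp - 0.5 * sum(minv * r0^2)
    th <- theta; r <- r0
    ok <- TRUE
    for (l in seq_len(L)) {
      st <- leapfrog(th, r, eps_i, grad_only, minv)
      th <- st$theta; r <- st$r
      if (any(!is.finite(th))) { ok <- FALSE; break }
    }
    if (ok) {
      prop <- target(th)
      h1 <- if (is.finite(prop$lp)) prop$lp - 0.5 * sum(minv * r^2) else -Inf
      dh <- h1 - h0
      if (!is.finite(dh)) dh <- -Inf
      a_stat <- min(1, exp(dh))
      if (dh < -1000) divergences <- divergences + 1
      if (log(stats::runif(1)) < dh) {
        theta <- th; cur <- prop
        if (!adapting) accept <- accept + 1
      }
    } else {
      a_stat <- 0
      divergences <- divergences + 1
      stats::runif(1)  # keep the RNG stream aligned across accept paths
    }

    if (adapting) {
      da <- da_update(da, a_stat)
      if (i > w1 && i <= w1 + w2) window_draws[i - w1, ] <- theta
      if (i == w1 + w2 && w2 > 5) {
        v <- apply(window_draws[seq_len(w2), , drop = FALSE], 2, stats::var)
        n <- w2
        minv <- (n / (n + 5)) * v + (5 / (n + 5)) * 1e-3
        minv[minv < 1e-8] <- 1e-8
        eps0 <- find_epsilon(target, theta, minv)
        da <- da_init(eps0)
      }
      if (i == n_warmup) eps <- phase_end_adapt()
    } else {
      draws[i - n_warmup, ] <- theta
    }
  }

  list(draws = draws, accept_rate = accept / n_iter, eps = eps,
       divergences = divergences, minv = minv)
}
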