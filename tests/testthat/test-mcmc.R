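test_that("log joint density matches hand-computed values", {
  tab <- count_table(c("a", "b"), c(0L, 0L), c(1, 1))
  p <- prior_spec("uniform_sigma", 0, 500)
  # two Poisson(1) zeros contribute -2; two standard-normal zeros
  # contribute -log(2*pi); the flat prior contributes -log(500)
  expect_equal(log_joint(tab, 0, c(0, 0), 1, p),
               -2 - log(2 * pi) - log(500), tolerance = 1e-12)

  # Poisson log-pmf at C=2, lambda=1: 2*0 - 1 - log(2!)
  tab2 <- count_table(c("a", "b"), c(2L, 0L), c(1, 1))
  expect_equal(log_joint(tab2, 0, c(0, 0), 1, p) -
                 log_joint(tab, 0, c(0, 0), 1, p),
               -1.693147 - (-1), tolerance = 1e-6)

  # outside the prior support
  p6 <- prior_spec("uniform_sigma", 1, 500)
  expect_identical(log_joint(tab, 0, c(0, 0), 0.5, p6), -Inf)
  expect_identical(log_joint(tab, 0, c(0, 0), -1, p), -Inf)
  ph <- prior_spec("hierarchical_uniform_sigma")
  expect_identical(log_joint(tab, 0, c(0, 0), 3, ph, lb = 0, ub = 2), -Inf)
  expect_true(is.finite(log_joint(tab, 0, c(0, 0), 1, ph, lb = 0.5, ub = 2)))
  pg <- prior_spec("gamma_precision", gamma_shape = 1, gamma_rate = 1)
  expect_true(is.finite(log_joint(tab, 0, c(0, 0), 1, pg)))
  expect_error(log_joint(tab, 0, c(0, 0, 0), 1, p), "per area")
})

test_that("sampler recovers a no-heterogeneity posterior", {
  fit <- fit_bayes(homogeneous_table(27, 1000),
                   prior_spec("uniform_sigma", 0, 500),
                   quick_mcmc(seed = 31))
  expect_lt(abs(mean(fit$mu)), 0.05)
  expect_lt(quantile(fit$sigma, 0.9), 0.1)
  expect_true(fit$diagnostics$rhat[["mu"]] < 1.1)
  # lambda identity holds draw-wise
  s <- c(1L, 17L, 203L)
  expect_equal(fit$lambda[s, 3],
               exp(fit$mu[s] + fit$nu[s, 3]) * fit$data$expected[3])
})

test_that("posterior matches the conjugate closed form when shrunk to it", {
  # With sigma pinned near zero the model collapses to C_i ~ Poisson(g E_i)
  # with flat prior on log g, so g = exp(mu) has posterior
  # Gamma(sum C, sum E): an end-to-end analytic check of the sampler.
  tab <- toy_table(4L)
  fit <- fit_bayes(tab, prior_spec("uniform_sigma", 1e-4, 2e-4),
                   mcmc_config(n_chains = 2, n_iter = 5000, n_burnin = 2500,
                               seed = 32))
  g <- exp(fit$mu)
  sC <- sum(tab$observed); sE <- sum(tab$expected)
  expect_lt(abs(mean(g) - sC / sE), 0.04)
  expect_lt(abs(sd(g) / (sqrt(sC) / sE) - 1), 0.15)
  for (pr in c(0.05, 0.5, 0.95))
    expect_lt(abs(quantile(g, pr) - qgamma(pr, sC, sE)), 0.06)
})

test_that("sampler agrees with an independent reference implementation", {
  # Reference: plain componentwise random-walk MH written in R on top of
  # log_joint (a separate code path from the compiled sampler), gamma
  # prior on the precision.
  tab <- count_table(c("x", "y", "z"), c(4L, 0L, 9L), c(3, 2, 6))
  prior <- prior_spec("gamma_precision", gamma_shape = 2, gamma_rate = 1)
  ref_sampler <- function(n_iter, seed) {
    set.seed(seed)
    mu <- 0; nu <- rep(0, 3); sigma <- 0.7
    out_mu <- numeric(n_iter); out_sig <- numeric(n_iter)
    out_nu <- matrix(0, n_iter, 3)
    lj <- log_joint(tab, mu, nu, sigma, prior)
    for (s in seq_len(n_iter)) {
      prop <- mu + 0.35 * rnorm(1)
      ljp <- log_joint(tab, prop, nu, sigma, prior)
      if (log(runif(1)) < ljp - lj) { mu <- prop; lj <- ljp }
      for (i in 1:3) {
        nup <- nu; nup[i] <- nu[i] + 0.6 * rnorm(1)
        ljp <- log_joint(tab, mu, nup, sigma, prior)
        if (log(runif(1)) < ljp - lj) { nu <- nup; lj <- ljp }
      }
      sp <- abs(sigma + 0.4 * rnorm(1))
      ljp <- log_joint(tab, mu, nu, sp, prior)
      if (log(runif(1)) < ljp - lj) { sigma <- sp; lj <- ljp }
      out_mu[s] <- mu; out_sig[s] <- sigma; out_nu[s, ] <- nu
    }
    keep <- seq(2001L, n_iter)
    list(mu = out_mu[keep], sigma = out_sig[keep], nu = out_nu[keep, ])
  }
  ref <- ref_sampler(22000L, seed = 33)
  fit <- fit_bayes(tab, prior,
                   mcmc_config(n_chains = 2, n_iter = 10000,
                               n_burnin = 3000, seed = 34))
  expect_lt(abs(mean(fit$mu) - mean(ref$mu)), 0.06)
  expect_lt(abs(mean(fit$sigma) - mean(ref$sigma)), 0.06)
  expect_lt(abs(quantile(fit$sigma, 0.9) - quantile(ref$sigma, 0.9)), 0.12)
  lam_ref <- colMeans(exp(ref$mu + ref$nu) *
                        rep(tab$expected, each = length(ref$mu)))
  expect_lt(max(abs(colMeans(fit$lambda) - lam_ref)), 0.25)
})

test_that("bounded uniform priors constrain every sigma draw", {
  tab <- homogeneous_table(10, 50)
  fit <- fit_bayes(tab, prior_spec("uniform_sigma", 1, 500),
                   quick_mcmc(seed = 35))
  expect_true(all(fit$sigma >= 1))
  expect_true(all(fit$sigma <= 500))
})

test_that("hierarchical bounds stay ordered and bracket sigma", {
  tab <- toy_table()
  fit <- fit_bayes(tab, model_prior(7), quick_mcmc(seed = 36))
  expect_true(all(fit$lb >= 0 & fit$lb <= 5))
  expect_true(all(fit$ub >= fit$lb & fit$ub <= 500))
  expect_true(all(fit$sigma >= fit$lb & fit$sigma <= fit$ub))
})

test_that("permuting areas permutes the posterior summaries", {
  tab <- toy_table()
  perm <- c(3L, 1L, 5L, 2L, 4L)
  tab_p <- count_table(tab$area[perm], tab$observed[perm],
                       tab$expected[perm])
  fit <- fit_bayes(tab, prior_spec("uniform_sigma", 0, 500),
                   quick_mcmc(seed = 37, n_iter = 8000, n_burnin = 2000))
  fit_p <- fit_bayes(tab_p, prior_spec("uniform_sigma", 0, 500),
                     quick_mcmc(seed = 38, n_iter = 8000, n_burnin = 2000))
  iv <- lambda_intervals(fit); iv_p <- lambda_intervals(fit_p)
  m <- match(iv$area, iv_p$area)
  # identical up to Monte-Carlo error (chains consume randomness in a
  # different area order, so bit-identity is not expected)
  expect_lt(max(abs(iv$point - iv_p$point[m]) /
                  pmax(iv$point, 0.3)), 0.15)
})

test_that("credible intervals follow the fixed quantile convention", {
  tab <- count_table(c("a", "b"), c(5L, 7L), c(5, 7))
  lam <- cbind(1:100, rep(7, 100))
  fit <- fake_fit(lam, tab)
  iv <- lambda_intervals(fit, 0.95, method = "fake")
  expect_equal(iv$point, c(50.5, 7))
  expect_equal(iv$lower, c(unname(quantile(1:100, 0.025)), 7))
  expect_equal(iv$upper, c(unname(quantile(1:100, 0.975)), 7))
  expect_equal(iv$lower[1], 3.475)   # type-7 quantile, frozen
  expect_equal(iv$upper[1], 97.525)
  expect_error(lambda_intervals(fit, 1.2), "level")
  expect_error(lambda_intervals(fake_fit(lam[1:50, ], tab)), "100 kept")
})

test_that("split-Rhat and ESS behave on known chains", {
  expect_equal(rhat_ess(list(rep(3, 100), rep(3, 100)))[["rhat"]], 1)
  set.seed(41)
  same <- list(rnorm(5000), rnorm(5000))
  expect_lt(rhat_ess(same)[["rhat"]], 1.01)
  apart <- list(rnorm(5000), rnorm(5000, mean = 5))
  expect_gt(rhat_ess(apart)[["rhat"]], 1.1)
  one <- rhat_ess(list(rnorm(500)))
  expect_true(is.na(one[["rhat"]]))
  expect_gt(one[["ess"]], 100)
  # strongly autocorrelated chain has a much smaller ESS than draws
  ar <- as.numeric(arima.sim(list(ar = 0.95), 5000))
  expect_lt(rhat_ess(list(ar, ar + 0))[["ess"]], 2000)
})
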