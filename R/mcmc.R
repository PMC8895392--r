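#' Log joint density of the Poisson random-effects model
#'
#' Evaluates, up to nothing (all normalising constants included), the log
#' of the joint density of data and parameters:
#' \deqn{\sum_i [C_i(\mu+\nu_i+\log E_i) - E_i e^{\mu+\nu_i} - \log C_i!]
#'       + \sum_i \log N(\nu_i; 0, \sigma^2) + \log p(\sigma)}
#' Returns `-Inf` for states outside the prior support.
#'
#' @param table a [count_table()].
#' @param mu intercept (log overall relative risk).
#' @param nu numeric vector of area random effects, length `nrow(table)`.
#' @param sigma random-effect standard deviation, > 0.
#' @param prior a [prior_spec()]; for the hierarchical family the bounds
#'   `lb`/`ub` arguments give the current bound values.
#' @param lb,ub current bounds when `prior` is hierarchical.
#' @return A single numeric log density (possibly `-Inf`).
#' @export
log_joint <- function(table, mu, nu, sigma, prior, lb = NULL, ub = NULL) {
  stopifnot(inherits(table, "count_table"), inherits(prior, "prior_spec"))
  if (length(nu) != nrow(table))
    stop("nu must have one element per area")
  if (!is.finite(sigma) || sigma <= 0) return(-Inf)
  lam <- exp(mu + nu) * table$expected
  ll <- sum(stats::dpois(table$observed, lam, log = TRUE)) +
    sum(stats::dnorm(nu, 0, sigma, log = TRUE))
  lp <- switch(prior$family,
    uniform_sigma = {
      if (sigma <= prior$lb || sigma >= prior$ub) -Inf
      else -log(prior$ub - prior$lb)
    },
    hierarchical_uniform_sigma = {
      if (is.null(lb)) lb <- 0
      if (is.null(ub)) ub <- prior$ub_hyper_max
      if (lb < 0 || lb > prior$lb_hyper_max || ub < lb ||
          ub > prior$ub_hyper_max || sigma <= lb || sigma >= ub) -Inf
      else -log(prior$lb_hyper_max) - log(prior$ub_hyper_max - lb) -
        log(ub - lb)
    },
    gamma_precision = {
      tau <- 1 / sigma^2
      # density of tau transformed to the sigma scale: |dtau/dsigma| = 2/sigma^3
      stats::dgamma(tau, prior$gamma_shape, rate = prior$gamma_rate,
                    log = TRUE) + log(2) - 3 * log(sigma)
    })
  ll + lp
}

#' Fit the Poisson random-effects model by MCMC
#'
#' Runs `n_chains` Metropolis-within-Gibbs chains for the model
#' \eqn{C_i \sim \mathrm{Poisson}(e^{\mu+\nu_i} E_i)}, \eqn{\nu_i \sim
#' N(0,\sigma^2)}, under the prior in `prior`.  The intercept and each
#' random effect move by adaptive random-walk Metropolis; for the
#' gamma-precision family \eqn{\tau} is drawn from its conjugate
#' conditional \eqn{\mathrm{Gamma}(shape + I/2, rate + \sum\nu_i^2/2)};
#' for the hierarchical family the bounds get Metropolis updates.
#'
#' Initialisation is deterministic: \eqn{\mu = \log(\sum C/\sum E)} (0 if
#' no cases), \eqn{\nu = 0}, \eqn{\sigma} at the midpoint of the prior
#' support clipped to \[0.01, 2\].
#'
#' @param table a [count_table()].
#' @param prior a [prior_spec()].
#' @param mcmc an [mcmc_config()].
#' @return An object of class `posterior_fit` with elements `mu`, `sigma`
#'   (vectors over kept draws, chains concatenated), `nu` and `lambda`
#'   (draws x areas matrices, `lambda[s,i] = exp(mu[s]+nu[s,i]) * E_i`),
#'   `lb`/`ub` draws for the hierarchical family, `chain` (chain index per
#'   draw), `prior`, `data`, `diagnostics` (split-\eqn{\hat R} and
#'   effective sample size for `mu` and `sigma`, plus acceptance rates).
#' @export
fit_bayes <- function(table, prior, mcmc = mcmc_config()) {
  stopifnot(inherits(table, "count_table"), inherits(prior, "prior_spec"),
            inherits(mcmc, "mcmc_config"))
  I <- nrow(table)
  sumC <- sum(table$observed); sumE <- sum(table$expected)
  init_mu <- if (sumC > 0) log(sumC / sumE) else 0
  init_sigma <- switch(prior$family,
    uniform_sigma = min(max((prior$lb + min(prior$ub, 4)) / 2, 0.01), 2),
    hierarchical_uniform_sigma = 0.5,
    gamma_precision = 0.5)
  if (prior$family == "uniform_sigma")
    init_sigma <- min(max(init_sigma, prior$lb + 1e-3), prior$ub - 1e-3)
  ptype <- match(prior$family, c("uniform_sigma",
                                 "hierarchical_uniform_sigma",
                                 "gamma_precision")) - 1L
  ps <- mcmc$proposal_scales

  chains <- vector("list", mcmc$n_chains)
  for (k in seq_len(mcmc$n_chains)) {
    set.seed(derive_seed(mcmc$seed, paste0("chain", k)))
    chains[[k]] <- .sampler_cpp(
      table$observed, table$expected,
      ptype, prior$lb, prior$ub,
      prior$lb_hyper_max, prior$ub_hyper_max,
      prior$gamma_shape, prior$gamma_rate,
      mcmc$n_iter, mcmc$n_burnin, mcmc$thin,
      init_mu, init_sigma,
      ps[["mu"]], ps[["nu"]], ps[["sigma"]],
      mcmc$adapt)
  }

  mu <- unlist(lapply(chains, `[[`, "mu"), use.names = FALSE)
  sigma <- unlist(lapply(chains, `[[`, "sigma"), use.names = FALSE)
  nu <- do.call(rbind, lapply(chains, `[[`, "nu"))
  n_keep <- length(chains[[1]]$mu)
  chain_id <- rep(seq_len(mcmc$n_chains), each = n_keep)
  lambda <- exp(mu + nu) * rep(table$expected, each = length(mu))
  if (!all(is.finite(mu))) stop("sampler produced non-finite draws for mu")

  diag_mu <- rhat_ess(split(mu, chain_id))
  diag_sigma <- rhat_ess(split(sigma, chain_id))
  acc <- colMeans(do.call(rbind, lapply(chains, `[[`, "accept")))

  out <- list(
    mu = mu, sigma = sigma, nu = nu, lambda = lambda,
    lb = unlist(lapply(chains, `[[`, "lb"), use.names = FALSE),
    ub = unlist(lapply(chains, `[[`, "ub"), use.names = FALSE),
    chain = chain_id, prior = prior, data = table, config = mcmc,
    diagnostics = list(
      rhat = c(mu = diag_mu[["rhat"]], sigma = diag_sigma[["rhat"]]),
      ess = c(mu = diag_mu[["ess"]], sigma = diag_sigma[["ess"]]),
      accept = acc,
      converged = isTRUE(diag_mu[["rhat"]] < 1.1) &&
        isTRUE(diag_sigma[["rhat"]] < 1.1)))
  class(out) <- "posterior_fit"
  out
}

#' @exportS3Method base::print
print.posterior_fit <- function(x, ...) {
  cat("Poisson random-effects posterior fit (", x$prior$family, " prior)\n",
      sep = "")
  cat(sprintf("  %d kept draws over %d chain(s); %d areas\n",
              length(x$mu), x$config$n_chains, ncol(x$nu)))
  cat(sprintf("  posterior mean mu = %.4f, sigma = %.4f\n",
              mean(x$mu), mean(x$sigma)))
  cat(sprintf("  Rhat(mu) = %.3f, Rhat(sigma) = %.3f\n",
              x$diagnostics$rhat[["mu"]], x$diagnostics$rhat[["sigma"]]))
  invisible(x)
}

#' Equal-tail credible intervals for the expected case counts
#'
#' Per area, the point estimate is the posterior mean of
#' \eqn{\lambda_i = e^{\mu+\nu_i} E_i} (the expectation of the predicted
#' number of incident cases) and the bounds are the equal-tail
#' `(1-level)/2` and `1-(1-level)/2` empirical quantiles of the
#' \eqn{\lambda_i} draws (type-7 quantiles).
#'
#' @param fit a `posterior_fit` from [fit_bayes()], with at least 100 kept
#'   draws.
#' @param level interval level in (0, 1).
#' @param method label stored in the `method` column.
#' @return A data frame with columns `method`, `area`, `point`, `lower`,
#'   `upper`, `level`, one row per area in input order.
#' @export
lambda_intervals <- function(fit, level = 0.95, method = fit$prior$family) {
  stopifnot(inherits(fit, "posterior_fit"))
  if (!(is.numeric(level) && length(level) == 1L && level > 0 && level < 1))
    stop("level must be a single number in (0, 1)")
  if (length(fit$mu) < 100L)
    stop("need at least 100 kept draws for interval summaries")
  a <- (1 - level) / 2
  q <- apply(fit$lambda, 2L, stats::quantile, probs = c(a, 1 - a),
             names = FALSE)
  data.frame(method = method, area = fit$data$area,
             point = colMeans(fit$lambda),
             lower = q[1L, ], upper = q[2L, ], level = level,
             stringsAsFactors = FALSE)
}

#' Split-chain convergence diagnostics
#'
#' Computes the split potential scale reduction factor \eqn{\hat R} and a
#' (combined-chain) effective sample size.  Each chain is split in half;
#' \eqn{\hat R = \sqrt{(W(n-1)/n + B/n) / W}} with the usual between/
#' within mean squares over the split chains.  ESS uses the pooled
#' autocorrelation with Geyer's initial-positive-sequence truncation.
#' Chains with zero total variance return \eqn{\hat R = 1} by convention.
#'
#' @param chains list of numeric vectors (one per chain), each with at
#'   least 10 draws.  A single chain yields `rhat = NA` and ESS only.
#' @return Named numeric vector `c(rhat = ..., ess = ...)`.
#' @export
rhat_ess <- function(chains) {
  if (is.numeric(chains)) chains <- list(chains)
  stopifnot(length(chains) >= 1L, all(vapply(chains, length, 1L) >= 10L))
  n0 <- min(vapply(chains, length, 1L))
  n0 <- n0 - (n0 %% 2L)
  halves <- list()
  for (ch in chains) {
    ch <- ch[seq_len(n0)]
    halves <- c(halves, list(ch[seq_len(n0 / 2)], ch[(n0 / 2 + 1):n0]))
  }
  m <- length(halves); n <- n0 / 2
  means <- vapply(halves, mean, 0); vars <- vapply(halves, stats::var, 0)
  W <- mean(vars); B <- n * stats::var(means)
  rhat <- if (length(chains) < 2L) {
    NA_real_
  } else if (W == 0 && B == 0) {
    1  # all-constant chains: no variance anywhere
  } else if (W == 0) {
    Inf
  } else {
    sqrt(((n - 1) / n * W + B / n) / W)
  }

  # ESS: average autocorrelation across chains, Geyer truncation
  pooled_var <- stats::var(unlist(chains, use.names = FALSE))
  if (pooled_var == 0) return(c(rhat = rhat, ess = sum(lengths(chains))))
  nmax <- min(vapply(chains, length, 1L))
  max_lag <- min(nmax - 1L, 1000L)
  acov <- sapply(chains, function(ch) {
    ch <- ch[seq_len(nmax)] - mean(ch[seq_len(nmax)])
    vapply(0:max_lag, function(l)
      sum(ch[seq_len(nmax - l)] * ch[(1 + l):nmax]) / nmax, 0)
  })
  acov <- rowMeans(as.matrix(acov))
  rho <- acov / acov[1L]
  # sum consecutive pairs until the pair sum goes non-positive
  s <- 0; l <- 2L
  while (l + 1L <= length(rho)) {
    pair <- rho[l] + rho[l + 1L]
    if (pair <= 0) break
    s <- s + pair
    l <- l + 2L
  }
  ess <- sum(lengths(chains)) / (1 + 2 * s)
  c(rhat = rhat, ess = min(ess, sum(lengths(chains))))
}
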