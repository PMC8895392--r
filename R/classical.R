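#' Exact (Garwood) Poisson confidence interval
#'
#' Classical exact interval for a Poisson mean given a single observed
#' count, from chi-square tail quantiles:
#' lower \eqn{= \chi^2_{\alpha/2, 2x}/2} (0 when \eqn{x = 0}) and upper
#' \eqn{= \chi^2_{1-\alpha/2, 2x+2}/2}, with \eqn{\alpha = 1 -} `level`.
#' Equivalently gamma quantiles with shapes \eqn{x} and \eqn{x+1}.  These
#' intervals are guaranteed conservative: coverage at least the nominal
#' level for every true mean.
#'
#' @param x non-negative integer count (vectorised).
#' @param level confidence level in (0, 1).
#' @return A two-column matrix `cbind(lower, upper)` on the count scale.
#' @export
exact_poisson_interval <- function(x, level = 0.95) {
  if (any(x < 0)) stop("counts must be non-negative")
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
  a <- 1 - level
  lower <- ifelse(x == 0, 0, stats::qgamma(a / 2, shape = x))
  upper <- stats::qgamma(1 - a / 2, shape = x + 1)
  cbind(lower = lower, upper = upper)
}

#' Byar's approximate Poisson confidence interval
#'
#' Closed-form cubic approximation to the exact interval; with \eqn{z}
#' the standard-normal quantile at \eqn{1-\alpha/2}:
#' \deqn{lower = x\,(1 - 1/(9x) - z/(3\sqrt x))^3, \quad
#'       upper = (x+1)(1 - 1/(9(x+1)) + z/(3\sqrt{x+1}))^3,}
#' with the lower bound defined as 0 at \eqn{x = 0} (the formula is
#' undefined there).  Accurate to well under 1% relative error for
#' moderate and large counts.
#'
#' @inheritParams exact_poisson_interval
#' @return A two-column matrix `cbind(lower, upper)` on the count scale.
#' @export
byars_interval <- function(x, level = 0.95) {
  if (any(x < 0)) stop("counts must be non-negative")
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
  z <- stats::qnorm(1 - (1 - level) / 2)
  xl <- pmax(x, 1)  # placeholder to keep the vectorised formula finite
  lower <- ifelse(x == 0, 0,
                  xl * (1 - 1 / (9 * xl) - z / (3 * sqrt(xl)))^3)
  xu <- x + 1
  upper <- xu * (1 - 1 / (9 * xu) + z / (3 * sqrt(xu)))^3
  cbind(lower = pmax(lower, 0), upper = upper)
}

#' Fit the empirical-Bayes gamma--Poisson model
#'
#' Assumes area relative risks \eqn{R_i \sim \mathrm{Gamma}(\alpha,
#' \beta)} (rate parameterisation) so that marginally \eqn{C_i \sim
#' \mathrm{NegBin}(size = \alpha, prob = \beta/(\beta+E_i))}.  Maximises
#' the marginal log-likelihood over \eqn{(\log\alpha, \log\beta)} by
#' quasi-Newton, started at method-of-moments values.
#'
#' Near-homogeneous data drive \eqn{\alpha \to \infty} (the gamma prior
#' degenerates to a point mass at \eqn{\alpha/\beta}); the optimum is then
#' at the search boundary and the fit is flagged.
#'
#' @param table a [count_table()] with at least 2 areas and at least one
#'   case in total.
#' @return List with `alpha`, `beta`, `loglik`, `boundary` (TRUE when the
#'   optimum hit the internal bound on \eqn{\log\alpha}), `convergence`.
#' @export
fit_eb_gamma <- function(table) {
  stopifnot(inherits(table, "count_table"))
  C <- table$observed; E <- table$expected
  if (sum(C) < 1L)
    stop("all counts are zero: the marginal likelihood is degenerate")
  # method-of-moments start: R_i ratios have mean a/b, var a/b^2 (plus
  # Poisson noise); crude but only a starting point
  r <- C / E
  m <- max(mean(r), 1e-3)
  v <- max(stats::var(r) - mean(1 / E) * m, 1e-6)
  a0 <- max(min(m^2 / v, 1e3), 1e-3); b0 <- a0 / m
  negll <- function(p) {
    a <- exp(p[1L]); b <- exp(p[2L])
    -sum(stats::dnbinom(C, size = a, prob = b / (b + E), log = TRUE))
  }
  ub <- log(1e6)
  opt <- stats::optim(c(log(a0), log(b0)), negll, method = "L-BFGS-B",
                      lower = c(-ub, -ub), upper = c(ub, ub),
                      control = list(factr = 1e3, maxit = 500L))
  alpha <- exp(opt$par[1L]); beta <- exp(opt$par[2L])
  list(alpha = alpha, beta = beta, loglik = -opt$value,
       boundary = opt$par[1L] > ub - 1e-3,
       convergence = opt$convergence)
}

#' Empirical-Bayes interval for one area
#'
#' By gamma--Poisson conjugacy the posterior of \eqn{R_i} is
#' \eqn{\mathrm{Gamma}(\alpha + x, \beta + e)}; the interval for
#' \eqn{\lambda_i = R_i e} is \eqn{e} times the equal-tail gamma
#' quantiles, and the point estimate is \eqn{e(\alpha+x)/(\beta+e)}.
#'
#' @param fit result of [fit_eb_gamma()].
#' @param x observed count(s).
#' @param e expected count(s), same length as `x`.
#' @param level interval level in (0, 1).
#' @return Data frame with `point`, `lower`, `upper` on the
#'   expected-cases scale.
#' @export
eb_interval <- function(fit, x, e, level = 0.95) {
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
  a <- fit$alpha + x; b <- fit$beta + e
  al <- (1 - level) / 2
  data.frame(point = e * a / b,
             lower = e * stats::qgamma(al, shape = a, rate = b),
             upper = e * stats::qgamma(1 - al, shape = a, rate = b))
}

#' Maximum-likelihood GLMM fit (Poisson log-link random intercept)
#'
#' Fits \eqn{C_i \sim \mathrm{Poisson}(e^{\mu + \nu_i} E_i)} with
#' \eqn{\nu_i \sim N(0, \sigma^2)} by Laplace-approximated maximum
#' likelihood (via \pkg{lme4}).  Per-area intervals use the conditional
#' mode \eqn{\hat\nu_i} and its conditional SD given the ML
#' \eqn{(\hat\mu, \hat\sigma)}:
#' \eqn{\exp(\hat\mu + \hat\nu_i \pm z\, sd_i)\,E_i}.  Hyperparameter
#' uncertainty is deliberately ignored, which is why these intervals
#' undercover for sparse counts.
#'
#' @param table a [count_table()] with >= 2 areas.
#' @return List with `mu_hat`, `sigma_hat`, `nu_modes`, `nu_sd`,
#'   `converged`, and the underlying `fit` object.
#' @export
fit_glmm_ml <- function(table) {
  stopifnot(inherits(table, "count_table"))
  df <- data.frame(y = table$observed, off = log(table$expected),
                   area = factor(table$area, levels = table$area))
  fit <- suppressWarnings(suppressMessages(
    lme4::glmer(y ~ 1 + (1 | area) + offset(off), data = df,
                family = stats::poisson(),
                control = lme4::glmerControl(
                  check.response.not.const = "ignore"))))
  re <- lme4::ranef(fit, condVar = TRUE)$area
  pv <- attr(re, "postVar")
  nu_sd <- sqrt(pmax(as.numeric(pv[1L, 1L, ]), 0))
  conv <- length(fit@optinfo$conv$lme4) == 0L &&
    isTRUE(fit@optinfo$conv$opt == 0L)
  list(mu_hat = unname(lme4::fixef(fit)[1L]),
       sigma_hat = sqrt(unname(lme4::VarCorr(fit)$area[1L, 1L])),
       nu_modes = re[table$area, 1L],
       nu_sd = nu_sd,
       converged = conv,
       fit = fit)
}

#' GLMM per-area intervals for the expected case counts
#'
#' @param fit result of [fit_glmm_ml()].
#' @param table the [count_table()] the model was fitted to.
#' @param level interval level.
#' @return Data frame with `method`, `area`, `point`, `lower`, `upper`,
#'   `level`.
#' @export
glmm_intervals <- function(fit, table, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  eta <- fit$mu_hat + fit$nu_modes
  data.frame(method = "glmm",
             area = table$area,
             point = exp(eta) * table$expected,
             lower = exp(eta - z * fit$nu_sd) * table$expected,
             upper = exp(eta + z * fit$nu_sd) * table$expected,
             level = level, stringsAsFactors = FALSE)
}
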