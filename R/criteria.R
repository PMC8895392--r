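#' Poisson deviance of a count table at given means
#'
#' The saturated-model-free deviance convention used throughout:
#' \eqn{-2 \sum_i \log \mathrm{Pois}(C_i; \lambda_i)}, including the
#' \eqn{\log C_i!} normalising term so that values are comparable across
#' models fitted to the same data (only differences between models are
#' meaningful).
#'
#' @param table a [count_table()].
#' @param lambda positive per-area means, length `nrow(table)`.
#' @return A single numeric deviance.
#' @export
poisson_deviance <- function(table, lambda) {
  stopifnot(inherits(table, "count_table"))
  if (length(lambda) != nrow(table)) stop("lambda must have one mean per area")
  if (any(!is.finite(lambda)) || any(lambda <= 0))
    stop("lambda must be positive and finite")
  -2 * sum(stats::dpois(table$observed, lambda, log = TRUE))
}

#' Deviance information criterion from posterior draws
#'
#' \eqn{\bar D} is the posterior mean of the deviance over draws;
#' \eqn{D(\bar\lambda)} plugs in the per-area posterior-mean
#' \eqn{\lambda_i}; the effective number of parameters is
#' \eqn{p_D = \bar D - D(\bar\lambda)} and
#' \eqn{\mathrm{DIC} = \bar D + p_D}.
#'
#' @param fit a `posterior_fit` with at least 100 kept draws (or any list
#'   carrying `lambda` draws and `data`).
#' @return List with `dbar`, `d_at_mean`, `pd`, `dic`.
#' @export
compute_dic <- function(fit) {
  lam <- fit$lambda; table <- fit$data
  if (nrow(lam) < 1L) stop("need at least one draw")
  C <- table$observed
  # deviance per draw, vectorised: -2 sum_i log dpois(C_i, lam[s,i])
  logpmf <- stats::dpois(rep(C, each = nrow(lam)), lam, log = TRUE)
  dim(logpmf) <- dim(lam)
  dev <- -2 * rowSums(logpmf)
  dbar <- mean(dev)
  d_at_mean <- poisson_deviance(table, colMeans(lam))
  pd <- dbar - d_at_mean
  list(dbar = dbar, d_at_mean = d_at_mean, pd = pd, dic = dbar + pd)
}

#' Watanabe-Akaike information criterion (both penalties)
#'
#' Per area \eqn{i} with draws \eqn{\lambda_i^s}:
#' \eqn{\mathrm{lppd}_i = \log \frac1S \sum_s p(C_i\mid\lambda_i^s)};
#' penalty 1 is twice the Jensen gap
#' \eqn{p_{1,i} = 2(\mathrm{lppd}_i - \frac1S\sum_s \log
#' p(C_i\mid\lambda_i^s))}; penalty 2 is the sample variance (denominator
#' \eqn{S-1}) of the log predictive density over draws.  Totals are sums
#' over areas and \eqn{\mathrm{WAIC}_k = -2(\mathrm{lppd} - p_k)}.
#'
#' @param fit a `posterior_fit` (or list with `lambda` draws and `data`);
#'   at least 2 draws are required for the variance penalty.
#' @return List with `lppd`, `p_waic1`, `p_waic2`, `waic1`, `waic2`.
#' @export
compute_waic <- function(fit) {
  lam <- fit$lambda; table <- fit$data
  S <- nrow(lam)
  if (S < 2L) stop("need at least 2 draws for the WAIC variance penalty")
  C <- table$observed
  logpmf <- stats::dpois(rep(C, each = S), lam, log = TRUE)
  dim(logpmf) <- dim(lam)
  # log mean exp per area, stabilised
  mx <- apply(logpmf, 2L, max)
  lppd_i <- mx + log(colMeans(exp(sweep(logpmf, 2L, mx))))
  mean_log <- colMeans(logpmf)
  p1_i <- 2 * (lppd_i - mean_log)
  p2_i <- apply(logpmf, 2L, stats::var)
  lppd <- sum(lppd_i); p1 <- sum(p1_i); p2 <- sum(p2_i)
  list(lppd = lppd, p_waic1 = p1, p_waic2 = p2,
       waic1 = -2 * (lppd - p1), waic2 = -2 * (lppd - p2))
}

#' All model criteria for a posterior fit
#'
#' Convenience wrapper combining [compute_dic()] and [compute_waic()].
#'
#' @param fit a `posterior_fit`.
#' @return A one-row data frame with columns `dbar`, `d_at_mean`, `pd`,
#'   `dic`, `lppd`, `p_waic1`, `p_waic2`, `waic1`, `waic2`.
#' @export
model_criteria <- function(fit) {
  d <- compute_dic(fit); w <- compute_waic(fit)
  data.frame(dbar = d$dbar, d_at_mean = d$d_at_mean, pd = d$pd, dic = d$dic,
             lppd = w$lppd, p_waic1 = w$p_waic1, p_waic2 = w$p_waic2,
             waic1 = w$waic1, waic2 = w$waic2)
}
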