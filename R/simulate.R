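#' Registry-like scenario presets
#'
#' Four presets emulate the observed-count summaries of the registry
#' entities used as simulation templates: two large-count cancers (CNS
#' tumours, ovarian adenocarcinoma) and two near-zero-count cancers
#' (middle-ear and tracheal adenocarcinoma).  Each preset fixes the
#' count-summary envelope (range and median over 27 areas) that the
#' generated expected counts must reproduce, together with a default
#' heterogeneity.  The intercept defaults to 0: only the product
#' \eqn{R_i E_i} is constrained by the published count summaries, so the
#' expected counts carry the scale.
#'
#' @param name one of `"cns"`, `"ovary"`, `"middle_ear"`, `"trachea"`.
#' @return A list with `n_areas`, `min_count`, `max_count`,
#'   `target_median`, `mu0`, `sigma0`.
#' @export
scenario_preset <- function(name = c("cns", "ovary", "middle_ear", "trachea")) {
  name <- match.arg(name)
  presets <- list(
    cns        = list(min_count = 174, max_count = 28732,
                      target_median = 2758, sigma0 = 0.2),
    ovary      = list(min_count = 96, max_count = 23957,
                      target_median = 3446, sigma0 = 0.2),
    middle_ear = list(min_count = 0, max_count = 17,
                      target_median = 1.8, sigma0 = 0.5),
    trachea    = list(min_count = 0, max_count = 39,
                      target_median = 6, sigma0 = 0.5))
  p <- presets[[name]]
  c(list(name = name, n_areas = 27L, mu0 = 0), p)
}

#' Generate per-area expected counts matching a count-summary envelope
#'
#' Produces `n_areas` positive expected counts, log-spaced between
#' `max(min_count, 0.5)` and `max_count`, rescaled multiplicatively so
#' their median matches `target_median` (values pushed past `max_count`
#' are capped there), then randomly shuffled.  A zero lower bound is
#' lifted to a 0.5-case floor so that Poisson means stay defined.
#'
#' @param n_areas number of areas \eqn{I}.
#' @param min_count,max_count range of the count envelope.
#' @param target_median required median (matched within 5%).
#' @param seed integer seed for the shuffle.
#' @return Numeric vector of length `n_areas`, all positive, median equal
#'   to `target_median` (up to the rescaling of interior points).
#' @export
make_expected_counts <- function(n_areas, min_count, max_count,
                                 target_median, seed = 1L) {
  if (!(min_count >= 0 && min_count <= target_median &&
        target_median <= max_count))
    stop("need 0 <= min_count <= target_median <= max_count")
  lo <- max(min_count, 0.5)
  if (max_count < lo) stop("max_count below the 0.5-case floor")
  e <- exp(seq(log(lo), log(max_count), length.out = n_areas))
  # multiplicative rescale so the sample median hits the target, then cap
  # at the envelope maximum (the published count range bounds what the
  # largest areas may produce)
  med <- stats::median(e)
  if (target_median > 0 && med > 0)
    e <- pmin(e * target_median / med, max_count)
  set.seed(derive_seed(seed, "expected_counts"))
  e <- sample(e)
  med <- stats::median(e)
  if (target_median > 0 && abs(med / target_median - 1) > 0.05)
    stop("could not match target median within 5%")
  e
}

#' Simulate replicate data sets from the generative model
#'
#' For each replicate \eqn{j}: draws \eqn{\nu_i^j \sim N(0, \sigma_0^2)},
#' computes \eqn{R_i^j = e^{\mu_0 + \nu_i^j}} and \eqn{\lambda_i^j =
#' R_i^j E_i}, and draws counts \eqn{C_i^j \sim
#' \mathrm{Poisson}(\lambda_i^j)}.  The truth is re-drawn per replicate,
#' so each replicate has its own target \eqn{\lambda_i^j} for coverage
#' evaluation.
#'
#' @param mu0 true intercept.
#' @param sigma0 true random-effect SD (>= 0; 0 means no heterogeneity).
#' @param expected per-area expected counts \eqn{E_i}.
#' @param n_reps number of replicates \eqn{J}.
#' @param seed integer seed.
#' @return A list of length `n_reps`; each element has `replicate`,
#'   `table` (a [count_table()]), and `truth` (list with `mu0`, `sigma0`,
#'   `expected`, `nu`, `R`, `lambda`).
#' @export
simulate_replicates <- function(mu0, sigma0, expected, n_reps, seed = 1L) {
  if (sigma0 < 0) stop("sigma0 must be >= 0")
  if (n_reps < 1L) stop("need at least one replicate")
  I <- length(expected)
  set.seed(derive_seed(seed, "replicates"))
  lapply(seq_len(n_reps), function(j) {
    nu <- stats::rnorm(I, 0, sigma0)
    R <- exp(mu0 + nu)
    lambda <- R * expected
    counts <- stats::rpois(I, lambda)
    list(replicate = j,
         table = count_table(sprintf("area%02d", seq_len(I)), counts,
                             expected,
                             entity_id = sprintf("replicate%04d", j)),
         truth = list(mu0 = mu0, sigma0 = sigma0, expected = expected,
                      nu = nu, R = R, lambda = lambda))
  })
}

#' Estimate generating truth from an observed count table
#'
#' Fits the random-effects model with a \eqn{\sigma \sim
#' \mathrm{Uniform}(0, 500)} prior and returns the posterior means of
#' \eqn{\mu} and \eqn{\sigma}, for use as the ground truth
#' \eqn{(\mu_0, \sigma_0)} of a simulation scenario anchored to real
#' data.
#'
#' @param table a [count_table()].
#' @param prior a [prior_spec()]; defaults to Uniform(0, 500) on sigma.
#' @param mcmc an [mcmc_config()].
#' @return Named numeric vector `c(mu0 = ..., sigma0 = ...)`.
#' @export
fit_truth_from_counts <- function(table,
                                  prior = prior_spec("uniform_sigma",
                                                     lb = 0, ub = 500),
                                  mcmc = mcmc_config()) {
  fit <- fit_bayes(table, prior, mcmc)
  c(mu0 = mean(fit$mu), sigma0 = mean(fit$sigma))
}

#' Simulate a replicate battery for a named preset
#'
#' Convenience wrapper: builds the preset's expected counts with
#' [make_expected_counts()] and simulates `n_reps` replicates with the
#' preset's \eqn{(\mu_0, \sigma_0)}.
#'
#' @param preset preset name, see [scenario_preset()].
#' @param n_reps number of replicates.
#' @param seed integer seed.
#' @param sigma0 optional override of the preset heterogeneity.
#' @return As [simulate_replicates()], with the expected counts attached
#'   as attribute `"expected"`.
#' @export
simulate_preset <- function(preset, n_reps, seed = 1L, sigma0 = NULL) {
  p <- scenario_preset(preset)
  e <- make_expected_counts(p$n_areas, p$min_count, p$max_count,
                            p$target_median, seed = seed)
  if (is.null(sigma0)) sigma0 <- p$sigma0
  reps <- simulate_replicates(p$mu0, sigma0, e, n_reps, seed = seed)
  attr(reps, "expected") <- e
  attr(reps, "preset") <- p
  reps
}
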