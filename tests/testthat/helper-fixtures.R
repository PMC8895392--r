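# Shared fixtures: small deterministic tables and a fast MCMC config for
# tests that need a posterior but not a publication-grade one.

toy_table <- function(I = 5L, counts = NULL, expected = NULL) {
  if (is.null(counts)) counts <- c(3L, 0L, 7L, 2L, 1L)[seq_len(I)]
  if (is.null(expected)) expected <- c(2.5, 1.2, 6.0, 3.3, 0.8)[seq_len(I)]
  count_table(sprintf("a%02d", seq_len(I)), counts, expected,
              entity_id = "toy")
}

homogeneous_table <- function(I = 27L, n = 1000L) {
  count_table(sprintf("a%02d", seq_len(I)), rep(as.integer(n), I),
              rep(as.numeric(n), I), entity_id = "homog")
}

quick_mcmc <- function(seed = 1L, n_iter = 2000L, n_burnin = 1000L) {
  mcmc_config(n_chains = 2L, n_iter = n_iter, n_burnin = n_burnin,
              seed = seed)
}

# Minimal stand-in for a posterior_fit when only lambda draws matter
# (criteria and interval summaries are pure functions of draws + data).
fake_fit <- function(lambda, table, mu = NULL, sigma = NULL) {
  lambda <- as.matrix(lambda)
  structure(list(mu = mu %||% rep(0, nrow(lambda)),
                 sigma = sigma %||% rep(1, nrow(lambda)),
                 nu = matrix(0, nrow(lambda), ncol(lambda)),
                 lambda = lambda, data = table,
                 prior = prior_spec("uniform_sigma", 0, 500)),
            class = "posterior_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
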