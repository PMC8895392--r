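#' Score one interval against the true expected count
#'
#' @param lower,upper interval bounds (closed interval; a truth exactly on
#'   a bound counts as covered).
#' @param point point estimate.
#' @param truth_lambda true expected count \eqn{\lambda_i^j} for this area
#'   and replicate.
#' @return List with `covered` (0/1), `width`, `sq_error`.
#' @export
evaluate_interval <- function(lower, upper, point, truth_lambda) {
  list(covered = as.numeric(lower <= truth_lambda & truth_lambda <= upper),
       width = upper - lower,
       sq_error = (point - truth_lambda)^2)
}

# Interval table (method, area, point, lower, upper) for one replicate and
# one method tag.  Bayesian tags "m1".."m9" map to the numbered candidate
# priors; "exact"/"byar" are count-scale Poisson intervals centred on the
# observed count; "eb" and "glmm" refit per replicate.
method_intervals <- function(method, table, level, mcmc) {
  if (grepl("^m[1-9]$", method)) {
    prior <- model_prior(as.integer(sub("m", "", method)))
    fit <- fit_bayes(table, prior, mcmc)
    return(lambda_intervals(fit, level, method = method))
  }
  switch(method,
    exact = {
      ci <- exact_poisson_interval(table$observed, level)
      data.frame(method = method, area = table$area,
                 point = as.numeric(table$observed),
                 lower = ci[, "lower"], upper = ci[, "upper"],
                 level = level, stringsAsFactors = FALSE)
    },
    byar = {
      ci <- byars_interval(table$observed, level)
      data.frame(method = method, area = table$area,
                 point = as.numeric(table$observed),
                 lower = ci[, "lower"], upper = ci[, "upper"],
                 level = level, stringsAsFactors = FALSE)
    },
    eb = {
      ebf <- fit_eb_gamma(table)
      ci <- eb_interval(ebf, table$observed, table$expected, level)
      data.frame(method = method, area = table$area, point = ci$point,
                 lower = ci$lower, upper = ci$upper, level = level,
                 stringsAsFactors = FALSE)
    },
    glmm = {
      g <- fit_glmm_ml(table)
      glmm_intervals(g, table, level)
    },
    stop("unknown method: ", method))
}

#' Coverage/width/RMSE benchmark over simulated replicates
#'
#' For every replicate and method, computes 95% (or `level`) intervals for
#' all areas and scores them against that replicate's true
#' \eqn{\lambda_i^j}.  Aggregation follows the pooled convention:
#' coverage and width are means/SDs over all \eqn{I \times J} intervals
#' (coverage in percent, so its SD is the binary-indicator SD
#' \eqn{100\sqrt{p(1-p)}} up to the \eqn{n-1} denominator); RMSE is
#' computed per replicate as \eqn{\sqrt{\mathrm{mean}_i (\hat\lambda_i -
#' \lambda_i)^2}} and then averaged over replicates
#' (`rmse_aggregation = "per_interval"` instead averages
#' \eqn{\sqrt{(\hat\lambda-\lambda)^2} = |\hat\lambda-\lambda|} over all
#' intervals).
#'
#' @param replicates list of simulated replicates from
#'   [simulate_replicates()] / [simulate_preset()].
#' @param methods character vector of method tags: `"m1"`..`"m9"`,
#'   `"exact"`, `"byar"`, `"eb"`, `"glmm"`.
#' @param mcmc an [mcmc_config()] used for the Bayesian methods; its seed
#'   is re-derived per replicate.
#' @param level interval level.
#' @param rmse_aggregation `"per_replicate"` (default) or
#'   `"per_interval"`.
#' @return A data frame with one row per method: `coverage_mean`,
#'   `coverage_sd` (percent), `width_mean`, `width_sd`, `rmse_mean`,
#'   `rmse_sd` (cases), and `n_failed` replicates excluded for that
#'   method.
#' @export
run_benchmark <- function(replicates, methods,
                          mcmc = mcmc_config(n_iter = 5000L,
                                             n_burnin = 2500L),
                          level = 0.95,
                          rmse_aggregation = c("per_replicate",
                                               "per_interval")) {
  rmse_aggregation <- match.arg(rmse_aggregation)
  if (length(replicates) < 2L) stop("need at least 2 replicates")
  scored <- per_method_scores(replicates, methods, mcmc, level)
  out <- lapply(methods, function(m) {
    s <- scored[[m]]
    rmse <- if (rmse_aggregation == "per_replicate") {
      vapply(s$sq_by_rep, function(v) sqrt(mean(v)), 0)
    } else sqrt(unlist(s$sq_by_rep, use.names = FALSE))
    data.frame(method = m,
               coverage_mean = 100 * mean(s$covered),
               coverage_sd = 100 * stats::sd(s$covered),
               width_mean = mean(s$width),
               width_sd = stats::sd(s$width),
               rmse_mean = mean(rmse),
               rmse_sd = stats::sd(rmse),
               n_failed = s$n_failed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Pooled scores per method: binary coverage indicators and widths over all
# I x J intervals, squared errors grouped by replicate; failed fits are
# excluded for that method with a count.
per_method_scores <- function(replicates, methods, mcmc, level) {
  res <- stats::setNames(vector("list", length(methods)), methods)
  for (m in methods) {
    covered <- numeric(0); width <- numeric(0)
    sq_by_rep <- list(); n_failed <- 0L
    for (rep in replicates) {
      cfg <- mcmc
      cfg$seed <- derive_seed(mcmc$seed, paste0(m, "-rep", rep$replicate))
      iv <- tryCatch(method_intervals(m, rep$table, level, cfg),
                     error = function(e) NULL)
      if (is.null(iv)) { n_failed <- n_failed + 1L; next }
      sc <- evaluate_interval(iv$lower, iv$upper, iv$point,
                              rep$truth$lambda)
      covered <- c(covered, sc$covered)
      width <- c(width, sc$width)
      sq_by_rep[[length(sq_by_rep) + 1L]] <- sc$sq_error
    }
    if (!length(covered)) stop("method ", m, " failed on every replicate")
    res[[m]] <- list(covered = covered, width = width,
                     sq_by_rep = sq_by_rep, n_failed = n_failed)
  }
  res
}
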