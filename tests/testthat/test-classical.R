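test_that("exact Poisson bounds match their defining tail equations", {
  # brute oracle: the exact interval endpoints solve
  # P(X >= x | lower) = alpha/2 and P(X <= x | upper) = alpha/2
  for (x in 0:50) {
    ci <- exact_poisson_interval(x, 0.95)
    expect_lte(ppois(x, ci[, "upper"]), 0.025 + 1e-6)
    expect_gte(ppois(x, ci[, "upper"] * (1 - 1e-9)), 0.025 - 1e-6)
    if (x > 0) {
      expect_lte(ppois(x - 1, ci[, "lower"], lower.tail = FALSE),
                 0.025 + 1e-6)
      expect_gte(ppois(x - 1, ci[, "lower"] * (1 + 1e-9),
                       lower.tail = FALSE), 0.025 - 1e-6)
    } else {
      expect_identical(ci[[1, "lower"]], 0)
    }
  }
  ci0 <- exact_poisson_interval(0, 0.95)
  expect_equal(ci0[[1, "upper"]], -log(0.025), tolerance = 1e-10)
  ci10 <- exact_poisson_interval(10, 0.95)
  expect_equal(ci10[[1, "lower"]], 4.7954, tolerance = 1e-4)
  expect_equal(ci10[[1, "upper"]], 18.3904, tolerance = 1e-4)
  expect_equal(ci10[[1, "lower"]], qchisq(0.025, 20) / 2, tolerance = 1e-12)
  expect_equal(ci10[[1, "upper"]], qchisq(0.975, 22) / 2, tolerance = 1e-12)
  expect_error(exact_poisson_interval(-1), "non-negative")
  expect_error(exact_poisson_interval(3, 1.2), "level")
})

test_that("Byar's approximation tracks the exact interval", {
  b10 <- byars_interval(10, 0.95)
  z <- qnorm(0.975)
  expect_equal(b10[[1, "lower"]],
               10 * (1 - 1 / 90 - z / (3 * sqrt(10)))^3, tolerance = 1e-12)
  expect_equal(b10[[1, "upper"]],
               11 * (1 - 1 / 99 + z / (3 * sqrt(11)))^3, tolerance = 1e-12)
  expect_equal(b10[[1, "lower"]], 4.7875, tolerance = 1e-4)
  expect_equal(b10[[1, "upper"]], 18.3917, tolerance = 1e-4)
  expect_identical(byars_interval(0, 0.95)[[1, "lower"]], 0)

  # < 1% relative error from x = 30 up; < 0.1% by x = 1000
  for (x in c(30, 40, 60, 100, 300, 1000)) {
    ex <- exact_poisson_interval(x, 0.95); by <- byars_interval(x, 0.95)
    tol <- if (x >= 1000) 0.001 else 0.01
    expect_lt(abs(by[, "lower"] / ex[, "lower"] - 1), tol)
    expect_lt(abs(by[, "upper"] / ex[, "upper"] - 1), tol)
  }
  expect_error(byars_interval(-2), "non-negative")
})

test_that("empirical-Bayes posterior equals the conjugate closed form", {
  fit <- list(alpha = 1, beta = 1)
  iv <- eb_interval(fit, x = 0, e = 1, level = 0.95)
  # posterior Gamma(1, 2): exponential quantiles -log(1-p)/2
  expect_equal(iv$lower, -log(1 - 0.025) / 2, tolerance = 1e-10)
  expect_equal(iv$upper, -log(0.025) / 2, tolerance = 1e-10)
  expect_equal(iv$lower, 0.01266, tolerance = 1e-4)
  expect_equal(iv$upper, 1.84444, tolerance = 1e-4)
  expect_equal(iv$point, 0.5)
  # general conjugate identity against qgamma directly
  fit2 <- list(alpha = 3.7, beta = 2.2)
  iv2 <- eb_interval(fit2, x = 5, e = 4, level = 0.9)
  expect_equal(iv2$lower, 4 * qgamma(0.05, 8.7, rate = 6.2),
               tolerance = 1e-10)
  expect_equal(iv2$upper, 4 * qgamma(0.95, 8.7, rate = 6.2),
               tolerance = 1e-10)
  # shrinkage vanishes as the count dominates
  iv3 <- eb_interval(fit, x = 10000, e = 100, level = 0.95)
  expect_lt(abs(iv3$point / 10000 - 1), 0.02)
})

test_that("EB marginal-likelihood fit recovers a known gamma mixing law", {
  set.seed(51)
  alphas <- replicate(200, {
    R <- rgamma(27, 4, rate = 4)
    tab <- count_table(sprintf("a%02d", 1:27), rpois(27, R * 500),
                       rep(500, 27))
    fit_eb_gamma(tab)$alpha
  })
  expect_lt(abs(mean(alphas) / 4 - 1), 0.4)

  # homogeneous data push the mixing distribution to a point mass
  hom <- fit_eb_gamma(homogeneous_table(27, 200))
  expect_true(hom$boundary || hom$alpha > 1e3)
  expect_lt(abs(hom$alpha / hom$beta - 1), 0.05)

  zeros <- count_table(c("a", "b"), c(0L, 0L), c(1, 1))
  expect_error(fit_eb_gamma(zeros), "zero")
})

test_that("GLMM maximum likelihood matches the generating model", {
  hom <- fit_glmm_ml(homogeneous_table(27, 1000))
  expect_lt(abs(hom$mu_hat), 0.02)
  expect_lt(hom$sigma_hat, 0.05)

  rep1 <- simulate_replicates(0, 0.5, rep(3000, 27), 1, seed = 52)[[1]]
  g <- fit_glmm_ml(rep1$table)
  expect_lt(abs(g$sigma_hat - 0.5), 0.15)
  iv <- glmm_intervals(g, rep1$table)
  expect_true(all(iv$lower <= iv$point & iv$point <= iv$upper))
  expect_identical(iv$area, rep1$table$area)
})

test_that("interval widths are non-negative everywhere", {
  for (x in c(0, 1, 2, 5, 17, 400)) {
    expect_gte(diff(as.numeric(exact_poisson_interval(x))), 0)
    expect_gte(diff(as.numeric(byars_interval(x))), 0)
  }
  iv <- eb_interval(list(alpha = 0.5, beta = 0.1), 0:5, rep(2, 6))
  expect_true(all(iv$upper >= iv$lower))
})
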