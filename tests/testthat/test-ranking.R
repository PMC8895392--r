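test_that("indicator vectors are deterministic functions of the fits", {
  tab <- toy_table()
  lam <- matrix(rep(c(2, 1, 6, 3, 1), each = 150), 150, 5)
  f <- fake_fit(lam, tab, sigma = rep(0.4, 150))
  ind <- compute_indicators(list(ma = f, mb = f))
  expect_equal(ind$width, c(0, 0))          # constant draws: zero width
  expect_equal(ind$sigma, c(0.4, 0.4))
  expect_identical(ind[1, -1], ind[2, -1], ignore_attr = TRUE)
  tab2 <- toy_table(5L, counts = c(1L, 1L, 1L, 1L, 1L))
  f2 <- fake_fit(lam, tab2)
  expect_error(compute_indicators(list(a = f, b = f2)), "same count table")
})

test_that("difference-from-minimum leaves a zero per entity and indicator", {
  ind <- data.frame(entity = rep(c("e1", "e2"), each = 3),
                    model = rep(c("m1", "m2", "m3"), 2),
                    width = c(3, 5, 9, 2, 2, 4),
                    sigma = c(1, 1, 1, 0.5, 0.7, 0.2),
                    waic1 = c(10, 11, 12, 30, 29, 28),
                    waic2 = c(10, 11, 12, 30, 29, 28),
                    dic = c(7, 8, 9, 40, 41, 39))
  d <- diff_from_min(ind)
  expect_equal(d$width[1:3], c(0, 2, 6))
  for (ent in c("e1", "e2"))
    for (col in c("width", "sigma", "waic1", "waic2", "dic")) {
      v <- d[d$entity == ent, col]
      expect_equal(min(v), 0)
      expect_true(all(v >= 0))
    }
  # shift invariance: adding a constant per entity changes nothing
  ind2 <- ind; ind2$dic <- ind2$dic + 100
  expect_equal(diff_from_min(ind2)$dic, d$dic)
  # a single model yields all-zero differences
  one <- ind[ind$model == "m1", ]
  expect_true(all(diff_from_min(one)$width == 0))
})

test_that("rank averaging follows competition-free average-tie ranking", {
  ind <- data.frame(entity = "e1", model = c("m1", "m2", "m3"),
                    width = c(3, 5, 9), sigma = c(3, 3, 9),
                    waic1 = c(1, 2, 3), waic2 = c(1, 2, 3),
                    dic = c(3, 2, 1))
  r <- rank_models(ind)
  expect_equal(r$per_entity$rank_width, c(1, 2, 3))
  expect_equal(r$per_entity$rank_sigma, c(1.5, 1.5, 3))
  expect_equal(r$per_entity$rank_dic, c(3, 2, 1))
  expect_equal(r$per_entity$avg_rank,
               rowMeans(cbind(c(1, 2, 3), c(1.5, 1.5, 3), c(1, 2, 3),
                              c(1, 2, 3), c(3, 2, 1))))
  # restricted "overall" subset
  r3 <- rank_models(ind, c("dic", "waic1", "waic2"))
  expect_equal(r3$per_entity$avg_rank, c(5 / 3, 2, 7 / 3))
  expect_identical(r3$by_model$model[1], "m1")
  expect_error(rank_models(ind, character(0)), "at least one")
})

test_that("rank averaging is equivariant under model relabelling", {
  set.seed(81)
  ind <- data.frame(entity = rep(sprintf("e%d", 1:6), each = 4),
                    model = rep(c("m1", "m2", "m3", "m4"), 6),
                    width = runif(24), sigma = runif(24),
                    waic1 = runif(24), waic2 = runif(24), dic = runif(24))
  r <- rank_models(ind)
  relab <- c(m1 = "z9", m2 = "a0", m3 = "q5", m4 = "b2")
  ind2 <- ind; ind2$model <- unname(relab[ind$model])
  r2 <- rank_models(ind2)
  m <- match(unname(relab[r$by_model$model]), r2$by_model$model)
  expect_equal(r2$by_model$mean_avg_rank[m], r$by_model$mean_avg_rank)
})

test_that("incidence scenarios use cumulative quartile membership", {
  expect_identical(stratify_by_incidence(0.02), c("A", "B", "C"))
  expect_identical(stratify_by_incidence(0.119), c("B", "C"))
  expect_identical(stratify_by_incidence(0.3), "C")
  expect_identical(stratify_by_incidence(0.5), "D")
  expect_identical(stratify_by_incidence(5.97), "D")
  expect_identical(stratify_by_incidence(0), c("A", "B", "C"))
  expect_error(stratify_by_incidence(-0.1), "non-negative")
})

test_that("scenario summaries match a direct order-statistics oracle", {
  set.seed(82)
  n_ent <- 40L
  ind <- data.frame(entity = rep(sprintf("e%02d", 1:n_ent), each = 2),
                    model = rep(c("m1", "m6"), n_ent),
                    width = rexp(2 * n_ent), sigma = rexp(2 * n_ent),
                    waic1 = rnorm(2 * n_ent), waic2 = rnorm(2 * n_ent),
                    dic = rnorm(2 * n_ent))
  d <- diff_from_min(ind)
  d$ir <- rep(runif(n_ent, 0, 0.029), each = 2)
  s <- summarize_scenario(d, "A")
  v <- d$dic[d$model == "m6"]
  expect_equal(s$median[s$model == "m6" & s$indicator == "dic"],
               sort(v)[(n_ent + 1) / 2 - 0.5] * 0.5 +
                 sort(v)[(n_ent + 1) / 2 + 0.5] * 0.5)
  expect_equal(s$p2.5[s$model == "m1" & s$indicator == "width"],
               unname(quantile(d$width[d$model == "m1"], 0.025)))
  expect_identical(unique(s$n_entities), n_ent)
  # single entity: the summary is that entity's difference
  one <- d[d$entity == "e01", ]
  s1 <- summarize_scenario(one, "A")
  expect_equal(s1$median[s1$model == "m1" & s1$indicator == "dic"],
               one$dic[one$model == "m1"])
  expect_error(summarize_scenario(d, "D"), "no entities")
})
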