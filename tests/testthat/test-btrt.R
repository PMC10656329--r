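test_that("the fitting interface returns a coherent pruned model", {
  set.seed(71)
  cfg <- scenario_config(3, 4, 80, "high")
  sim <- simulate_preferences(cfg, seed = 6)
  m <- suppressWarnings(btrt(sim$pairs, sim$covariates, mode = "oso",
                             max_terminals = 3, folds = 5, c = 0.5, seed = 4))
  expect_s3_class(m, "btrt")
  expect_gte(m$size, 0)
  expect_lte(m$size, nrow(m$trunk$split_history))
  expect_equal(length(coef(m)), count_parameters(4, 4, m$size + 1))
  expect_equal(deviance(m), m$trunk$fits[[m$size + 1]]$deviance)
  expect_output(print(m), "regression trunk")
  expect_output(print(summary(m)), "Split sequence")
  # reproducibility: the same seed gives the same pruned size and profile
  m2 <- suppressWarnings(btrt(sim$pairs, sim$covariates, mode = "oso",
                              max_terminals = 3, folds = 5, c = 0.5, seed = 4))
  expect_identical(m$cv$profile, m2$cv$profile)
  expect_identical(m$size, m2$size)
})

test_that("predictions respect the reference object and pair antisymmetry", {
  set.seed(72)
  cfg <- scenario_config(2, 4, 60, "high")
  sim <- simulate_preferences(cfg, seed = 13)
  m <- suppressWarnings(btrt(sim$pairs, sim$covariates, max_terminals = 2,
                             folds = 5, seed = 2))
  L <- predict(m, type = "worth")
  expect_equal(dim(L), c(60L, 4L))
  expect_true(all(L[, "D"] == 0))  # reference object pinned at zero
  P <- predict(m, type = "pair")
  expect_equal(dim(P), c(60L, 6L))
  expect_true(all(P > 0 & P < 1))
  expect_equal(unname(P[, "A>D"]),
               unname(preference_probability(L[, "A"], L[, "D"])))
  # new judges are routed through the fitted thresholds
  nd <- data.frame(judge = c("n1", "n2"), x1 = c(-2, 2), x2 = c(0, 1),
                   x3 = 0, x4 = 0)
  expect_equal(dim(predict(m, nd)), c(2L, 4L))
})

test_that("model-based simulation round-trips through the fit", {
  set.seed(73)
  cfg <- scenario_config(1, 4, 50, "high")
  sim <- simulate_preferences(cfg, seed = 19)
  m <- suppressWarnings(btrt(sim$pairs, sim$covariates, max_terminals = 1,
                             prune = FALSE))
  out <- simulate(m, nsim = 2, seed = 5)
  expect_length(out, 2)
  expect_equal(nrow(out[[1]]), nrow(sim$pairs))
  for (j in unique(out[[1]]$judge)[1:10])
    expect_true(check_transitivity(out[[1]]$y[out[[1]]$judge == j], 4)$allowed)
  r <- residuals(m)
  expect_length(r, nrow(sim$pairs))
  expect_true(all(is.finite(r)))
})

test_that("rankings input is converted and kept for consensus summaries", {
  set.seed(74)
  rk <- random_rankings(40, 4)
  cov <- random_covariates(rk$judge, P = 2)
  m <- suppressWarnings(btrt(rk, cov, max_terminals = 2, folds = 5, seed = 8))
  expect_false(is.null(m$rankings))
  s <- summary(m)
  expect_false(is.null(s$consensus))
  expect_equal(sum(s$consensus$H), 40L)
})
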