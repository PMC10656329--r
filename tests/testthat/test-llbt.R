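test_that("preference probabilities follow the doubled worth-difference logit", {
  expect_equal(preference_probability(0.7, 0.7), 0.5)
  # worth gap 0.9 (strongest vs reference object, low effect, 4 objects)
  expect_equal(preference_probability(0.9, 0), exp(1.8) / (1 + exp(1.8)),
               tolerance = 1e-12)
  expect_equal(preference_probability(0.9, 0), 0.8581, tolerance = 1e-4)
  # antisymmetry, numerically stable at extreme gaps
  x <- c(-30, -2, 0, 0.3, 5, 40)
  expect_equal(preference_probability(x, 0) + preference_probability(0, x),
               rep(1, length(x)))
})

test_that("the cell deviance matches its closed form and is additive", {
  expect_equal(poisson_deviance(c(1, 0), c(1, 0)), 0)
  expect_equal(poisson_deviance(c(1, 0), c(0.5, 0.5)), 2 * log(2))
  y <- c(1, 0, 0, 1); m <- c(0.7, 0.3, 0.4, 0.6)
  expect_equal(poisson_deviance(y, m),
               poisson_deviance(y[1:2], m[1:2]) + poisson_deviance(y[3:4], m[3:4]))
})

test_that("two-object fit recovers the closed-form worth difference", {
  p <- as_pairs(data.frame(judge = letters[1:4], object_i = "A",
                           object_j = "B", y = c(1, 1, 1, 0)))
  f <- llbt_fit(build_design(p))
  expect_equal(unname(f$lambda["A"] - f$lambda["B"]), 0.5 * qlogis(3 / 4),
               tolerance = 1e-6)
  # saturating case: fitted probability equals the empirical win frequency
  expect_equal(unname(f$fitted[1]), 0.75, tolerance = 1e-6)
})

test_that("perfectly balanced preferences give zero worths", {
  # all 6 orderings of 3 objects, once each: every object wins half its duels
  r <- as_rankings(rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                         c(3, 1, 2), c(2, 3, 1), c(3, 2, 1)))
  f <- llbt_fit(build_design(pairs_from_rankings(r)))
  expect_equal(unname(f$lambda), c(0, 0, 0), tolerance = 1e-8)
})

test_that("profiled fit equals the explicit-nuisance Poisson fit", {
  set.seed(21)
  for (k in 1:3) {
    r <- random_rankings(5, 3)
    cov <- random_covariates(r$judge, P = 1)
    d <- build_design(pairs_from_rankings(r), cov)
    f <- llbt_fit(d)
    df <- as.data.frame(d)
    sc <- colnames(d$X)
    form <- reformulate(c("0", "factor(cell)", sprintf("`%s`", sc)), "y")
    of <- glm(form, family = poisson(), data = df)
    expect_equal(unname(tail(coef(of), length(sc))), unname(f$coefficients),
                 tolerance = 1e-6)
    # identical deviance, and identical deviance differences on nesting
    expect_equal(deviance(of), f$deviance, tolerance = 1e-6)
    d0 <- build_design(pairs_from_rankings(r))
    f0 <- llbt_fit(d0)
    of0 <- glm(reformulate(c("0", "factor(cell)",
                             sprintf("`%s`", colnames(d0$X))), "y"),
               family = poisson(), data = as.data.frame(d0))
    expect_equal(deviance(of0) - deviance(of), f0$deviance - f$deviance,
                 tolerance = 1e-6)
  }
})

test_that("dispersion is Pearson/df and scales the corrected SEs", {
  set.seed(22)
  r <- random_rankings(40, 4)
  f <- llbt_fit(build_design(pairs_from_rankings(r)))
  expect_equal(f$se_corrected, f$se * sqrt(f$dispersion))
  p <- f$fitted; y <- f$y
  expect_equal(f$dispersion,
               sum((y - p)^2 / (p * (1 - p))) / (length(y) - ncol(f$design$X)),
               tolerance = 1e-8)
})

test_that("dispersion is near 1 under a correctly specified model", {
  set.seed(23)
  phis <- vapply(1:5, function(k) {
    cfg <- null_scenario(4, 300)
    sim <- simulate_preferences(cfg, seed = 7000 + k)
    llbt_fit(build_design(sim$pairs))$dispersion
  }, numeric(1))
  expect_lt(abs(mean(phis) - 1), 0.1)
})

test_that("adding a structural column never increases the deviance", {
  set.seed(24)
  for (k in 1:3) {
    r <- random_rankings(15, 4)
    cov <- random_covariates(r$judge, P = 2)
    p <- pairs_from_rankings(r)
    f0 <- llbt_fit(build_design(p))
    f1 <- llbt_fit(build_design(p, cov[c("judge", "x1")]))
    f2 <- llbt_fit(build_design(p, cov))
    f3 <- llbt_fit(build_design(p, cov, regions = list(R2 = r$judge[1:7])))
    expect_true(f0$deviance >= f1$deviance - 1e-8)
    expect_true(f1$deviance >= f2$deviance - 1e-8)
    expect_true(f2$deviance >= f3$deviance - 1e-8)
  }
})
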