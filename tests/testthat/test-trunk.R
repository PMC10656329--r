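test_that("candidate thresholds are the distinct values minus the maximum", {
  x <- cbind(x1 = c(1, 2, 2, 3))
  cands <- split_candidates(x, min_bucket = 1)
  expect_equal(cands$value, c(1, 2))
  expect_equal(cands$n_left, c(1L, 3L))
  # constant covariate contributes nothing; min_bucket drops unbalanced cuts
  expect_equal(nrow(split_candidates(cbind(x1 = rep(2, 6)), 1)), 0L)
  expect_equal(nrow(split_candidates(cbind(x1 = c(1, 2, 2, 3)), 2)), 0L)
  expect_equal(split_candidates(cbind(x1 = c(1, 2, 2, 3, 3)), 2)$value, 2)
  # excluded covariates (one-split-only mode) are skipped
  x2 <- cbind(x1 = 1:6, x2 = c(1, 1, 2, 2, 3, 3))
  expect_false("x1" %in% split_candidates(x2, 1, exclude = "x1")$covariate)
  # a dichotomous 0/1 covariate has the single threshold 0
  expect_equal(split_candidates(cbind(z = rep(0:1, 5)), 2)$value, 0)
})

test_that("a duplicated covariate loses the tie to the lower index", {
  set.seed(41)
  cfg <- scenario_config(1, 4, 60, "high")
  sim <- simulate_preferences(cfg, seed = 88)
  cov <- sim$covariates[c("judge", "x1")]
  cov$x2 <- cov$x1
  tr <- suppressWarnings(grow_trunk(sim$pairs, cov, max_terminals = 2))
  expect_equal(tr$split_history$covariate, "x1")
})

test_that("nodes below twice the minimum bucket are not split", {
  set.seed(42)
  cfg <- scenario_config(1, 4, 9, "high")
  sim <- simulate_preferences(cfg, seed = 5)
  tr <- suppressWarnings(grow_trunk(sim$pairs, sim$covariates,
                                    max_terminals = 5, min_bucket = 5))
  expect_equal(nrow(tr$split_history), 0L)
  expect_equal(length(tr$fits), 1L)
})

test_that("one-split-only mode never reuses a split covariate", {
  set.seed(43)
  cfg <- scenario_config(2, 4, 80, "high")
  sim <- simulate_preferences(cfg, seed = 12)
  tr <- suppressWarnings(grow_trunk(sim$pairs, sim$covariates, mode = "oso",
                                    max_terminals = 5))
  expect_false(any(duplicated(tr$split_history$covariate)))
})

test_that("training deviance is nonincreasing along the trunk sequence", {
  set.seed(44)
  cfg <- scenario_config(3, 4, 70, "high")
  sim <- simulate_preferences(cfg, seed = 3)
  for (mode in c("oso", "ms")) {
    tr <- suppressWarnings(grow_trunk(sim$pairs, sim$covariates, mode = mode,
                                      max_terminals = 4))
    devs <- vapply(tr$fits, function(f) f$deviance, numeric(1))
    expect_true(all(diff(devs) <= 1e-8))
    # parameter counts follow the closed formula at every size
    for (s in seq_along(tr$fits))
      expect_equal(ncol(tr$fits[[s]]$design$X), count_parameters(4, 4, s))
  }
})

test_that("region indicators of a grown trunk are mutually exclusive", {
  set.seed(45)
  cfg <- scenario_config(2, 4, 80, "low")
  sim <- simulate_preferences(cfg, seed = 9)
  tr <- suppressWarnings(grow_trunk(sim$pairs, sim$covariates, mode = "ms",
                                    max_terminals = 4))
  ord <- terminals_at_size(tr)
  members <- lapply(ord, function(id) tr$nodes[[as.character(id)]]$judges)
  expect_equal(sort(unlist(members)), seq_along(tr$judges))
  expect_false(any(duplicated(unlist(members))))
  # every split respected the minimum bucket
  expect_true(all(lengths(members) >= tr$min_bucket))
})

test_that("terminal predicates are derived from the tree structure", {
  # the published MS survey trunk: grade average at 27.5, then age 25 in the
  # low-grade branch, ECTS 39 below that, grade 21 in its left child
  tr <- trunk_from_splits(data.frame(
    node = c(1, 2, 4, 8),
    covariate = c("grade", "age", "ects", "grade"),
    value = c(27.5, 25, 39, 21)))
  preds <- region_predicates(tr)
  cond <- function(p) paste(p$covariate, p$op, p$value, collapse = ", ")
  # reference region: the always-right path
  expect_equal(cond(preds$R1), "grade > 27.5")
  expect_equal(attr(preds, "node_ids"), c(3L, 16L, 17L, 9L, 5L))
  expect_equal(cond(preds$R2), "grade <= 27.5, age <= 25, ects <= 39, grade <= 21")
  # the structural R3 keeps the ECTS condition implied by its parent split
  expect_equal(cond(preds$R3), "grade <= 27.5, age <= 25, ects <= 39, grade > 21")
  expect_equal(cond(preds$R4), "grade <= 27.5, age <= 25, ects > 39")
  expect_equal(cond(preds$R5), "grade <= 27.5, age > 25")
  # splitting a non-terminal node is rejected
  expect_error(trunk_from_splits(data.frame(node = c(1, 1),
                                            covariate = "a", value = 1:2)),
               "not terminal")
})

test_that("the reference region follows the rightmost path after each split", {
  set.seed(46)
  cfg <- scenario_config(2, 4, 90, "high")
  sim <- simulate_preferences(cfg, seed = 21)
  tr <- suppressWarnings(grow_trunk(sim$pairs, sim$covariates, mode = "ms",
                                    max_terminals = 4))
  for (t in 0:nrow(tr$split_history)) {
    ord <- terminals_at_size(tr, t)
    ref <- ord[length(ord)]
    # the reference is reachable from the root by > branches only
    pred <- tr$nodes[[as.character(ref)]]$pred
    expect_true(all(pred$op == ">"))
    # the size-t fit carries exactly t region coefficient blocks
    fit <- tr$fits[[t + 1]]
    expect_equal(length(fit$design$region_names), max(0, t))
  }
})
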