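test_that("weak-order enumeration matches the ordered-partition counts", {
  expect_equal(nrow(weak_orders(3)), 13L)
  expect_equal(nrow(weak_orders(4)), 75L)
  expect_equal(nrow(weak_orders(5)), 541L)
  W <- weak_orders(4)
  expect_false(any(duplicated(apply(W, 1, paste, collapse = ""))))
  # rank values always form a contiguous 1..k set
  ok <- apply(W, 1, function(w) setequal(w, seq_len(max(w))))
  expect_true(all(ok))
})

test_that("tau-x behaves like a rank correlation with ties as agreement", {
  expect_equal(tau_x(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  expect_equal(tau_x(c(1, 2, 3, 4), c(4, 3, 2, 1)), -1)
  # hand evaluation of the score-matrix formula for r2 = (1, 1, 3)
  expect_equal(tau_x(c(1, 2, 3), c(1, 1, 3)), 2 / 3)
  set.seed(61)
  W <- weak_orders(4)
  for (k in 1:30) {
    r1 <- W[sample(nrow(W), 1), ]
    r2 <- W[sample(nrow(W), 1), ]
    expect_equal(tau_x(r1, r2), tau_x(r2, r1))
    expect_true(abs(tau_x(r1, r2)) <= 1)
  }
  expect_error(tau_x(1:3, 1:4), "same objects")
})

test_that("tau-x equals Kendall's tau on untied rankings", {
  set.seed(62)
  for (k in 1:20) {
    r1 <- sample(5); r2 <- sample(5)
    expect_equal(tau_x(r1, r2), cor(r1, r2, method = "kendall"))
  }
})

test_that("the median ranking attains the exhaustive-scan optimum", {
  m <- median_ranking(rbind(c(1, 2, 3), c(1, 2, 3), c(1, 3, 2)))
  expect_equal(unname(m$consensus), c(1, 2, 3))
  expect_equal(m$C, "123")
  ident <- median_ranking(rbind(c(2, 1, 3), c(2, 1, 3)))
  expect_equal(unname(ident$consensus), c(2, 1, 3))
  expect_equal(ident$tau_bar, 1)
  # independent scan: plain double loop over all weak orders
  set.seed(63)
  for (k in 1:3) {
    ranks <- t(vapply(1:6, function(h) sample(4), integer(4)))
    W <- weak_orders(4)
    sc <- vapply(seq_len(nrow(W)), function(w)
      mean(vapply(seq_len(nrow(ranks)), function(h)
        tau_x(W[w, ], ranks[h, ]), numeric(1))), numeric(1))
    m <- median_ranking(ranks)
    expect_equal(m$tau_bar, max(sc), tolerance = 1e-12)
    # two exactly opposite rankings: no consensus does better than 0
    opp <- median_ranking(rbind(1:4, 4:1))
    expect_lte(opp$tau_bar, 0 + 1e-12)
  }
})

test_that("per-node consensus summaries partition the judges", {
  set.seed(64)
  cfg <- scenario_config(2, 4, 60, "high")
  sim <- simulate_preferences(cfg, seed = 41)
  rk <- as_rankings(btrtrunk:::ranks_from_pairs(sim$pairs))
  tr <- suppressWarnings(grow_trunk(sim$pairs, sim$covariates,
                                    max_terminals = 3))
  cs <- consensus_by_node(tr, rk)
  expect_equal(sum(cs$H), 60L)
  expect_equal(cs$region[1], "R1")
  expect_true(all(cs$tau_bar >= -1 & cs$tau_bar <= 1))
  # a single member is its own consensus
  one <- median_ranking(rk$ranks[1, , drop = FALSE])
  expect_equal(unname(one$consensus), unname(rk$ranks[1, ]))
  expect_equal(one$tau_bar, 1)
})
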