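test_that("rankings expand to the pairwise preferences they imply", {
  r <- as_rankings(rbind(c(1, 2, 3), c(3, 2, 1)))
  p <- pairs_from_rankings(r)
  expect_equal(nrow(p), 6L)
  # judge 1 ranks A>B>C: every lower-indexed object wins
  expect_equal(p$y[p$judge == "1"], c(1L, 1L, 1L))
  # judge 2 is the full reversal
  expect_equal(p$y[p$judge == "2"], c(0L, 0L, 0L))
  expect_true(attr(p, "derived_from_rankings"))
})

test_that("a 100-judge, 5-object panel yields ten comparisons per judge", {
  set.seed(31)
  p <- pairs_from_rankings(random_rankings(100, 5))
  expect_equal(nrow(p), 1000L)
  expect_true(all(table(p$judge) == 10L))
})

test_that("invalid rankings are rejected naming the judge", {
  expect_error(as_rankings(data.frame(judge = c("a", "b"),
                                      A = c(1, 2), B = c(1, 1), C = c(3, 3))),
               "judge 'a'")
  expect_error(as_rankings(rbind(c(1, 2, 5))), "permutation")
  expect_error(as_rankings(rbind(c(1, 2))), "3 objects")
})

test_that("transitive patterns are exactly the permutation patterns", {
  # 4 objects: 2^6 = 64 binary patterns, 4! = 24 transitive, 40 cyclic
  pats <- as.matrix(expand.grid(rep(list(0:1), 6)))
  ok <- apply(pats, 1, function(y) check_transitivity(y, 4)$allowed)
  expect_equal(sum(ok), 24L)
  expect_equal(sum(!ok), 40L)
  expect_equal(check_transitivity(pats[1, ], 4)$n_allowed, 24L)
  # 3 objects: 8 patterns, 6 allowed; the two cycles are rejected
  pats3 <- as.matrix(expand.grid(rep(list(0:1), 3)))
  ok3 <- apply(pats3, 1, function(y) check_transitivity(y, 3)$allowed)
  expect_equal(sum(ok3), 6L)
  expect_false(check_transitivity(c(1, 0, 1), 3)$allowed)  # A>B, B>C, C>A
  expect_error(check_transitivity(c(1, 0), 3), "length")
})

test_that("projection returns the closest permutation pattern", {
  # transitive input comes back unchanged
  y <- c(1L, 1L, 1L)
  expect_identical(project_to_nearest_permutation(y, 3), y)
  # the 3-object cycle has exactly 3 permutation patterns at distance 1
  set.seed(42)
  cyc <- c(1, 0, 1)
  outs <- replicate(60, paste(project_to_nearest_permutation(cyc, 3),
                              collapse = ""))
  dists <- vapply(unique(outs), function(s) {
    v <- as.integer(strsplit(s, "")[[1]])
    expect_true(check_transitivity(v, 3)$allowed)
    sum(v != cyc)
  }, numeric(1))
  expect_true(all(dists == 1))
  expect_equal(length(unique(outs)), 3L)
})

test_that("projection always lands on a transitive pattern", {
  set.seed(7)
  for (n_o in 3:5) {
    np <- n_o * (n_o - 1) / 2
    for (k in 1:20) {
      y <- rbinom(np, 1, 0.5)
      out <- project_to_nearest_permutation(y, n_o)
      expect_true(check_transitivity(out, n_o)$allowed)
      if (check_transitivity(y, n_o)$allowed) expect_identical(out, as.integer(y))
    }
  }
})
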