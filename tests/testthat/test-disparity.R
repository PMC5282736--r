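test_that("sum of ranges and variances match hand computations", {
  expect_equal(sum_of_ranges(matrix(c(2, 5), 1)), 0)
  pts <- rbind(c(0, 0), c(1, 2), c(3, 1))
  expect_equal(sum_of_ranges(pts), 5)
  expect_equal(sum_of_ranges(pts[c(1, 1, 2, 2, 3, 3), ]), 5) # multiplicity-blind
  expect_equal(sum_of_variances(rbind(c(1, 1), c(1, 1))), 0)
  expect_equal(sum_of_variances(c(0, 2)), 2)
  expect_equal(sum_of_variances(-pts), sum_of_variances(pts))
  expect_error(sum_of_ranges(matrix(numeric(0), 0, 2)), "at least 1")
  expect_error(sum_of_variances(matrix(0, 1, 2)), "at least 2")
})

test_that("jackknife at full group size reproduces the observed value", {
  set.seed(2)
  fx <- two_group_ordination(matrix(rnorm(10), 5), matrix(rnorm(10), 5))
  res <- jackknife_disparity(fx$ord, fx$grouping, iterations = 50,
                             subsample_size = 5, seed = 1,
                             permutation_iterations = 0)
  for (g in colnames(res$replicates)) {
    expect_true(all(res$replicates[, g] == res$observed[[g]]))
  }
  expect_equal(nrow(res$replicates), 50L)
})

test_that("jackknife of a 3-taxon group at subsample 2 equals the leave-one-out set", {
  set.seed(3)
  pts <- matrix(rnorm(6), 3, 2)
  fx <- two_group_ordination(pts, matrix(rnorm(8), 4))
  # exhaustive oracle: all C(3,2) subset values
  loo <- apply(utils::combn(3, 2), 2, function(idx) sum_of_ranges(pts[idx, ]))
  res <- jackknife_disparity(fx$ord, fx$grouping, iterations = 200,
                             subsample_size = 2, seed = 4,
                             permutation_iterations = 0)
  reps <- res$replicates[, "A"]
  expect_true(all(vapply(reps, function(r) any(abs(r - loo) < 1e-12), logical(1))))
  expect_true(all(vapply(loo, function(l) any(abs(l - reps) < 1e-12), logical(1))))
})

test_that("rarefied ranges are biased downward, never above the observed value", {
  set.seed(6)
  for (rep in 1:5) {
    fx <- two_group_ordination(matrix(rnorm(24), 8), matrix(rnorm(18), 6))
    res <- jackknife_disparity(fx$ord, fx$grouping, iterations = 200,
                               subsample_size = 4, seed = rep,
                               permutation_iterations = 0)
    for (g in colnames(res$replicates)) {
      expect_true(all(res$replicates[, g] <= res$observed[[g]] + 1e-12))
      expect_lte(mean(res$replicates[, g]), res$observed[[g]])
    }
  }
})

test_that("jackknife runs are reproducible under a fixed seed and validate sizes", {
  set.seed(10)
  fx <- two_group_ordination(matrix(rnorm(12), 6), matrix(rnorm(8), 4))
  a <- jackknife_disparity(fx$ord, fx$grouping, iterations = 30, seed = 9)
  b <- jackknife_disparity(fx$ord, fx$grouping, iterations = 30, seed = 9)
  expect_identical(a$replicates, b$replicates)
  expect_identical(a$p_values, b$p_values)
  expect_equal(a$subsample_size, 4L)   # defaults to the smallest group
  expect_error(
    jackknife_disparity(fx$ord, fx$grouping, iterations = 5, subsample_size = 5),
    "B"
  )
})

test_that("permutation p is 1 for identical groups and exchangeable in labels", {
  pts <- matrix(rnorm(10), 5, 2)
  fx <- two_group_ordination(pts, pts)
  res <- permutation_test(fx$ord, fx$grouping, iterations = 99, seed = 1)
  expect_equal(res$p_values["A", "B"], 1)
  expect_equal(res$observed_diff["A", "B"], 0)

  # exchanging which group is called A and which B leaves p untouched,
  # including with unequal group sizes
  set.seed(20)
  coords <- matrix(rnorm(20), 10, 2)
  rownames(coords) <- paste0("t", 1:10)
  ord <- ordination_from_coords(coords)
  g1 <- taxon_grouping(setNames(rep(c("A", "B"), c(6, 4)), rownames(coords)))
  g2 <- taxon_grouping(setNames(rep(c("B", "A"), c(6, 4)), rownames(coords)))
  p1 <- permutation_test(ord, g1, iterations = 199, seed = 5)
  p2 <- permutation_test(ord, g2, iterations = 199, seed = 5)
  expect_equal(p1$p_values["A", "B"], p2$p_values["A", "B"])
  expect_gt(min(p1$p_values, na.rm = TRUE), 0)  # +1 correction
})

test_that("a planted 3x spread difference is detected", {
  set.seed(31)
  fx <- two_group_ordination(matrix(rnorm(40, sd = 3), 20),
                             matrix(rnorm(40, sd = 1), 20))
  res <- permutation_test(fx$ord, fx$grouping, iterations = 999, seed = 2)
  expect_lte(res$p_values["A", "B"], 0.05)
})

test_that("permutation p-values are approximately uniform under the null", {
  set.seed(77)
  pvals <- replicate(500, {
    fx <- two_group_ordination(matrix(rnorm(16), 8), matrix(rnorm(16), 8))
    lobomorph:::permutation_pair(fx$ord$coordinates[1:8, ],
                                 fx$ord$coordinates[9:16, ],
                                 sum_of_ranges, 99)$p
  })
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})
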