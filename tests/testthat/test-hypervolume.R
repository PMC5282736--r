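test_that("the hypervolume of a dense uniform square is close to 1", {
  set.seed(1)
  pts <- matrix(runif(2000), ncol = 2)
  hv <- estimate_hypervolume(pts, bandwidth = c(0.05, 0.05),
                             threshold_quantile = 0.05,
                             n_samples = 20000, seed = 2)
  expect_lt(abs(hv$volume - 1), 0.15)
  # consistency identity and interior points inside their own model
  expect_equal(hv$volume, nrow(hv$random_points) / hv$point_density)
  expect_true(all(inclusion_test(hv, hv$random_points)))
})

test_that("a 1D Gaussian hypervolume matches the analytic density contour", {
  set.seed(4)
  x <- matrix(rnorm(1000), ncol = 1)
  hv <- estimate_hypervolume(x, threshold_quantile = 0.05,
                             n_samples = 40000, seed = 5)
  # KDE of N(0,1) with bandwidth h is ~N(0, 1 + h^2); the region holding 95%
  # of its mass is the central 95% interval
  h <- hv$bandwidth
  expected <- 2 * qnorm(0.975) * sqrt(1 + h^2)
  expect_lt(abs(hv$volume - expected) / expected, 0.15)
})

test_that("volume grows with bandwidth and shrinks with the quantile", {
  v_by_h <- vapply(c(0.5, 1, 2), function(h) {
    estimate_hypervolume(matrix(0, 1, 1), bandwidth = h,
                         threshold_quantile = 0, n_samples = 5000,
                         seed = 3)$volume
  }, numeric(1))
  expect_true(all(diff(v_by_h) > 0))

  set.seed(6)
  pts <- matrix(rnorm(200), ncol = 2)
  v_by_q <- vapply(c(0.05, 0.2, 0.5), function(q) {
    estimate_hypervolume(pts, bandwidth = c(0.3, 0.3), threshold_quantile = q,
                         n_samples = 10000, seed = 7)$volume
  }, numeric(1))
  expect_true(all(diff(v_by_q) < 0))
})

test_that("disjoint clouds modelled jointly have additive volume", {
  set.seed(8)
  a <- matrix(rnorm(200), ncol = 2)
  b <- sweep(matrix(rnorm(200), ncol = 2), 2, c(100, 0), "+")
  args <- list(bandwidth = c(0.5, 0.5), threshold_quantile = 0.05,
               n_samples = 20000)
  joint <- do.call(estimate_hypervolume, c(list(rbind(a, b), seed = 1), args))
  va <- do.call(estimate_hypervolume, c(list(a, seed = 2), args))$volume
  vb <- do.call(estimate_hypervolume, c(list(b, seed = 3), args))$volume
  expect_lt(abs(joint$volume - (va + vb)) / (va + vb), 0.15)
})

test_that("inclusion follows the density threshold", {
  set.seed(9)
  pts <- matrix(rnorm(400), ncol = 2)
  hv <- estimate_hypervolume(pts, n_samples = 10000, seed = 10)
  expect_true(inclusion_test(hv, colMeans(pts)))
  expect_false(inclusion_test(hv, c(10 * max(abs(pts)), 0)))
  expect_error(inclusion_test(hv, c(0, 0, 0)), "dimension")
})

test_that("Sorensen overlap is ~1 on itself, ~0 on disjoint clouds, symmetric", {
  set.seed(12)
  pts <- matrix(rnorm(300), ncol = 2)
  A <- estimate_hypervolume(pts, n_samples = 10000, seed = 1)
  B <- estimate_hypervolume(pts, n_samples = 10000, seed = 2)
  self <- sorensen_overlap(A, B)
  expect_gte(self$sorensen, 0.9)
  expect_lte(self$sorensen, 1)

  far <- estimate_hypervolume(pts + 100, n_samples = 10000, seed = 3)
  expect_lte(sorensen_overlap(A, far)$sorensen, 0.05)
  expect_equal(sorensen_overlap(A, far)$sorensen,
               sorensen_overlap(far, A)$sorensen)
  expect_lte(self$intersection_volume, min(A$volume, B$volume))

  one_d <- estimate_hypervolume(matrix(rnorm(50), ncol = 1),
                                n_samples = 5000, seed = 4)
  expect_error(sorensen_overlap(A, one_d), "dimension mismatch")
})

test_that("degenerate inputs are rejected or warned about", {
  expect_error(estimate_hypervolume(matrix(0, 1, 2)), ">= 2 points")
  const <- matrix(c(0, 0, 0, 1, 2, 3), 3, 2) # first axis has zero variance
  expect_error(estimate_hypervolume(const), "zero-variance")
  expect_error(estimate_hypervolume(matrix(rnorm(10), 5), bandwidth = -1),
               "positive")
  expect_warning(
    estimate_hypervolume(matrix(rnorm(20), 10, 2), bandwidth = c(1, 1),
                         n_samples = 50, seed = 1),
    "noisy"
  )
})

test_that("centroids and centroid distances follow plane geometry", {
  coords <- rbind(a1 = c(1, 1), a2 = c(-1, -1), b1 = c(3, 4), b2 = c(3, 4))
  fx <- ordination_from_coords(coords)
  g <- taxon_grouping(c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  cent <- group_centroids(fx, g)
  expect_equal(unname(cent["A", ]), c(0, 0))   # symmetric pair at the origin
  expect_equal(unname(cent["B", ]), c(3, 4))
  cd <- centroid_distances(cent)
  expect_equal(cd["A", "B"], 5)                # 3-4-5 triangle
  expect_equal(diag(cd), c(A = 0, B = 0))
  expect_error(centroid_distances(cent["A", , drop = FALSE]), ">= 2")
})

test_that("per-group fitting skips groups too small for a stable KDE", {
  set.seed(14)
  coords <- matrix(rnorm(36), 9, 4)
  rownames(coords) <- paste0("t", 1:9)
  fx <- ordination_from_coords(coords)
  g <- taxon_grouping(setNames(rep(c("big", "tiny"), c(6, 3)), rownames(coords)))
  hv <- group_hypervolumes(fx, g, n_samples = 2000, seed = 1)
  expect_named(hv$models, "big")
  expect_equal(hv$skipped, c(tiny = 3L))  # below d + 1 = 5 in 4D
})
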