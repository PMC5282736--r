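test_that("deduplicate merges identical taxa and averages their distances", {
  v <- matrix(c(0, 0, 0.2,
                0, 0, 0.4,
                0.2, 0.4, 0), 3, byrow = TRUE,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  D <- lobomorph:::new_dissimilarity_matrix(v)
  dd <- deduplicate(D, tolerance = 0)
  expect_equal(rownames(dd$D$values), c("x", "z"))
  expect_equal(dd$D$values["x", "z"], 0.3)       # mean of 0.2 and 0.4
  expect_equal(dd$merges, list(x = c("x", "y")))

  # identity when nothing is within tolerance; idempotent afterwards
  again <- deduplicate(dd$D, tolerance = 0)
  expect_identical(again$D$values, dd$D$values)
  expect_equal(length(again$merges), 0L)

  all_same <- lobomorph:::new_dissimilarity_matrix(
    matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3])))
  collapsed <- deduplicate(all_same)
  expect_equal(nrow(collapsed$D$values), 1L)
  expect_error(neighbour_joining(collapsed$D), ">= 3 taxa")
})

test_that("three-taxon NJ solves the three-point equations", {
  v <- matrix(c(0, 2, 3,
                2, 0, 3,
                3, 3, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbour_joining(lobomorph:::new_dissimilarity_matrix(v))
  lens <- setNames(tr$edge.length[match(seq_along(tr$tip.label),
                                        tr$edge[, 2])], tr$tip.label)
  expect_equal(lens, c(A = 1, B = 1, C = 2))
})

test_that("NJ recovers additive trees exactly (topology and path lengths)", {
  set.seed(21)
  for (rep in 1:10) {
    oracle <- random_additive_distances(sample(5:10, 1))
    tr <- neighbour_joining(oracle$D)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(oracle$tree), tr)), 0)
    got <- ape::cophenetic.phylo(tr)[rownames(oracle$D), colnames(oracle$D)]
    expect_equal(max(abs(got - oracle$D)), 0, tolerance = 1e-8)
    expect_equal(attr(tr, "negative_clamped"), 0L)
  }
})

test_that("NJ output does not depend on input taxon order", {
  set.seed(22)
  m <- random_binary_matrix(8, 30)
  D <- pairwise_dissimilarity(m)
  tr1 <- neighbour_joining(D)
  perm <- sample(nrow(D$values))
  D2 <- lobomorph:::new_dissimilarity_matrix(D$values[perm, perm])
  tr2 <- neighbour_joining(D2)
  expect_equal(as.numeric(ape::dist.topo(tr1, tr2)), 0)
  co1 <- ape::cophenetic.phylo(tr1)
  co2 <- ape::cophenetic.phylo(tr2)[rownames(co1), colnames(co1)]
  expect_equal(co1, co2, tolerance = 1e-10)
})

test_that("negative NJ branch estimates are clamped to zero", {
  # strongly non-additive distances force a negative estimate
  v <- matrix(c(0, 0.404, 0.594, 0.242,
                0.404, 0, 0.913, 0.903,
                0.594, 0.913, 0, 0.947,
                0.242, 0.903, 0.947, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  raw <- ape::nj(as.dist(v))
  expect_true(any(raw$edge.length < 0))   # the case actually exercises the clamp
  tr <- neighbour_joining(lobomorph:::new_dissimilarity_matrix(v))
  expect_true(all(tr$edge.length >= 0))
  expect_gte(attr(tr, "negative_clamped"), 1L)
})

test_that("phenograms round-trip through Newick", {
  set.seed(23)
  oracle <- random_additive_distances(7)
  tr <- neighbour_joining(oracle$D)
  f <- tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- read_newick(f)
  expect_equal(as.numeric(ape::dist.topo(tr, back)), 0)
  expect_equal(sort(ape::cophenetic.phylo(back)[lower.tri(diag(7))]),
               sort(ape::cophenetic.phylo(tr)[lower.tri(diag(7))]),
               tolerance = 1e-6)
})

test_that("k-means assessment finds two planted blobs with a high silhouette", {
  set.seed(24)
  blobs <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40) + 10, 20))
  km <- kmeans_assessment(blobs, k_range = 2:5, seed = 1)
  expect_equal(km$best_k, 2L)
  expect_gt(max(km$table$score), 0.7)
  expect_true(km$strong_structure)

  # doubling every point must not change the silhouette ranking
  km2 <- kmeans_assessment(rbind(blobs, blobs), k_range = 2:5, seed = 1)
  expect_equal(km2$best_k, 2L)
})

test_that("a single Gaussian blob is flagged as weak structure", {
  set.seed(25)
  blob <- matrix(rnorm(160), 40, 4)   # as many axes as a typical morphospace
  km <- kmeans_assessment(blob, k_range = 2:5, seed = 2)
  expect_lt(max(km$table$score), 0.4)
  expect_false(km$strong_structure)
  expect_error(kmeans_assessment(blob, k_range = 2:40), "k_range")
})

test_that("the gap statistic criterion is available and seeded", {
  set.seed(26)
  blobs <- rbind(matrix(rnorm(30), 15), matrix(rnorm(30) + 8, 15))
  km <- kmeans_assessment(blobs, k_range = 2:4, criterion = "gap",
                          restarts = 10, seed = 3)
  expect_equal(km$best_k, 2L)
  expect_true(is.na(km$strong_structure))
})
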