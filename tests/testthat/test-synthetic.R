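test_that("generated matrices match the requested shape and truth record", {
  spec <- synthetic_spec(n_groups = 3, taxa_per_group = c(4, 5, 6),
                         n_characters = 25, states_per_character = 3,
                         missing_rate = 0.1, inapplicable_rate = 0.08,
                         n_outlier_taxa = 2)
  sim <- generate_matrix(spec, seed = 1)
  expect_equal(n_taxa(sim$matrix), 4 + 5 + 6 + 2)
  expect_equal(n_characters(sim$matrix), 25L)
  expect_setequal(sim$grouping$groups_of_interest, c("g1", "g2", "g3"))
  expect_equal(sim$truth$outlier_taxa, c("outlier_1", "outlier_2"))
  expect_equal(as.integer(table(sim$grouping$assignment)[c("g1", "g2", "g3")]),
               c(4L, 5L, 6L))
  # inapplicable cells form one contiguous block per core taxon
  block <- unname(which(sim$matrix$cells["g1_1", ] == "-"))
  expect_equal(block, seq(min(block), max(block)))
  expect_length(block, round(0.08 * 25))
})

test_that("generation is reproducible under a fixed seed", {
  spec <- synthetic_spec(n_groups = 2, taxa_per_group = 5, n_characters = 30)
  a <- generate_matrix(spec, seed = 11)
  b <- generate_matrix(spec, seed = 11)
  c <- generate_matrix(spec, seed = 12)
  expect_identical(a$matrix$cells, b$matrix$cells)
  expect_false(identical(a$matrix$cells, c$matrix$cells))
  expect_error(synthetic_spec(states_per_character = 1), ">= 2")
  expect_error(synthetic_spec(missing_rate = 1.2), "\\[0, 1\\]")
})

test_that("zero divergence yields exchangeable groups (calibrated p-values)", {
  set.seed(33)
  rejections <- 0L
  n_rep <- 30
  for (r in seq_len(n_rep)) {
    sim <- generate_matrix(
      synthetic_spec(n_groups = 2, taxa_per_group = 8, n_characters = 30,
                     divergence = 0, missing_rate = 0),
      seed = 1000 + r
    )
    D <- pairwise_dissimilarity(sim$matrix)
    ord <- suppressWarnings(pcoa_ordination(D))
    p <- permutation_test(ord, sim$grouping, iterations = 99,
                          axes = 2)$p_values[1, 2]
    rejections <- rejections + (p <= 0.05)
  }
  # true type-I error 0.05: seeing more than 20% rejections would be extreme
  expect_lte(rejections / n_rep, 0.2)
})

test_that("strongly divergent groups occupy quasi non-overlapping morphospace", {
  set.seed(34)
  low_overlap <- 0L
  n_seed <- 8
  for (r in seq_len(n_seed)) {
    sim <- generate_matrix(
      synthetic_spec(n_groups = 3, taxa_per_group = 8, n_characters = 40,
                     divergence = 0.8, missing_rate = 0),
      seed = 2000 + r
    )
    D <- pairwise_dissimilarity(sim$matrix)
    ord <- suppressWarnings(pcoa_ordination(D))
    hv <- group_hypervolumes(ord, sim$grouping, axes = 3,
                             n_samples = 4000, seed = r)
    ov <- overlap_table(hv$models)
    low_overlap <- low_overlap + all(ov$sorensen < 0.1)
  }
  expect_gte(low_overlap / n_seed, 0.75)
})

test_that("point clouds carry exact planted centroid geometry", {
  sim <- generate_point_clouds(3, n_points = 10, dimension = 4,
                               centroid_separation = 5, spread = 1, seed = 41)
  cd <- sim$truth$centroid_distances
  expect_equal(unname(cd[upper.tri(cd)]), rep(5, 3))
  expect_equal(nrow(sim$coordinates), 30L)

  same <- generate_point_clouds(2, 50, 2, centroid_separation = 0, seed = 42)
  expect_true(all(same$truth$centroids == 0))
  A <- estimate_hypervolume(same$coordinates[1:50, ], n_samples = 8000, seed = 1)
  B <- estimate_hypervolume(same$coordinates[51:100, ], n_samples = 8000, seed = 2)
  expect_gt(sorensen_overlap(A, B)$sorensen, 0.5)

  expect_error(generate_point_clouds(5, 10, 3, centroid_separation = 2),
               "simplex")
})

test_that("estimated centroid distances recover planted separations", {
  set.seed(43)
  for (r in 1:5) {
    sim <- generate_point_clouds(2, n_points = 20, dimension = 4,
                                 centroid_separation = 5, spread = 1,
                                 seed = 300 + r)
    ord <- pcoa_ordination(as.matrix(dist(sim$coordinates)))
    cent <- group_centroids(ord, sim$grouping,
                            axes = ncol(ord$coordinates))
    est <- centroid_distances(cent)["g1", "g2"]
    se <- sqrt(2) * 1 / sqrt(20)
    expect_lt(abs(est - 5), 3 * se)
  }
})

test_that("the study-shaped stand-in has the published dataset's dimensions", {
  sim <- synthetic_study_matrix(seed = 5)
  expect_equal(n_taxa(sim$matrix), 19L)
  expect_equal(n_characters(sim$matrix), 39L)
  expect_setequal(sim$grouping$groups_of_interest, c("H", "L", "O"))
  expect_setequal(sim$truth$query_taxa,
                  c("Microdictyon", "Onychodictyon_gracilis",
                    "Onychodictyon_ferox"))
  sizes <- table(sim$grouping$assignment)
  expect_equal(as.integer(sizes[c("H", "L", "O")]), c(6L, 5L, 5L))
})

test_that("synthetic bundles write the formats the pipeline reads", {
  sim <- generate_matrix(synthetic_spec(n_groups = 2, taxa_per_group = 4,
                                        n_characters = 12), seed = 9)
  dir <- tempfile()
  paths <- write_synthetic(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read_matrix(paths["matrix"])
  expect_identical(back$cells, sim$matrix$cells)
  g <- read_groups(paths["groups"], groups_of_interest = c("g1", "g2"))
  expect_identical(g$assignment[names(sim$grouping$assignment)],
                   sim$grouping$assignment)
  truth <- jsonlite::read_json(paths["truth"])
  expect_named(truth$modal, c("g1", "g2"))
})
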