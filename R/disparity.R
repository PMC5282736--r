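#' Disparity metrics on ordination coordinates
#'
#' `sum_of_ranges()` is the sum over axes of the coordinate range
#' (max minus min) of a group's points — a measure of the extent of
#' morphospace a group spans, sensitive to sample size. `sum_of_variances()`
#' sums the per-axis sample variances (`n - 1` denominator) — a measure of
#' dispersion around the group mean, far less size-sensitive.
#'
#' @param points numeric matrix of group coordinates (taxa in rows, axes in
#'   columns); a vector is treated as a one-axis matrix.
#' @return single non-negative number.
#' @examples
#' pts <- rbind(c(0, 0), c(1, 2), c(3, 1))
#' sum_of_ranges(pts)    # 5
#' sum_of_variances(pts)
#' @export
sum_of_ranges <- function(points) {
  points <- as_points(points)
  if (nrow(points) < 1L) stop("sum_of_ranges needs at least 1 point")
  sum(apply(points, 2, function(v) diff(range(v))))
}

#' @rdname sum_of_ranges
#' @export
sum_of_variances <- function(points) {
  points <- as_points(points)
  if (nrow(points) < 2L) stop("sum_of_variances needs at least 2 points")
  sum(apply(points, 2, stats::var))
}

as_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 1)
  storage.mode(points) <- "double"
  points
}

disparity_metric <- function(metric = c("ranges", "variances")) {
  metric <- match.arg(metric)
  switch(metric, ranges = sum_of_ranges, variances = sum_of_variances)
}

# group coordinate matrices on the retained (or requested) axes
group_points <- function(ord, grouping, axes = NULL) {
  check_grouping_against(grouping, rownames(ord$coordinates))
  co <- ord_coordinates(ord, axes)
  lapply(stats::setNames(nm = grouping$groups_of_interest), function(g) {
    co[group_members(grouping, g), , drop = FALSE]
  })
}

#' Jackknifed (rarefied) group disparity
#'
#' For each group of interest, repeatedly subsamples `subsample_size` taxa
#' without replacement and evaluates the disparity metric on the retained
#' ordination axes. Rarefying all groups to a common subsample size removes
#' the sample-size bias of range-based metrics, making groups of different
#' sizes comparable; the replicate distributions are what violin plots of
#' jackknifed disparity display.
#'
#' @param ord an `ordination` (see [pcoa_ordination()]).
#' @param grouping a [taxon_grouping()]; only `groups_of_interest` are used.
#' @param metric `"ranges"` (default) or `"variances"`.
#' @param iterations number of jackknife replicates per group.
#' @param subsample_size taxa drawn per replicate; `NULL` (default) uses the
#'   smallest group-of-interest size so all groups are rarefied alike.
#' @param axes number of ordination axes; `NULL` uses the Broken-Stick
#'   retained count.
#' @param seed optional integer seed; recorded in the result.
#' @param permutation_iterations iterations for the accompanying pairwise
#'   permutation tests; `0` skips them.
#' @return an object of class `disparity_result`: observed values, replicate
#'   matrix (`iterations` rows, one column per group), a summary table
#'   (observed, jackknife mean and 2.5/50/97.5 percent quantiles), pairwise
#'   permutation p-values (when requested), and the settings used.
#' @export
jackknife_disparity <- function(ord, grouping, metric = c("ranges", "variances"),
                                iterations = 5000, subsample_size = NULL,
                                axes = NULL, seed = NULL,
                                permutation_iterations = iterations) {
  metric <- match.arg(metric)
  if (iterations < 1) stop("`iterations` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  fn <- disparity_metric(metric)
  pts <- group_points(ord, grouping, axes)
  sizes <- vapply(pts, nrow, integer(1))
  if (is.null(subsample_size)) subsample_size <- min(sizes)
  if (subsample_size < 2) stop("`subsample_size` must be >= 2")
  too_small <- names(sizes)[sizes < subsample_size]
  if (length(too_small)) {
    stop("subsample_size ", subsample_size, " exceeds the size of group(s): ",
         paste(too_small, collapse = ", "))
  }

  observed <- vapply(pts, fn, numeric(1))
  replicates <- vapply(pts, function(p) {
    n <- nrow(p)
    vapply(seq_len(iterations), function(i) {
      fn(p[sample.int(n, subsample_size), , drop = FALSE])
    }, numeric(1))
  }, numeric(iterations))
  replicates <- matrix(replicates, nrow = iterations,
                       dimnames = list(NULL, names(pts)))

  qs <- apply(replicates, 2, stats::quantile, probs = c(0.025, 0.5, 0.975))
  summary <- data.frame(
    group = names(pts),
    n = sizes,
    observed = unname(observed),
    jackknife_mean = colMeans(replicates),
    q025 = qs[1, ], median = qs[2, ], q975 = qs[3, ],
    row.names = NULL
  )

  p_values <- NULL
  if (permutation_iterations > 0 && length(pts) > 1) {
    p_values <- permutation_test(ord, grouping, metric = metric,
                                 iterations = permutation_iterations,
                                 axes = axes)$p_values
  }

  structure(
    list(metric = metric, observed = observed, replicates = replicates,
         summary = summary, p_values = p_values,
         iterations = iterations, subsample_size = subsample_size,
         seed = seed),
    class = "disparity_result"
  )
}

#' @export
print.disparity_result <- function(x, ...) {
  cat(sprintf("Jackknifed sum of %s: %d iterations, subsample size %d\n",
              x$metric, x$iterations, x$subsample_size))
  print(x$summary, digits = 4)
  if (!is.null(x$p_values)) {
    cat("Pairwise permutation p-values:\n")
    print(round(x$p_values, 4))
  }
  invisible(x)
}

#' Permutation test for a disparity difference between groups
#'
#' For each pair of groups of interest, the observed statistic is the
#' absolute difference in the disparity metric. The null distribution is
#' built by pooling the two groups' taxa and randomly re-partitioning them
#' into the original group sizes; the p-value uses the add-one correction
#' `p = (count of null >= observed + 1) / (iterations + 1)`, so it is never
#' exactly zero.
#'
#' @inheritParams jackknife_disparity
#' @param iterations number of random re-partitions per pair.
#' @return list with `p_values` and `observed_diff` (symmetric matrices over
#'   the groups of interest, diagonal `NA`), plus `metric`, `iterations` and
#'   `seed`.
#' @export
permutation_test <- function(ord, grouping, metric = c("ranges", "variances"),
                             iterations = 5000, axes = NULL, seed = NULL) {
  metric <- match.arg(metric)
  if (iterations < 1) stop("`iterations` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  fn <- disparity_metric(metric)
  pts <- group_points(ord, grouping, axes)
  small <- names(pts)[vapply(pts, nrow, integer(1)) < 2]
  if (length(small)) {
    stop("permutation test needs >=2 members per group; too small: ",
         paste(small, collapse = ", "))
  }
  groups <- names(pts)
  k <- length(groups)
  if (k < 2) stop("permutation test needs at least two groups of interest")
  p_values <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  observed_diff <- p_values
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      res <- permutation_pair(pts[[a]], pts[[b]], fn, iterations)
      p_values[a, b] <- p_values[b, a] <- res$p
      observed_diff[a, b] <- observed_diff[b, a] <- res$observed
    }
  }
  list(p_values = p_values, observed_diff = observed_diff,
       metric = metric, iterations = iterations, seed = seed)
}

permutation_pair <- function(pa, pb, fn, iterations) {
  observed <- abs(fn(pa) - fn(pb))
  pooled <- rbind(pa, pb)
  # canonicalise so the p-value is exactly invariant under exchanging the
  # group labels: fixed row order, and always draw the smaller subset
  if (!is.null(rownames(pooled)) && !anyDuplicated(rownames(pooled))) {
    pooled <- pooled[order(rownames(pooled)), , drop = FALSE]
  }
  k <- min(nrow(pa), nrow(pb))
  n <- nrow(pooled)
  null <- vapply(seq_len(iterations), function(i) {
    idx <- sample.int(n, k)
    abs(fn(pooled[idx, , drop = FALSE]) - fn(pooled[-idx, , drop = FALSE]))
  }, numeric(1))
  list(p = (sum(null >= observed) + 1) / (iterations + 1), observed = observed)
}

#' Export disparity tables
#'
#' Writes the per-group summary (and optionally the long-format replicate
#' table) of a [jackknife_disparity()] result as CSV.
#'
#' @param x a `disparity_result`.
#' @param path output file for the summary table.
#' @param replicates_path optional output file for the long-format replicate
#'   table (`group, iteration, value`).
#' @export
write_disparity <- function(x, path, replicates_path = NULL) {
  df <- x$summary
  df[, -(1:2)] <- signif(df[, -(1:2)], 6)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(replicates_path)) {
    long <- data.frame(
      group = rep(colnames(x$replicates), each = nrow(x$replicates)),
      iteration = rep(seq_len(nrow(x$replicates)), ncol(x$replicates)),
      value = signif(as.vector(x$replicates), 6)
    )
    utils::write.csv(long, replicates_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
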