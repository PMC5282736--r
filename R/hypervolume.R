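#' Kernel-density hypervolume of a point cloud
#'
#' Models the region of ordination space a group occupies as the set of
#' points where a Gaussian product-kernel density estimate of the group's
#' coordinates exceeds a quantile threshold, and estimates that region's
#' volume.
#'
#' The density threshold is the `threshold_quantile` quantile of the kernel
#' density evaluated at `n_samples` Monte-Carlo draws from the kernel mixture
#' itself, so the retained region captures `1 - threshold_quantile` of the
#' mixture's probability mass. The volume of the region `{x : f(x) >= t}` is
#' estimated by importance sampling: `V = E_f[ 1{f(X) >= t} / f(X) ]`,
#' averaged over the same mixture draws. Uniformly distributed interior
#' points are obtained by resampling the retained draws with weights
#' `1 / f(x)`; they drive the Sorensen-Dice overlap estimate and satisfy the
#' model's own inclusion test by construction.
#'
#' @param points numeric matrix (observations in rows, axes in columns); a
#'   vector is treated as one-dimensional data.
#' @param bandwidth `NULL` for Silverman's multivariate rule per axis
#'   (`sd_j * (4 / ((d + 2) n))^(1 / (d + 4))`), or a positive value per axis
#'   (recycled).
#' @param threshold_quantile proportion of the kernel mixture's probability
#'   mass left outside the hypervolume (default `0.05`).
#' @param n_samples Monte-Carlo draws from the kernel mixture.
#' @param n_random_points uniform interior points to retain in the model.
#' @param seed optional integer seed.
#' @return an object of class `hypervolume_model`: `dimension`,
#'   `data_points`, `bandwidth`, `threshold_quantile`, `threshold_density`,
#'   `volume`, `random_points`, `point_density`
#'   (`nrow(random_points) / volume`), `n_samples`, `seed`.
#' @examples
#' set.seed(1)
#' pts <- matrix(runif(400), ncol = 2)
#' hv <- estimate_hypervolume(pts, bandwidth = c(0.05, 0.05), n_samples = 5000)
#' hv$volume # close to 1: the unit square
#' @export
estimate_hypervolume <- function(points, bandwidth = NULL,
                                 threshold_quantile = 0.05,
                                 n_samples = 10000, n_random_points = 1000,
                                 seed = NULL) {
  points <- as_points(points)
  n <- nrow(points)
  d <- ncol(points)
  if (d < 1L) stop("hypervolume needs dimension >= 1")
  if (threshold_quantile < 0 || threshold_quantile >= 1) {
    stop("`threshold_quantile` must be in [0, 1)")
  }
  if (is.null(bandwidth)) {
    if (n < 2L) stop("need >= 2 points for automatic bandwidth")
    bandwidth <- silverman_bandwidth(points)
  } else {
    bandwidth <- rep_len(as.numeric(bandwidth), d)
    if (n < 1L) stop("need >= 1 point with explicit bandwidth")
  }
  if (any(!is.finite(bandwidth)) || any(bandwidth <= 0)) {
    stop("bandwidths must be positive and finite; a zero-variance axis ",
         "needs an explicit bandwidth")
  }
  if (n_samples < 100 * d) {
    warning("n_samples < 100 * dimension; volume estimate will be noisy")
  }
  if (!is.null(seed)) set.seed(seed)

  samples <- sample_kernel_mixture(points, bandwidth, n_samples)
  dens <- kde_gauss_eval(samples, points, bandwidth)
  threshold <- unname(stats::quantile(dens, threshold_quantile))
  keep <- dens >= threshold
  volume <- mean(keep / dens)

  kept_idx <- which(keep)
  m <- min(n_random_points, length(kept_idx))
  ridx <- sample(kept_idx, m, replace = TRUE, prob = 1 / dens[kept_idx])
  random_points <- samples[ridx, , drop = FALSE]

  structure(
    list(dimension = d, data_points = points, bandwidth = bandwidth,
         threshold_quantile = threshold_quantile,
         threshold_density = threshold, volume = volume,
         random_points = random_points,
         point_density = nrow(random_points) / volume,
         n_samples = n_samples, seed = seed),
    class = "hypervolume_model"
  )
}

silverman_bandwidth <- function(points) {
  n <- nrow(points)
  d <- ncol(points)
  sds <- apply(points, 2, stats::sd)
  sds * (4 / ((d + 2) * n))^(1 / (d + 4))
}

sample_kernel_mixture <- function(points, bandwidth, n_samples) {
  d <- ncol(points)
  comp <- sample.int(nrow(points), n_samples, replace = TRUE)
  noise <- matrix(stats::rnorm(n_samples * d), n_samples, d)
  points[comp, , drop = FALSE] + sweep(noise, 2, bandwidth, "*")
}

#' @export
print.hypervolume_model <- function(x, ...) {
  cat(sprintf("KDE hypervolume: %d points in %dD, volume %.4g\n",
              nrow(x$data_points), x$dimension, x$volume))
  cat(sprintf("  bandwidth: %s; threshold quantile %.3g; %d interior points\n",
              paste(signif(x$bandwidth, 3), collapse = ", "),
              x$threshold_quantile, nrow(x$random_points)))
  invisible(x)
}

#' Point inclusion in a hypervolume
#'
#' A query point lies inside the hypervolume when the model's kernel density
#' at that point reaches the model's density threshold.
#'
#' @param model a `hypervolume_model`.
#' @param query numeric matrix of query points (rows), or a single point as a
#'   vector; must match the model's dimension.
#' @return logical vector, one entry per query point (named after the query
#'   row names, when present).
#' @export
inclusion_test <- function(model, query) {
  stopifnot(inherits(model, "hypervolume_model"))
  if (is.null(dim(query))) {
    if (length(query) != model$dimension) {
      stop(sprintf("query dimension %d does not match model dimension %d",
                   length(query), model$dimension))
    }
    query <- matrix(query, 1)
  }
  query <- as_points(query)
  if (ncol(query) != model$dimension) {
    stop(sprintf("query dimension %d does not match model dimension %d",
                 ncol(query), model$dimension))
  }
  dens <- kde_gauss_eval(query, model$data_points, model$bandwidth)
  stats::setNames(dens >= model$threshold_density, rownames(query))
}

#' Sorensen-Dice overlap between two hypervolumes
#'
#' The intersection volume is estimated by cross-inclusion: the fraction of
#' each model's uniform interior points falling inside the other model gives
#' an estimate of `V(A intersect B)`, and the two estimates are averaged.
#' The Sorensen-Dice index is `2 V(A^B) / (V(A) + V(B))`, in `[0, 1]`.
#'
#' @param A,B `hypervolume_model`s of equal dimension with positive volume.
#' @param labels optional length-2 character vector naming the pair.
#' @return an object of class `overlap_result`: `labels`,
#'   `intersection_volume`, `union_volume`, `sorensen`.
#' @export
sorensen_overlap <- function(A, B, labels = c("A", "B")) {
  stopifnot(inherits(A, "hypervolume_model"), inherits(B, "hypervolume_model"))
  if (A$dimension != B$dimension) {
    stop("hypervolume dimension mismatch: ", A$dimension, " vs ", B$dimension)
  }
  if (A$volume <= 0 || B$volume <= 0) stop("both volumes must be positive")
  frac_a_in_b <- mean(inclusion_test(B, A$random_points))
  frac_b_in_a <- mean(inclusion_test(A, B$random_points))
  intersection <- mean(c(frac_a_in_b * A$volume, frac_b_in_a * B$volume))
  intersection <- min(intersection, A$volume, B$volume)
  sorensen <- 2 * intersection / (A$volume + B$volume)
  structure(
    list(labels = labels,
         intersection_volume = intersection,
         union_volume = A$volume + B$volume - intersection,
         sorensen = min(max(sorensen, 0), 1)),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Sorensen-Dice overlap %s/%s: %.4f (intersection %.4g)\n",
              x$labels[1], x$labels[2], x$sorensen, x$intersection_volume))
  invisible(x)
}

#' Group centroids in morphospace
#'
#' Centroid of each group of interest: by default the arithmetic mean of the
#' members' coordinates on the retained axes; alternatively the mean of a
#' fitted hypervolume's uniform interior points (`from = "random_points"`,
#' requires `models`).
#'
#' @param ord an `ordination`.
#' @param grouping a [taxon_grouping()].
#' @param axes number of axes (`NULL` = Broken-Stick retained count).
#' @param from `"data"` (default) or `"random_points"`.
#' @param models named list of `hypervolume_model`s (one per group of
#'   interest), only used with `from = "random_points"`.
#' @return numeric matrix, one row per group of interest.
#' @export
group_centroids <- function(ord, grouping, axes = NULL,
                            from = c("data", "random_points"), models = NULL) {
  from <- match.arg(from)
  if (from == "random_points") {
    if (is.null(models)) stop("`models` required with from = 'random_points'")
    cent <- do.call(rbind, lapply(models, function(m) colMeans(m$random_points)))
    rownames(cent) <- names(models)
    return(cent)
  }
  pts <- group_points(ord, grouping, axes)
  empty <- names(pts)[vapply(pts, nrow, integer(1)) == 0]
  if (length(empty)) stop("empty group(s): ", paste(empty, collapse = ", "))
  do.call(rbind, lapply(pts, colMeans))
}

#' Pairwise Euclidean distances between centroids
#'
#' @param centroids matrix of centroid coordinates (groups in rows).
#' @return symmetric distance matrix with zero diagonal.
#' @export
centroid_distances <- function(centroids) {
  if (is.null(dim(centroids)) || nrow(centroids) < 2L) {
    stop("need >= 2 centroids")
  }
  as.matrix(stats::dist(centroids))
}

#' Fit one hypervolume per group of interest
#'
#' Groups too small to support a kernel-density hypervolume (fewer than 3
#' points in up to two dimensions, fewer than `d + 1` above) are reported in
#' `skipped` rather than fitted.
#'
#' @inheritParams group_centroids
#' @param seed integer seed; each group gets a deterministic child seed.
#' @param ... passed to [estimate_hypervolume()].
#' @return list with `models` (named list of `hypervolume_model`s) and
#'   `skipped` (named integer vector of group sizes).
#' @export
group_hypervolumes <- function(ord, grouping, axes = NULL, seed = NULL, ...) {
  pts <- group_points(ord, grouping, axes)
  d <- ncol(pts[[1]])
  min_n <- if (d <= 2) 3L else d + 1L
  sizes <- vapply(pts, nrow, integer(1))
  fit <- sizes >= min_n
  models <- lapply(seq_along(pts)[fit], function(i) {
    s <- if (is.null(seed)) NULL else seed + i
    estimate_hypervolume(pts[[i]], seed = s, ...)
  })
  names(models) <- names(pts)[fit]
  list(models = models, skipped = sizes[!fit])
}

#' Pairwise Sorensen-Dice overlap table
#'
#' @param models named list of `hypervolume_model`s.
#' @return data frame with one row per unordered pair: group labels,
#'   component and intersection volumes, and the Sorensen index.
#' @export
overlap_table <- function(models) {
  groups <- names(models)
  if (length(groups) < 2L) stop("need >= 2 hypervolumes")
  pairs <- utils::combn(groups, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    ov <- sorensen_overlap(models[[a]], models[[b]], labels = c(a, b))
    data.frame(group_a = a, group_b = b,
               volume_a = models[[a]]$volume, volume_b = models[[b]]$volume,
               intersection = ov$intersection_volume, sorensen = ov$sorensen)
  })
  do.call(rbind, rows)
}

#' Export hypervolume tables
#'
#' @param models named list of `hypervolume_model`s.
#' @param path output CSV for the per-group summary.
#' @export
write_hypervolumes <- function(models, path) {
  df <- data.frame(
    group = names(models),
    n = vapply(models, function(m) nrow(m$data_points), integer(1)),
    dimension = vapply(models, function(m) m$dimension, integer(1)),
    volume = signif(vapply(models, function(m) m$volume, numeric(1)), 6)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
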