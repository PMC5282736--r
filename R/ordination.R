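#' Broken-Stick expected eigenvalue proportions
#'
#' Null expectation for the proportion of variation on each of `p` ordination
#' axes when total variation is split at random:
#' `b_k = (1/p) * sum(1/i for i in k..p)`. The proportions sum to 1.
#'
#' @param p number of pieces (positive eigenvalues), `>= 1`.
#' @return numeric vector of length `p`, non-increasing, summing to 1.
#' @examples
#' broken_stick_expectation(2) # 0.75 0.25
#' @export
broken_stick_expectation <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || p < 1 || p != round(p)) {
    stop("`p` must be a single integer >= 1")
  }
  p <- as.integer(p)
  rev(cumsum(1 / rev(seq_len(p)))) / p
}

#' Principal coordinates analysis of a dissimilarity matrix
#'
#' Metric multidimensional scaling: the dissimilarity matrix is squared,
#' double-centred (Gower transform of `-0.5 * D^2`) and eigendecomposed;
#' coordinates are eigenvectors scaled by the square root of their
#' eigenvalues. Non-Euclidean inputs (typical for Gower-type distances under
#' pairwise deletion) produce negative eigenvalues; by default these are
#' dropped with a warning, or an additive correction (`"lingoes"`,
#' `"cailliez"`) can be applied. Axis signs are fixed so the
#' largest-magnitude loading on each axis is positive, making output files
#' reproducible.
#'
#' The number of significant axes is chosen against the Broken-Stick model:
#' leading axes whose relative eigenvalue (as a proportion of the summed
#' positive eigenvalues) exceeds the Broken-Stick expectation are retained,
#' stopping at the first failure, with a floor of one axis.
#'
#' @param D a `dissimilarity_matrix` (see [pairwise_dissimilarity()]) or a
#'   plain symmetric numeric matrix with zero diagonal.
#' @param correction `"none"` (default), `"lingoes"` or `"cailliez"`.
#' @return an object of class `ordination`: list with `coordinates`
#'   (taxa-by-axes matrix, columns ordered by non-increasing eigenvalue),
#'   `eigenvalues` (all eigenvalues of the centred matrix, non-increasing),
#'   `relative_eigenvalues` (positive eigenvalues as proportions of their
#'   sum), `correction`, `negative_dropped` and `n_retained`.
#' @examples
#' pts <- cbind(c(0, 1, 3))
#' D <- as.matrix(dist(pts))
#' ord <- pcoa_ordination(D)
#' ord$coordinates
#' @export
pcoa_ordination <- function(D, correction = c("none", "lingoes", "cailliez")) {
  correction <- match.arg(correction)
  values <- if (inherits(D, "dissimilarity_matrix")) {
    require_complete(D, "PCoA")
    D$values
  } else {
    as.matrix(D)
  }
  n <- nrow(values)
  if (n < 2L) stop("PCoA needs at least 2 taxa")
  if (is.null(rownames(values))) {
    rownames(values) <- colnames(values) <- paste0("t", seq_len(n))
  }
  if (anyNA(values)) stop("PCoA input contains undefined distances")
  if (any(abs(values - t(values)) > 1e-10)) stop("PCoA input must be symmetric")
  if (any(diag(values) != 0)) stop("PCoA input must have a zero diagonal")
  if (any(values < 0)) stop("PCoA input must be non-negative")

  if (all(values == 0)) {
    # all taxa coincide: a single zero axis, no variation to partition
    coords <- matrix(0, n, 1, dimnames = list(rownames(values), "axis1"))
    return(new_ordination(coords, eigenvalues = rep(0, n - 1),
                          relative = numeric(0), correction = correction,
                          negative_dropped = 0L))
  }

  res <- ape::pcoa(values, correction = correction)
  eig <- res$values$Eigenvalues
  if (correction != "none" && "Corr_eig" %in% names(res$values)) {
    eig_used <- res$values$Corr_eig
    coords <- if (!is.null(res$vectors.cor)) res$vectors.cor else res$vectors
  } else {
    eig_used <- eig
    coords <- res$vectors
  }
  tol <- max(abs(eig_used)) * 1e-9
  pos <- eig_used > tol
  n_neg <- sum(eig_used < -tol)
  if (correction == "none" && n_neg > 0) {
    warning(sprintf("dropping %d negative eigenvalue(s); input is non-Euclidean (consider correction = 'lingoes' or 'cailliez')",
                    n_neg))
  }
  k <- min(ncol(coords), sum(pos))
  coords <- coords[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("axis", seq_len(k))
  rownames(coords) <- rownames(values)
  coords <- fix_axis_signs(coords)
  relative <- eig_used[pos] / sum(eig_used[pos])
  new_ordination(coords, eigenvalues = sort(eig_used, decreasing = TRUE),
                 relative = relative, correction = correction,
                 negative_dropped = n_neg)
}

new_ordination <- function(coordinates, eigenvalues, relative, correction,
                           negative_dropped) {
  ord <- structure(
    list(coordinates = coordinates,
         eigenvalues = eigenvalues,
         relative_eigenvalues = relative,
         correction = correction,
         negative_dropped = negative_dropped,
         n_retained = NA_integer_),
    class = "ordination"
  )
  ord$n_retained <- retained_axes(ord)
  ord
}

# eigenvector signs are arbitrary; anchor each axis on its largest |loading|
fix_axis_signs <- function(coords) {
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  coords
}

#' Number of Broken-Stick-significant axes
#'
#' Counts leading axes whose relative eigenvalue exceeds the Broken-Stick
#' expectation, stopping at the first axis that fails; at least one axis is
#' always retained.
#'
#' @param ord an `ordination`.
#' @return integer axis count.
#' @export
retained_axes <- function(ord) {
  stopifnot(inherits(ord, "ordination"))
  rel <- ord$relative_eigenvalues
  if (length(rel) == 0L) return(1L)
  bs <- broken_stick_expectation(length(rel))
  exceeds <- rel > bs
  k <- if (!exceeds[1]) 0L else which.min(c(exceeds, FALSE)) - 1L
  max(1L, as.integer(k))
}

#' Ordination coordinates on the retained axes
#'
#' @param ord an `ordination`.
#' @param axes number of axes to return; defaults to the Broken-Stick
#'   retained count (capped at the axes available).
#' @return taxa-by-axes numeric matrix.
#' @export
ord_coordinates <- function(ord, axes = NULL) {
  stopifnot(inherits(ord, "ordination"))
  if (is.null(axes)) axes <- ord$n_retained
  axes <- min(axes, ncol(ord$coordinates))
  ord$coordinates[, seq_len(axes), drop = FALSE]
}

#' @export
print.ordination <- function(x, ...) {
  npos <- length(x$relative_eigenvalues)
  cat(sprintf("PCoA ordination: %d taxa, %d positive axes (correction: %s)\n",
              nrow(x$coordinates), npos, x$correction))
  if (x$negative_dropped > 0) {
    cat(sprintf("  %d negative eigenvalue(s) dropped\n", x$negative_dropped))
  }
  cat(sprintf("  Broken-Stick retains %d axis/axes\n", x$n_retained))
  if (npos > 0) {
    shown <- utils::head(x$relative_eigenvalues, 6)
    cat("  relative eigenvalues:",
        paste(sprintf("%.3f", shown), collapse = " "),
        if (npos > 6) "...\n" else "\n")
  }
  invisible(x)
}

#' Export ordination tables
#'
#' Writes taxon coordinates (`write_ordination`) and the eigenvalue table
#' (`write_eigenvalues`) as CSV.
#'
#' @param ord an `ordination`.
#' @param path output file.
#' @param axes number of coordinate columns to write (default: all).
#' @export
write_ordination <- function(ord, path, axes = ncol(ord$coordinates)) {
  co <- ord$coordinates[, seq_len(min(axes, ncol(ord$coordinates))), drop = FALSE]
  df <- data.frame(taxon = rownames(co), signif(co, 6), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ordination
#' @export
write_eigenvalues <- function(ord, path) {
  rel <- ord$relative_eigenvalues
  npos <- length(rel)
  bs <- if (npos > 0) broken_stick_expectation(npos) else numeric(0)
  df <- data.frame(
    axis = seq_along(ord$eigenvalues),
    eigenvalue = signif(ord$eigenvalues, 6),
    relative = signif(c(rel, rep(NA, length(ord$eigenvalues) - npos)), 6),
    broken_stick = signif(c(bs, rep(NA, length(ord$eigenvalues) - npos)), 6)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
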