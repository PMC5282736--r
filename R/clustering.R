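#' Merge effectively duplicated taxa in a dissimilarity matrix
#'
#' Taxa at pairwise distance at most `tolerance` of one another are collapsed
#' into a single representative before tree building (identically coded taxa
#' otherwise produce zero-length cherries). Groups are formed by transitive
#' closure; the representative keeps the first member's label, and its
#' distance to any other taxon is the arithmetic mean of the members'
#' distances to it.
#'
#' Idempotent at a fixed tolerance: re-running on the reduced matrix merges
#' nothing further (under `tolerance = 0` exactly; small tolerances can in
#' principle chain, which the transitive closure already resolves).
#'
#' @param D a `dissimilarity_matrix`.
#' @param tolerance merge threshold (default `0`: exact duplicates only).
#' @return list with `D` (reduced `dissimilarity_matrix`) and `merges`
#'   (named list: representative -> character vector of all members).
#' @export
deduplicate <- function(D, tolerance = 0) {
  stopifnot(inherits(D, "dissimilarity_matrix"))
  v <- D$values
  n <- nrow(v)
  labels <- rownames(v)
  # union-find transitive closure over pairs within tolerance
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (!is.na(v[i, j]) && v[i, j] <= tolerance) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  reps <- sort(unique(root))
  merges <- list()
  for (r in reps) {
    members <- labels[root == r]
    if (length(members) > 1) merges[[labels[r]]] <- members
  }
  if (length(reps) == n) {
    return(list(D = D, merges = merges))
  }
  k <- length(reps)
  nv <- matrix(0, k, k, dimnames = list(labels[reps], labels[reps]))
  nc <- matrix(0L, k, k, dimnames = dimnames(nv))
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (a == b) next
      ia <- which(root == reps[a]); ib <- which(root == reps[b])
      nv[a, b] <- mean(v[ia, ib, drop = FALSE])
      nc[a, b] <- as.integer(round(mean(D$comparable[ia, ib, drop = FALSE])))
    }
  }
  diag(nc) <- as.integer(round(diag(D$comparable)[reps]))
  list(D = new_dissimilarity_matrix(nv, nc, D$method, D$polymorphism_rule),
       merges = merges)
}

#' Neighbour-joining phenogram
#'
#' Builds an unrooted Saitou-Nei neighbour-joining tree from the
#' dissimilarity matrix (via [ape::nj()]). Dissimilarities under pairwise
#' deletion are generally non-additive, so NJ can estimate negative branch
#' lengths; these are clamped to zero and the deficit transferred to the
#' adjacent branch (towards the root of ape's internal representation), which
#' preserves tip-to-tip path lengths through the affected node. The number
#' of clamped branches is recorded in the `negative_clamped` attribute.
#'
#' @param D a complete `dissimilarity_matrix` (>= 3 taxa), or a plain
#'   symmetric matrix.
#' @return an [ape::phylo] tree.
#' @examples
#' v <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' tr <- neighbour_joining(new_dissimilarity_matrix(v))
#' tr$edge.length # branches 1, 1, 2
#' @export
neighbour_joining <- function(D) {
  values <- if (inherits(D, "dissimilarity_matrix")) {
    require_complete(D, "neighbour joining")
    D$values
  } else as.matrix(D)
  if (nrow(values) < 3L) stop("neighbour joining needs >= 3 taxa")
  tree <- ape::nj(stats::as.dist(values))
  clamp_negative_branches(tree)
}

# Kuhner-Felsenstein style post-pass: zero each negative branch and move its
# (negative) length onto the adjacent branch so paths through the node keep
# their total length where possible.
clamp_negative_branches <- function(tree) {
  clamped <- 0L
  repeat {
    neg <- which(tree$edge.length < 0)
    if (!length(neg)) break
    e <- neg[which.min(tree$edge.length[neg])]
    len <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    clamped <- clamped + 1L
    parent <- tree$edge[e, 1]
    up <- which(tree$edge[, 2] == parent)           # edge above the parent node
    adj <- if (length(up)) up[1] else {
      sib <- which(tree$edge[, 1] == parent)        # root: use a sibling edge
      setdiff(sib, e)[1]
    }
    if (!is.na(adj)) {
      tree$edge.length[adj] <- tree$edge.length[adj] + len
      if (tree$edge.length[adj] < 0 && tree$edge.length[adj] > -1e-12) {
        tree$edge.length[adj] <- 0
      }
    }
    if (clamped > 4L * nrow(tree$edge)) break       # safety against cycling
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "negative_clamped") <- clamped
  tree
}

#' Write / read a phenogram as Newick
#'
#' Thin wrappers over [ape::write.tree()] and [ape::read.tree()] so trees
#' round-trip losslessly at the stated precision.
#'
#' @param tree an [ape::phylo].
#' @param path file path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)

#' k-means cluster-number assessment on ordination axes
#'
#' Runs k-means (best of `restarts` starts) for each candidate number of
#' clusters and scores the partitions with the mean silhouette width or the
#' gap statistic. The "best" k maximises the criterion (for the gap
#' statistic, via the first-SE-max rule). A silhouette below 0.4 at the
#' optimum is flagged as weak evidence of any cluster structure.
#'
#' @param coordinates numeric matrix (observations in rows).
#' @param k_range integer vector of candidate cluster counts, within
#'   `[2, n - 1]`.
#' @param criterion `"silhouette"` (default) or `"gap"`.
#' @param restarts random starts per k.
#' @param seed optional integer seed.
#' @return an object of class `kmeans_assessment`: `table` (data frame of k,
#'   within-cluster sum of squares, criterion score), `best_k`, `criterion`,
#'   `strong_structure` (silhouette criterion only), and `clusters` (the
#'   best-k assignment).
#' @export
kmeans_assessment <- function(coordinates, k_range = 2:6,
                              criterion = c("silhouette", "gap"),
                              restarts = 25, seed = NULL) {
  criterion <- match.arg(criterion)
  coordinates <- as_points(coordinates)
  n <- nrow(coordinates)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range >= n)) {
    stop("k_range must lie within [2, n - 1] (n = ", n, ")")
  }
  if (!is.null(seed)) set.seed(seed)

  dmat <- stats::dist(coordinates)
  fits <- lapply(k_range, function(k) {
    stats::kmeans(coordinates, centers = k, nstart = restarts)
  })
  wss <- vapply(fits, function(f) f$tot.withinss, numeric(1))

  if (criterion == "silhouette") {
    score <- vapply(seq_along(fits), function(i) {
      mean(cluster::silhouette(fits[[i]]$cluster, dmat)[, "sil_width"])
    }, numeric(1))
    best_i <- which.max(score)
  } else {
    gap <- cluster::clusGap(coordinates,
                            FUNcluster = function(x, k) stats::kmeans(x, k, nstart = restarts),
                            K.max = max(k_range), B = 50, verbose = FALSE)
    tab <- gap$Tab[k_range, , drop = FALSE]
    score <- tab[, "gap"]
    best_k_gap <- k_range[cluster::maxSE(tab[, "gap"], tab[, "SE.sim"],
                                         method = "firstSEmax")]
    best_i <- match(best_k_gap, k_range)
  }

  structure(
    list(table = data.frame(k = k_range, within_ss = wss, score = score),
         best_k = k_range[best_i],
         criterion = criterion,
         strong_structure = if (criterion == "silhouette") score[best_i] >= 0.4 else NA,
         clusters = fits[[best_i]]$cluster,
         seed = seed),
    class = "kmeans_assessment"
  )
}

#' @export
print.kmeans_assessment <- function(x, ...) {
  cat(sprintf("k-means assessment (%s): best k = %d%s\n", x$criterion,
              x$best_k,
              if (identical(x$strong_structure, FALSE)) " (weak structure)" else ""))
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @rdname kmeans_assessment
#' @param x a `kmeans_assessment`.
#' @param path output CSV.
#' @export
write_kmeans <- function(x, path) {
  df <- x$table
  df$within_ss <- signif(df$within_ss, 6)
  df$score <- signif(df$score, 6)
  df$best <- df$k == x$best_k
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
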