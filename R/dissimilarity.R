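#' Pairwise taxon dissimilarities under pairwise deletion
#'
#' Computes a symmetric taxon-by-taxon dissimilarity matrix from a discrete
#' character matrix. For each pair, only characters scored (neither missing
#' nor inapplicable) in both taxa are compared; inapplicable cells are treated
#' exactly like missing ones. Per-character differences are 0/1 mismatches for
#' unordered characters and `|a - b| / range` for ordered ones (range taken
#' over the full matrix).
#'
#' Methods:
#' \describe{
#'   \item{`gower`}{mean per-character difference over comparable characters.}
#'   \item{`mord`}{maximum observable rescaled distance: sum of raw
#'     per-character differences divided by the sum of maximum attainable
#'     differences (1 per unordered character, the state range per ordered
#'     character) over comparable characters. Coincides with `gower` when all
#'     characters are unordered.}
#'   \item{`hamming`}{raw mismatch proportion, ignoring character ordering.}
#' }
#'
#' Polymorphic cells are resolved by `polymorphism_rule`: `"min"` takes the
#' smallest difference over the two state sets (0 when they intersect),
#' `"mean"` averages the difference over all state pairs.
#'
#' Distances built this way are bounded in \[0, 1\] but, because each pair may
#' use a different character subset, they need not satisfy the triangle
#' inequality.
#'
#' @param x a [character_matrix()].
#' @param method `"mord"` (default), `"gower"` or `"hamming"`.
#' @param polymorphism_rule `"min"` (default) or `"mean"`.
#' @return an object of class `dissimilarity_matrix`: list with `values`
#'   (symmetric numeric matrix, `NA` where a pair shares no scored character),
#'   `comparable` (integer matrix of per-pair comparable-character counts),
#'   `method` and `polymorphism_rule`.
#' @examples
#' m <- character_matrix(rbind(A = c("0", "1", "?"), B = c("0", "-", "1")))
#' pairwise_dissimilarity(m)$values
#' @export
pairwise_dissimilarity <- function(x, method = c("mord", "gower", "hamming"),
                                   polymorphism_rule = c("min", "mean")) {
  validate_character_matrix(x)
  method <- match.arg(method)
  polymorphism_rule <- match.arg(polymorphism_rule)
  if (n_taxa(x) < 2L) stop("need at least 2 taxa for pairwise dissimilarities")

  nt <- n_taxa(x)
  nc <- n_characters(x)
  states <- lapply(seq_len(nt), function(i) {
    lapply(seq_len(nc), function(j) cell_states(x$cells[i, j]))
  })
  scored <- scored_cells(x)
  # per-character observed range over the whole matrix (for ordered scaling)
  char_range <- vapply(seq_len(nc), function(j) {
    s <- unlist(lapply(seq_len(nt), function(i) states[[i]][[j]]))
    if (length(s) == 0L) 0 else diff(range(s))
  }, numeric(1))

  values <- matrix(0, nt, nt, dimnames = list(taxon_labels(x), taxon_labels(x)))
  comparable <- matrix(0L, nt, nt, dimnames = dimnames(values))
  diag(comparable) <- as.integer(rowSums(scored))

  for (i in seq_len(nt - 1L)) {
    for (j in (i + 1L):nt) {
      comp <- which(scored[i, ] & scored[j, ])
      comparable[i, j] <- comparable[j, i] <- length(comp)
      if (length(comp) == 0L) {
        values[i, j] <- values[j, i] <- NA_real_
        next
      }
      raw <- numeric(length(comp))   # |a-b| (ordered) or 0/1 (unordered)
      maxd <- numeric(length(comp))  # max attainable difference
      for (k in seq_along(comp)) {
        ch <- comp[k]
        d <- state_set_difference(states[[i]][[ch]], states[[j]][[ch]],
                                  ordered = x$ordering[ch] && method != "hamming",
                                  rule = polymorphism_rule)
        raw[k] <- d
        maxd[k] <- if (x$ordering[ch] && method != "hamming") char_range[ch] else 1
      }
      v <- switch(method,
        hamming = mean(raw),
        gower = mean(ifelse(maxd > 0, raw / maxd, 0)),
        mord = if (sum(maxd) > 0) sum(raw) / sum(maxd) else 0
      )
      values[i, j] <- values[j, i] <- v
    }
  }
  structure(
    list(values = values, comparable = comparable,
         method = method, polymorphism_rule = polymorphism_rule),
    class = "dissimilarity_matrix"
  )
}

# Difference between two non-empty state sets for one character.
# unordered: 0/1 mismatch; ordered: |a-b| (unscaled; caller divides by range).
state_set_difference <- function(a, b, ordered, rule) {
  if (!ordered) {
    if (rule == "min") {
      return(if (length(intersect(a, b))) 0 else 1)
    }
    g <- expand.grid(a = a, b = b)
    return(mean(g$a != g$b))
  }
  diffs <- abs(outer(a, b, "-"))
  if (rule == "min") min(diffs) else mean(diffs)
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  n <- nrow(x$values)
  und <- sum(is.na(x$values[upper.tri(x$values)]))
  cat(sprintf("Dissimilarity matrix (%s, polymorphism rule '%s'): %d taxa\n",
              x$method, x$polymorphism_rule, n))
  if (und > 0) cat(sprintf("  %d pair(s) share no scored character (NA)\n", und))
  invisible(x)
}

#' @export
as.dist.dissimilarity_matrix <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$values, diag = diag, upper = upper)
}

#' Has every pair at least one comparable character?
#'
#' @param D a `dissimilarity_matrix`.
#' @return `TRUE` when all off-diagonal distances are defined.
#' @export
is_complete <- function(D) {
  !anyNA(D$values[upper.tri(D$values)])
}

# Fail fast before stages that require a complete matrix.
require_complete <- function(D, stage) {
  if (!is_complete(D)) {
    bad <- which(is.na(D$values) & upper.tri(D$values), arr.ind = TRUE)
    pairs <- apply(bad, 1, function(idx) {
      paste(rownames(D$values)[idx[1]], colnames(D$values)[idx[2]], sep = " / ")
    })
    stop(stage, " requires a complete dissimilarity matrix; pairs with no ",
         "comparable characters: ", paste(pairs, collapse = "; "),
         ". Remove missing-data-rich taxa first (see filter_outliers).")
  }
  invisible(D)
}

#' Comparability report for a dissimilarity matrix
#'
#' Summarises how many characters each taxon pair actually shares, flagging
#' pairs whose comparable-character count falls below `min_comparable`. Useful
#' for spotting missing-data-rich taxa whose distances rest on very little
#' evidence.
#'
#' @param D a `dissimilarity_matrix`.
#' @param min_comparable pairs strictly below this count are listed.
#' @return list with `per_taxon` (data frame: taxon, mean and minimum
#'   comparable count over its pairs) and `low_pairs` (data frame of flagged
#'   pairs). The input is not modified.
#' @export
distance_completeness_report <- function(D, min_comparable = 1L) {
  stopifnot(inherits(D, "dissimilarity_matrix"))
  n <- nrow(D$values)
  if (n < 2L) stop("comparability report needs at least 2 taxa")
  labels <- rownames(D$values)
  off <- D$comparable
  diag(off) <- NA_integer_
  per_taxon <- data.frame(
    taxon = labels,
    mean_comparable = rowMeans(off, na.rm = TRUE),
    min_comparable = apply(off, 1, min, na.rm = TRUE)
  )
  idx <- which(upper.tri(off) & off < min_comparable, arr.ind = TRUE)
  low_pairs <- data.frame(
    taxon_a = labels[idx[, 1]],
    taxon_b = labels[idx[, 2]],
    comparable = D$comparable[idx]
  )
  list(per_taxon = per_taxon, low_pairs = low_pairs)
}

#' Export a dissimilarity matrix
#'
#' `write_distances()` writes the square matrix as CSV;
#' `write_distances_phylip()` writes PHYLIP-style lower-triangle text.
#'
#' @param D a `dissimilarity_matrix`.
#' @param path output file.
#' @export
write_distances <- function(D, path) {
  df <- data.frame(taxon = rownames(D$values), D$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_distances
#' @export
write_distances_phylip <- function(D, path) {
  n <- nrow(D$values)
  lines <- as.character(n)
  for (i in seq_len(n)) {
    vals <- if (i > 1) paste(formatC(D$values[i, 1:(i - 1)], format = "f", digits = 6),
                             collapse = " ") else ""
    lines <- c(lines, trimws(paste(formatC(rownames(D$values)[i], width = -12), vals)))
  }
  writeLines(lines, path)
  invisible(path)
}

# Internal constructor used by deduplicate() and tests: wrap a plain symmetric
# matrix as a dissimilarity_matrix.
new_dissimilarity_matrix <- function(values, comparable = NULL,
                                     method = "precomputed",
                                     polymorphism_rule = "none") {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (is.null(rownames(values))) {
    rownames(values) <- colnames(values) <- paste0("t", seq_len(nrow(values)))
  }
  if (is.null(comparable)) {
    comparable <- matrix(1L, nrow(values), ncol(values),
                         dimnames = dimnames(values))
  }
  structure(
    list(values = values, comparable = comparable,
         method = method, polymorphism_rule = polymorphism_rule),
    class = "dissimilarity_matrix"
  )
}
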