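# Fixtures are built in code; nothing binary ships with the package.

# small hand-written matrices -------------------------------------------------

toy_matrix <- function() {
  character_matrix(rbind(
    A = c("0", "1", "1"),
    B = c("0", "1", "1"),
    C = c("1", "0", "0")
  ))
}

nexus_text <- function(interleaved = FALSE) {
  if (!interleaved) {
    c("#NEXUS",
      "BEGIN DATA;",
      "  DIMENSIONS NTAX=2 NCHAR=3;",
      "  FORMAT DATATYPE=STANDARD MISSING=? GAP=- SYMBOLS=\"01\";",
      "  MATRIX",
      "    taxon_a 01?",
      "    'taxon b' 0-1",
      "  ;",
      "END;")
  } else {
    c("#NEXUS",
      "BEGIN CHARACTERS;",
      "  DIMENSIONS NTAX=2 NCHAR=4;",
      "  FORMAT DATATYPE=STANDARD MISSING=? GAP=- SYMBOLS=\"01\" INTERLEAVE;",
      "  MATRIX",
      "    taxon_a 01",
      "    taxon_b 0-",
      "",
      "    taxon_a ?1",
      "    taxon_b 10",
      "  ;",
      "END;")
  }
}

write_temp_lines <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# random matrices for property-style tests ------------------------------------

random_binary_matrix <- function(n_taxa, n_char, missing_rate = 0.1) {
  cells <- matrix(as.character(stats::rbinom(n_taxa * n_char, 1, 0.5)),
                  n_taxa, n_char,
                  dimnames = list(paste0("t", seq_len(n_taxa)), NULL))
  mask <- matrix(stats::runif(n_taxa * n_char) < missing_rate, n_taxa, n_char)
  cells[mask] <- "?"
  character_matrix(cells)
}

# coordinate-level fixtures ----------------------------------------------------

# an `ordination` wrapper around known coordinates, for stages that only
# consume coordinates (disparity, hypervolume, clustering)
ordination_from_coords <- function(coords) {
  if (is.null(rownames(coords))) {
    rownames(coords) <- paste0("t", seq_len(nrow(coords)))
  }
  colnames(coords) <- paste0("axis", seq_len(ncol(coords)))
  structure(
    list(coordinates = coords,
         eigenvalues = rep(1, ncol(coords)),
         relative_eigenvalues = rep(1 / ncol(coords), ncol(coords)),
         correction = "none", negative_dropped = 0L,
         n_retained = ncol(coords)),
    class = "ordination"
  )
}

two_group_ordination <- function(pa, pb) {
  coords <- rbind(pa, pb)
  rownames(coords) <- c(paste0("a", seq_len(nrow(pa))),
                        paste0("b", seq_len(nrow(pb))))
  g <- taxon_grouping(setNames(rep(c("A", "B"), c(nrow(pa), nrow(pb))),
                               rownames(coords)))
  list(ord = ordination_from_coords(coords), grouping = g)
}

# trees -------------------------------------------------------------------------

# does the unrooted tree contain a split placing `side` and `other` on
# opposite sides (taxa outside both sets unconstrained)?
has_separating_split <- function(tree, side, other) {
  bp <- ape::prop.part(tree)
  labs <- attr(bp, "labels")
  si <- match(side, labs); oi <- match(other, labs)
  any(vapply(bp, function(p) {
    (all(si %in% p) && !any(oi %in% p)) || (all(oi %in% p) && !any(si %in% p))
  }, logical(1)))
}

# path-length (additive) distances of a random tree; the additivity oracle
random_additive_distances <- function(n) {
  tree <- ape::rtree(n, rooted = FALSE)
  tree$edge.length <- stats::runif(nrow(tree$edge), 0.1, 2)
  list(tree = tree, D = ape::cophenetic.phylo(tree))
}
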