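#' Discrete morphological character matrices
#'
#' A `character_matrix` holds a taxa-by-characters table of discrete
#' (cladistic) scores. Each cell is one of: a single state symbol (a small
#' non-negative integer), the missing token `"?"`, the inapplicable token
#' `"-"`, or a polymorphism written `"{..}"` (e.g. `"{01}"` for states 0 and
#' 1). Missing and inapplicable cells are kept distinct in the data model even
#' though downstream dissimilarities treat both as unscored, so that
#' alternative treatments remain testable.
#'
#' @param cells character matrix (taxa in rows, characters in columns) of
#'   canonical cell tokens. Row names are taxon labels; column names are
#'   character ids (defaulted to `c1..cK` when absent).
#' @param ordering logical vector, one flag per character: `TRUE` for ordered
#'   (additive) characters, `FALSE` (default) for unordered.
#' @param alphabet integer vector of permitted state symbols. Defaults to the
#'   states observed in `cells`.
#'
#' @return An object of class `character_matrix`: a list with elements
#'   `cells`, `ordering` and `alphabet`.
#' @examples
#' m <- character_matrix(rbind(
#'   A = c("0", "1", "?"),
#'   B = c("0", "-", "1")
#' ))
#' n_taxa(m)
#' unscored_fraction(m)
#' @export
character_matrix <- function(cells, ordering = NULL, alphabet = NULL) {
  if (!is.matrix(cells) || !is.character(cells)) {
    stop("`cells` must be a character matrix of cell tokens")
  }
  if (nrow(cells) < 1L) stop("character matrix must contain at least one taxon")
  if (ncol(cells) < 1L) stop("character matrix must contain at least one character")
  if (is.null(rownames(cells))) {
    stop("`cells` must carry taxon labels as row names")
  }
  if (is.null(colnames(cells))) {
    colnames(cells) <- paste0("c", seq_len(ncol(cells)))
  }
  cells[] <- canonical_cell(cells)
  if (is.null(ordering)) ordering <- rep(FALSE, ncol(cells))
  ordering <- rep_len(as.logical(ordering), ncol(cells))
  observed <- observed_states(cells)
  if (is.null(alphabet)) {
    alphabet <- observed
    if (length(alphabet) == 0L) alphabet <- 0:1
  }
  alphabet <- sort(unique(as.integer(alphabet)))
  obj <- structure(
    list(cells = cells, ordering = ordering, alphabet = alphabet),
    class = "character_matrix"
  )
  validate_character_matrix(obj)
  obj
}

#' Validate a character matrix
#'
#' Checks the structural invariants: unique non-empty taxon labels, rectangular
#' cells, every state symbol inside the declared alphabet, and polymorphic
#' sets of at least two distinct valid states.
#'
#' @param x a `character_matrix`.
#' @return `x`, invisibly, if valid; otherwise an error naming the offending
#'   taxon and character.
#' @export
validate_character_matrix <- function(x) {
  stopifnot(inherits(x, "character_matrix"))
  taxa <- rownames(x$cells)
  if (any(!nzchar(taxa))) stop("taxon labels must be non-empty")
  if (anyDuplicated(taxa)) {
    stop("duplicated taxon labels: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  if (length(x$ordering) != ncol(x$cells)) {
    stop("`ordering` must have one flag per character")
  }
  for (i in seq_len(nrow(x$cells))) {
    for (j in seq_len(ncol(x$cells))) {
      cell <- x$cells[i, j]
      if (cell %in% c(MISSING_TOKEN, INAPPLICABLE_TOKEN)) next
      states <- cell_states(cell)
      if (length(states) == 0L || anyNA(states)) {
        stop(sprintf("unparseable cell '%s' at taxon '%s', character '%s'",
                     cell, taxa[i], colnames(x$cells)[j]))
      }
      if (is_polymorphic_cell(cell) && length(states) < 2L) {
        stop(sprintf("polymorphic cell with <2 distinct states at taxon '%s', character '%s'",
                     taxa[i], colnames(x$cells)[j]))
      }
      bad <- setdiff(states, x$alphabet)
      if (length(bad)) {
        stop(sprintf("state symbol '%s' at taxon '%s', character '%s' is not in the declared alphabet",
                     paste(bad, collapse = ","), taxa[i], colnames(x$cells)[j]))
      }
    }
  }
  invisible(x)
}

MISSING_TOKEN <- "?"
INAPPLICABLE_TOKEN <- "-"

# Canonicalise raw cell tokens: trim whitespace, map () polymorphism notation
# to {} and sort the states inside a polymorphism ("{10}" -> "{01}").
canonical_cell <- function(cell) {
  cell <- gsub("[[:space:]]", "", cell)
  poly <- grepl("^[({].*[)}]$", cell)
  if (any(poly)) {
    inner <- gsub("^[({]|[)}]$", "", cell[poly])
    inner <- gsub(",", "", inner)
    cell[poly] <- vapply(strsplit(inner, ""), function(s) {
      paste0("{", paste(sort(unique(s)), collapse = ""), "}")
    }, character(1))
  }
  cell
}

is_polymorphic_cell <- function(cell) grepl("^\\{", cell)

# Integer states encoded by a cell token; integer(0) for missing/inapplicable.
cell_states <- function(cell) {
  if (cell %in% c(MISSING_TOKEN, INAPPLICABLE_TOKEN)) return(integer(0))
  if (is_polymorphic_cell(cell)) {
    return(suppressWarnings(as.integer(strsplit(gsub("[{}]", "", cell), "")[[1]])))
  }
  suppressWarnings(as.integer(cell))
}

observed_states <- function(cells) {
  tok <- cells[!cells %in% c(MISSING_TOKEN, INAPPLICABLE_TOKEN)]
  if (length(tok) == 0L) return(integer(0))
  sort(unique(unlist(lapply(tok, cell_states))))
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("Character matrix: %d taxa x %d characters\n",
              nrow(x$cells), ncol(x$cells)))
  cat(sprintf("  alphabet: {%s}; %d ordered, %d unordered characters\n",
              paste(x$alphabet, collapse = ","),
              sum(x$ordering), sum(!x$ordering)))
  cat(sprintf("  unscored cells: %.1f%% ('%s' missing, '%s' inapplicable)\n",
              100 * mean(!scored_cells(x)), MISSING_TOKEN, INAPPLICABLE_TOKEN))
  invisible(x)
}

#' Matrix dimensions and labels
#'
#' @param x a `character_matrix`.
#' @return `n_taxa()` and `n_characters()` return counts; `taxon_labels()`
#'   the ordered taxon names.
#' @export
n_taxa <- function(x) nrow(x$cells)

#' @rdname n_taxa
#' @export
n_characters <- function(x) ncol(x$cells)

#' @rdname n_taxa
#' @export
taxon_labels <- function(x) rownames(x$cells)

#' Which cells carry a score?
#'
#' Logical matrix marking cells that are neither missing nor inapplicable.
#' @param x a `character_matrix`.
#' @export
scored_cells <- function(x) {
  m <- x$cells != MISSING_TOKEN & x$cells != INAPPLICABLE_TOKEN
  dimnames(m) <- dimnames(x$cells)
  m
}

#' Per-taxon unscored-cell fraction
#'
#' Missing (`?`) and inapplicable (`-`) cells both count as unscored, mirroring
#' their treatment as uncertainties in the dissimilarity stage.
#' @param x a `character_matrix`.
#' @return named numeric vector in `[0, 1]`, one entry per taxon.
#' @export
unscored_fraction <- function(x) {
  rowMeans(!scored_cells(x))
}

#' Subset a character matrix by taxa
#'
#' @param x a `character_matrix`.
#' @param taxa character vector of taxon labels (or logical/integer row index).
#' @return a `character_matrix` restricted to the requested taxa, characters
#'   untouched.
#' @export
subset_taxa <- function(x, taxa) {
  cells <- x$cells[taxa, , drop = FALSE]
  if (nrow(cells) == 0L) stop("taxon subset is empty")
  character_matrix(cells, ordering = x$ordering, alphabet = x$alphabet)
}

#' Taxon-to-group assignments
#'
#' Binds a named group assignment to the taxa of a character matrix (or any
#' labelled coordinate set) and singles out the groups of interest for the
#' disparity statistics.
#'
#' @param assignment named character vector: names are taxon labels, values
#'   group labels. Taxa absent from it are treated as ungrouped (queries).
#' @param groups_of_interest character vector of group labels the disparity
#'   and hypervolume stages operate on. Defaults to all assigned groups.
#' @return an object of class `taxon_grouping`.
#' @examples
#' g <- taxon_grouping(c(A = "g1", B = "g1", C = "g2"))
#' group_members(g, "g1")
#' @export
taxon_grouping <- function(assignment, groups_of_interest = NULL) {
  if (is.null(names(assignment)) || any(!nzchar(names(assignment)))) {
    stop("`assignment` must be a named vector (names = taxon labels)")
  }
  if (anyDuplicated(names(assignment))) {
    stop("duplicated taxon labels in grouping: ",
         paste(unique(names(assignment)[duplicated(names(assignment))]), collapse = ", "))
  }
  assignment <- vapply(assignment, as.character, character(1))
  if (is.null(groups_of_interest)) groups_of_interest <- sort(unique(assignment))
  missing_groups <- setdiff(groups_of_interest, assignment)
  if (length(missing_groups)) {
    stop("groups of interest without members: ",
         paste(missing_groups, collapse = ", "))
  }
  structure(
    list(assignment = assignment, groups_of_interest = as.character(groups_of_interest)),
    class = "taxon_grouping"
  )
}

#' @export
print.taxon_grouping <- function(x, ...) {
  tab <- table(x$assignment)
  cat(sprintf("Taxon grouping: %d taxa in %d groups (%s of interest)\n",
              length(x$assignment), length(tab),
              paste(x$groups_of_interest, collapse = ", ")))
  print(tab)
  invisible(x)
}

#' @rdname taxon_grouping
#' @param grouping a `taxon_grouping`.
#' @param group a group label.
#' @export
group_members <- function(grouping, group) {
  names(grouping$assignment)[grouping$assignment == group]
}

# Check that every assigned taxon exists among `labels`; used when a grouping
# is paired with a matrix or ordination.
check_grouping_against <- function(grouping, labels) {
  unknown <- setdiff(names(grouping$assignment), labels)
  if (length(unknown)) {
    stop("grouping assigns taxa absent from the data: ",
         paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}
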