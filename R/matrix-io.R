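#' Read a discrete character matrix
#'
#' Reads a morphological matrix from NEXUS (`CHARACTERS`/`DATA` block,
#' interleaved or not) or CSV (first column taxon labels, header row of
#' character ids). `"?"` maps to missing, `"-"` to inapplicable, and `"{..}"`
#' or `"(..)"` to a polymorphic state set. `ASSUMPTIONS`/`TREES` blocks in a
#' NEXUS file are ignored.
#'
#' @param path file to read.
#' @param format `"nexus"` or `"csv"`; guessed from the file extension when
#'   `NULL`.
#' @param ordering optional logical vector marking ordered characters
#'   (sidecar configuration; all characters default to unordered).
#' @return a validated [character_matrix()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("taxon,c1,c2,c3", "A,0,1,?", "B,0,-,1"), f)
#' read_matrix(f)
#' @export
read_matrix <- function(path, format = NULL, ordering = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- guess_format(path, format)
  rows <- switch(format,
    nexus = parse_nexus_matrix(path),
    csv   = parse_csv_matrix(path),
    stop("unsupported format: ", format)
  )
  character_matrix(rows, ordering = ordering)
}

guess_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(tolower(format), c("nexus", "csv")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("nex", "nexus", "nxs")) "nexus"
  else if (ext %in% c("csv", "txt")) "csv"
  else stop("cannot guess format from extension '", ext, "'; pass `format`")
}

# --- NEXUS ------------------------------------------------------------------

strip_nexus_comments <- function(text) {
  # [] comments may span lines; a simple state machine keeps quoted labels safe
  out <- character(length(text))
  depth <- 0L
  for (k in seq_along(text)) {
    chars <- strsplit(text[[k]], "")[[1]]
    keep <- logical(length(chars))
    for (i in seq_along(chars)) {
      if (chars[i] == "[") depth <- depth + 1L
      else if (chars[i] == "]" && depth > 0L) depth <- depth - 1L
      else if (depth == 0L) keep[i] <- TRUE
    }
    out[k] <- paste(chars[keep], collapse = "")
  }
  out
}

parse_nexus_matrix <- function(path) {
  text <- readLines(path, warn = FALSE)
  if (!length(text) || !grepl("^#NEXUS", toupper(trimws(text[1])))) {
    stop("not a NEXUS file (missing #NEXUS header): ", path)
  }
  text <- strip_nexus_comments(text)
  up <- toupper(text)

  begin <- grep("^\\s*BEGIN\\s+(DATA|CHARACTERS)\\s*;", up)
  if (!length(begin)) stop("no DATA or CHARACTERS block in ", path)
  ends <- grep("^\\s*END\\s*;", up)
  end <- ends[ends > begin[1]][1]
  if (is.na(end)) stop("unterminated DATA/CHARACTERS block in ", path)
  block <- text[(begin[1] + 1L):(end - 1L)]
  blockup <- toupper(block)

  dim_line <- paste(block[grep("DIMENSIONS", blockup)], collapse = " ")
  ntax <- nexus_keyval(dim_line, "NTAX")
  nchar_ <- nexus_keyval(dim_line, "NCHAR")
  if (is.na(ntax) || is.na(nchar_)) stop("DIMENSIONS must declare NTAX and NCHAR")

  fmt_line <- paste(block[grep("FORMAT", blockup)], collapse = " ")
  missing_sym <- nexus_keyval(fmt_line, "MISSING", default = "?", numeric = FALSE)
  gap_sym <- nexus_keyval(fmt_line, "GAP", default = "-", numeric = FALSE)

  mstart <- grep("^\\s*MATRIX\\b", blockup)
  if (!length(mstart)) stop("no MATRIX statement in DATA/CHARACTERS block")
  mlines <- block[(mstart[1] + 1L):length(block)]
  semi <- grep(";", mlines)
  if (length(semi)) {
    mlines[semi[1]] <- sub(";.*$", "", mlines[semi[1]])
    mlines <- mlines[seq_len(semi[1])]
  }
  mlines <- trimws(mlines)
  mlines <- mlines[nzchar(mlines)]

  rows <- list()  # taxon -> concatenated token vector (handles interleave)
  order_seen <- character(0)
  for (line in mlines) {
    parsed <- parse_nexus_row(line)
    taxon <- parsed$taxon
    toks <- parsed$tokens
    toks[toks == missing_sym] <- MISSING_TOKEN
    toks[toks == gap_sym] <- INAPPLICABLE_TOKEN
    if (is.null(rows[[taxon]])) {
      rows[[taxon]] <- toks
      order_seen <- c(order_seen, taxon)
    } else {
      rows[[taxon]] <- c(rows[[taxon]], toks)
    }
  }
  if (length(rows) != ntax) {
    stop(sprintf("NEXUS declares NTAX=%d but matrix has %d taxa", ntax, length(rows)))
  }
  lens <- vapply(rows, length, integer(1))
  if (any(lens != nchar_)) {
    bad <- order_seen[lens[order_seen] != nchar_][1]
    stop(sprintf("taxon '%s' has %d characters, expected NCHAR=%d",
                 bad, lens[[bad]], nchar_))
  }
  m <- do.call(rbind, rows[order_seen])
  rownames(m) <- order_seen
  colnames(m) <- paste0("c", seq_len(nchar_))
  m
}

nexus_keyval <- function(line, key, default = NA, numeric = TRUE) {
  pat <- paste0("(?i)", key, "\\s*=\\s*(\"[^\"]*\"|'[^']*'|\\S+)")
  m <- regmatches(line, regexpr(pat, line, perl = TRUE))
  if (!length(m)) return(default)
  val <- sub(paste0("(?i)", key, "\\s*=\\s*"), "", m, perl = TRUE)
  val <- gsub("^['\"]|['\"]$", "", val)
  val <- sub(";$", "", val)
  if (numeric) as.integer(val) else val
}

# One matrix row: taxon label (possibly 'quoted with spaces') then cell tokens.
# Tokens are single symbols except {..}/(..) polymorphism groups.
parse_nexus_row <- function(line) {
  line <- trimws(line)
  if (grepl("^'", line)) {
    close_q <- regexpr("'", substring(line, 2)) + 1L
    taxon <- substr(line, 2, close_q - 1L)
    rest <- trimws(substring(line, close_q + 1L))
  } else {
    sp <- regexpr("\\s", line)
    if (sp < 0) stop("matrix row without cells: '", line, "'")
    taxon <- substr(line, 1, sp - 1L)
    rest <- trimws(substring(line, sp + 1L))
  }
  tokens <- character(0)
  chars <- strsplit(gsub("\\s", "", rest), "")[[1]]
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c("{", "(")) {
      closer <- if (ch == "{") "}" else ")"
      j <- i
      while (j <= length(chars) && chars[j] != closer) j <- j + 1L
      if (j > length(chars)) stop("unclosed polymorphism in row for '", taxon, "'")
      tokens <- c(tokens, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else {
      tokens <- c(tokens, ch)
      i <- i + 1L
    }
  }
  list(taxon = taxon, tokens = tokens)
}

# --- CSV --------------------------------------------------------------------

parse_csv_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        strip.white = TRUE)
  if (ncol(df) < 2L) stop("CSV matrix needs a taxon column plus >=1 character column")
  taxa <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(taxa)) {
    stop("duplicated taxon labels in ", path, ": ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  rownames(m) <- taxa
  m
}

#' Write a character matrix
#'
#' Serialises to NEXUS (single `DATA` block, `MISSING=?`, `GAP=-`,
#' polymorphisms in `{..}` notation) or CSV. Re-reading the file with
#' [read_matrix()] reproduces the in-memory matrix cell-for-cell.
#'
#' @param x a [character_matrix()].
#' @param path output file.
#' @param format `"nexus"` or `"csv"`; guessed from the extension when `NULL`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, format = NULL) {
  validate_character_matrix(x)
  format <- guess_format(path, format)
  if (format == "csv") {
    df <- data.frame(taxon = taxon_labels(x), x$cells,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  symbols <- paste(x$alphabet, collapse = "")
  # pad labels so rows align; quote labels containing whitespace
  labels <- taxon_labels(x)
  labels_out <- ifelse(grepl("\\s", labels), paste0("'", labels, "'"), labels)
  pad <- max(nchar(labels_out)) + 2L
  rows <- vapply(seq_len(n_taxa(x)), function(i) {
    paste0(formatC(labels_out[i], width = -pad),
           paste(x$cells[i, ], collapse = ""))
  }, character(1))
  writeLines(c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", n_taxa(x), n_characters(x)),
    sprintf("  FORMAT DATATYPE=STANDARD MISSING=%s GAP=%s SYMBOLS=\"%s\";",
            MISSING_TOKEN, INAPPLICABLE_TOKEN, symbols),
    "  MATRIX",
    paste0("    ", rows),
    "  ;",
    "END;"
  ), path)
  invisible(path)
}

#' Read a taxon-to-group assignment table
#'
#' Expects a two-column CSV (`taxon,group`; a header row is accepted and
#' detected by name). Taxa labelled with any group are assigned; rows with an
#' empty group are kept as ungrouped query taxa.
#'
#' @param path CSV file.
#' @param groups_of_interest optional subset of group labels for the
#'   disparity stages; defaults to all groups found.
#' @return a [taxon_grouping()].
#' @export
read_groups <- function(path, groups_of_interest = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        strip.white = TRUE, header = TRUE)
  if (ncol(df) < 2L) stop("group table needs two columns (taxon, group)")
  assignment <- stats::setNames(df[[2]], df[[1]])
  assignment <- assignment[nzchar(assignment)]
  taxon_grouping(assignment, groups_of_interest = groups_of_interest)
}

#' @rdname read_groups
#' @param grouping a [taxon_grouping()].
#' @export
write_groups <- function(grouping, path) {
  df <- data.frame(taxon = names(grouping$assignment),
                   group = unname(grouping$assignment))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove missing-data-rich outlier taxa
#'
#' Taxa whose unscored-cell fraction (missing plus inapplicable) exceeds
#' `max_missing_fraction` are dropped before the dissimilarity stage. Poorly
#' scored taxa act as ordination outliers — their few comparable characters
#' make them spuriously distant from everything — so removing them is part of
#' the standard workflow for fossil matrices.
#'
#' @param x a [character_matrix()].
#' @param max_missing_fraction taxa strictly above this unscored fraction are
#'   removed; `1` keeps everything.
#' @return list with `matrix` (the filtered [character_matrix()]) and
#'   `removed` (data frame of dropped taxa with their unscored fractions).
#' @examples
#' m <- character_matrix(rbind(A = c("0", "1"), B = c("?", "?")))
#' filter_outliers(m, 0.5)$removed
#' @export
filter_outliers <- function(x, max_missing_fraction) {
  validate_character_matrix(x)
  if (!is.numeric(max_missing_fraction) || length(max_missing_fraction) != 1L ||
      max_missing_fraction < 0 || max_missing_fraction > 1) {
    stop("`max_missing_fraction` must be a single value in [0, 1]")
  }
  frac <- unscored_fraction(x)
  drop <- frac > max_missing_fraction
  removed <- data.frame(taxon = names(frac)[drop],
                        unscored_fraction = unname(frac[drop]))
  if (all(drop)) {
    stop("all taxa exceed the unscored-fraction threshold ",
         max_missing_fraction)
  }
  kept <- if (any(drop)) subset_taxa(x, !drop) else x
  list(matrix = kept, removed = removed)
}
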