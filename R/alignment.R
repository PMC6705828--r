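# Alignment container and readers/writers (FASTA, relaxed sequential
# PHYLIP) plus Newick tree I/O.
#
# An alignment is stored as an ape 'DNAbin' matrix: one row per isolate,
# unique rownames, all rows the same length. All functions in the package
# accept either a DNAbin matrix or a character matrix and canonicalize via
# as_alignment().

#' Coerce to the canonical alignment representation
#'
#' @param x a `DNAbin` matrix, a character matrix with rownames, or a named
#'   character vector of equal-length sequence strings.
#' @return a `DNAbin` matrix with unique rownames.
#' @export
as_alignment <- function(x) {
  if (inherits(x, "DNAbin")) {
    if (!is.matrix(x)) x <- as.matrix(x)
  } else if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x))) .stop_fmt("sequence vector must be named")
    lens <- nchar(x)
    if (length(unique(lens)) > 1L)
      .stop_fmt("unequal sequence lengths: %s", paste(unique(lens), collapse = ", "))
    m <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(m) <- names(x)
    x <- ape::as.DNAbin(m)
  } else if (is.matrix(x) && is.character(x)) {
    x <- ape::as.DNAbin(x)
  } else {
    .stop_fmt("cannot interpret object of class '%s' as an alignment", class(x)[1L])
  }
  nm <- rownames(x)
  if (is.null(nm) || any(!nzchar(nm)))
    .stop_fmt("alignment rows must carry non-empty names")
  if (anyDuplicated(nm))
    .stop_fmt("duplicate isolate names: %s",
              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  x
}

#' Convert an alignment to an upper-case character matrix
#' @param x an alignment.
#' @return character matrix of symbols in `{A,C,G,T,N,-}` (plus IUPAC codes).
#' @export
alignment_matrix <- function(x) {
  toupper(as.character(as_alignment(x)))
}

#' Read a multiple sequence alignment
#'
#' Supports FASTA and relaxed sequential PHYLIP (name token terminated by
#' whitespace, no 10-character limit; sequences may wrap over lines). Rows
#' are returned in file order; duplicate names or unequal row lengths are
#' format errors.
#'
#' @param path file path.
#' @param format `"fasta"` or `"phylip"`.
#' @return a `DNAbin` matrix.
#' @export
read_alignment <- function(path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (!file.exists(path)) .stop_fmt("alignment file not found: %s", path)
  if (format == "fasta") {
    seqs <- ape::read.FASTA(path)
    if (length(seqs) == 0L) .stop_fmt("no sequences in %s", path)
    lens <- lengths(seqs)
    if (length(unique(lens)) > 1L)
      .stop_fmt("unequal row lengths in %s: %s", path,
                paste(unique(lens), collapse = ", "))
    if (anyDuplicated(names(seqs)))
      .stop_fmt("duplicate names in %s", path)
    return(as_alignment(as.matrix(seqs)))
  }
  .read_phylip(path)
}

# Relaxed sequential PHYLIP: header "n L", then per isolate a name token
# followed by sequence characters until L have been collected.
.read_phylip <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[nzchar(trimws(txt))]
  if (length(txt) < 1L) .stop_fmt("empty PHYLIP file: %s", path)
  hdr <- suppressWarnings(as.integer(strsplit(trimws(txt[1L]), "\\s+")[[1L]]))
  if (length(hdr) < 2L || anyNA(hdr[1:2]))
    .stop_fmt("malformed PHYLIP header in %s: '%s'", path, txt[1L])
  n <- hdr[1L]; L <- hdr[2L]
  toks <- unlist(strsplit(trimws(txt[-1L]), "\\s+"), use.names = FALSE)
  toks <- toks[nzchar(toks)]
  nms <- character(n)
  rows <- vector("list", n)
  i <- 1L
  for (k in seq_len(n)) {
    if (i > length(toks)) .stop_fmt("PHYLIP file %s truncated at record %d", path, k)
    nms[k] <- toks[i]; i <- i + 1L
    got <- character(0)
    ngot <- 0L
    while (ngot < L) {
      if (i > length(toks))
        .stop_fmt("PHYLIP record '%s' shorter than header length %d", nms[k], L)
      got <- c(got, toks[i]); ngot <- ngot + nchar(toks[i]); i <- i + 1L
    }
    if (ngot != L)
      .stop_fmt("PHYLIP record '%s' has %d characters, header says %d",
                nms[k], ngot, L)
    rows[[k]] <- paste(got, collapse = "")
  }
  if (i <= length(toks))
    .stop_fmt("PHYLIP file %s has trailing data beyond %d records", path, n)
  if (anyDuplicated(nms)) .stop_fmt("duplicate names in %s", path)
  names(rows) <- nms
  as_alignment(unlist(rows))
}

#' Write an alignment
#' @param x an alignment.
#' @param path output file path.
#' @param format `"fasta"` or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(x, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  x <- as_alignment(x)
  if (format == "fasta") {
    ape::write.FASTA(x, path)
  } else {
    m <- alignment_matrix(x)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%d %d", nrow(m), ncol(m)), con)
    writeLines(paste(rownames(m), apply(m, 1L, paste, collapse = "")), con)
  }
  invisible(path)
}

#' Indices of variable alignment columns
#'
#' A column is variable when it contains at least two distinct unambiguous
#' bases among A, C, G, T; ambiguity codes and gaps never make a column
#' variable. The count of these columns is the quantity d_S that drives
#' identity-column trimming and the beta cap.
#'
#' @param x an alignment.
#' @param chunk number of matrix cells per processing block (memory bound).
#' @return integer vector of column indices.
#' @export
variable_columns <- function(x, chunk = 4e6) {
  x <- as_alignment(x)
  n <- nrow(x); L <- ncol(x)
  if (L == 0L) return(integer(0))
  step <- max(1L, as.integer(chunk) %/% max(1L, n))
  raw <- unclass(x)
  out <- vector("list", ceiling(L / step))
  b <- 0L
  for (s in seq.int(1L, L, by = step)) {
    e <- min(L, s + step - 1L)
    blk <- raw[, s:e, drop = FALSE]
    nd <- integer(e - s + 1L)
    for (cd in .ACGT_CODES) nd <- nd + (colSums(blk == cd) > 0L)
    b <- b + 1L
    out[[b]] <- which(nd >= 2L) + s - 1L
  }
  unlist(out, use.names = FALSE) %||% integer(0)
}

#' Number of variable columns (d_S)
#' @param x an alignment.
#' @return integer count.
#' @export
n_variable_columns <- function(x) length(variable_columns(x))

#' Read a Newick tree
#'
#' Wraps the ape parser with an explicit bracket-balance check so malformed
#' input reports the offending character position.
#'
#' @param path file path, or a literal Newick string via `text`.
#' @param text optional Newick string (overrides `path`).
#' @return an object of class `phylo`.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(path) || !file.exists(path))
      .stop_fmt("tree file not found: %s", path %||% "<NULL>")
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  chars <- strsplit(text, "")[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      .stop_fmt("Newick parse error: unmatched ')' at position %d", i)
  }
  if (depth != 0L)
    .stop_fmt("Newick parse error: %d unclosed '(' at end of input", depth)
  if (!grepl(";", text, fixed = TRUE))
    .stop_fmt("Newick parse error: missing terminating ';' at position %d",
              nchar(text))
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) .stop_fmt("Newick parse error in '%s'", substr(text, 1, 60))
  tr
}

#' Write a tree in Newick format
#'
#' Branch lengths are serialized with 12 significant digits so a read/write
#' round trip preserves them to well below 1e-9 relative error. Internal
#' node labels (e.g. support values) are preserved.
#'
#' @param tree a `phylo` object.
#' @param path output file path; `NULL` returns the Newick string.
#' @return the Newick string, invisibly when writing to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(tree$edge.length) &&
      any(!is.finite(tree$edge.length) | tree$edge.length < 0))
    .stop_fmt("tree has missing or negative branch lengths")
  ntip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  fmt <- function(x) sprintf("%.12g", x)
  rec <- function(node, edge_idx) {
    if (node <= ntip) {
      lab <- tree$tip.label[node]
    } else {
      sub <- vapply(kids[[as.character(node)]], function(e)
        rec(tree$edge[e, 2L], e), character(1))
      nl <- ""
      if (!is.null(tree$node.label)) {
        v <- tree$node.label[node - ntip]
        if (!is.na(v)) nl <- v
      }
      lab <- paste0("(", paste(sub, collapse = ","), ")", nl)
    }
    if (!is.na(edge_idx) && !is.null(tree$edge.length))
      lab <- paste0(lab, ":", fmt(tree$edge.length[edge_idx]))
    lab
  }
  root <- ntip + 1L
  txt <- paste0(rec(root, NA_integer_), ";")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
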