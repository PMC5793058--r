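#' All-pairs percent-identity matrix
#'
#' Global-alignment identity for every sequence pair, computed once per pair
#' and mirrored (symmetric by construction, diagonal 100).
#'
#' @param proteins Named list (or list with identifiable elements) of
#'   [protein_candidate()] / [seq_record()] objects, or a named character
#'   vector; ids must be unique.
#' @param params [align_params()].
#' @return Symmetric numeric matrix of percentages with sequence ids as
#'   dimnames.
#' @export
identity_matrix <- function(proteins, params = align_params()) {
  if (is.character(proteins)) {
    seqs <- as.list(proteins)
    ids <- names(proteins)
  } else {
    seqs <- lapply(proteins, as_residues)
    ids <- names(proteins)
    if (is.null(ids)) ids <- vapply(proteins, seq_label, character(1))
  }
  if (length(seqs) < 2L)
    cx_stop("coralox_contract_error", "need at least 2 sequences")
  if (anyDuplicated(ids))
    cx_stop("coralox_contract_error", "duplicate sequence ids")
  n <- length(seqs)
  m <- diag(100, n)
  dimnames(m) <- list(ids, ids)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      aln <- global_align(seqs[[i]], seqs[[j]], params)
      m[i, j] <- m[j, i] <- aln$identity_pct
    }
  }
  m
}

validate_identity_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    cx_stop("coralox_contract_error", "identity matrix must be square")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    cx_stop("coralox_contract_error", "identity matrix needs unique labels")
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    cx_stop("coralox_contract_error", "identity matrix must be symmetric")
  if (any(m < -1e-8) || any(m > 100 + 1e-8))
    cx_stop("coralox_contract_error", "identities must lie in [0, 100]")
  invisible(m)
}

#' Write / read a PHYLIP-like square identity matrix
#'
#' @param m Identity matrix.
#' @param path Output TSV path.
#' @return `path` invisibly ([write_identity_matrix()]); a validated matrix
#'   ([read_identity_matrix()]).
#' @export
write_identity_matrix <- function(m, path) {
  validate_identity_matrix(m)
  df <- data.frame(label = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_identity_matrix
#' @export
read_identity_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  validate_identity_matrix(m)
  m
}

#' Neighbor-joining tree from an identity matrix
#'
#' Distances are `100 - identity`; the tree is the standard neighbor-joining
#' topology (Q-criterion). Negative branch lengths, which NJ can produce on
#' non-additive matrices, are clamped to zero and noted in the
#' `"clamped_edges"` attribute.
#'
#' @param matrix Symmetric percent-identity matrix with unique labels.
#' @return An unrooted `ape::phylo` tree with branch lengths on the
#'   `100 - identity` distance scale.
#' @export
nj_tree <- function(matrix) {
  validate_identity_matrix(matrix)
  if (nrow(matrix) < 3L)
    cx_stop("coralox_contract_error", "neighbor joining needs >= 3 labels")
  d <- stats::as.dist(100 - matrix)
  tree <- ape::nj(d)
  clamped <- sum(tree$edge.length < 0)
  if (clamped > 0) tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "clamped_edges") <- clamped
  tree
}

#' Newick serialisation
#'
#' Thin wrappers with input validation: [write_newick()] serialises a tree
#' (branch lengths kept to at least 6 decimals), [read_newick()] parses a
#' Newick string or file and reports unbalanced parentheses with the
#' offending character position.
#'
#' @param tree An `ape::phylo` object.
#' @param path Optional output path; when `NULL` the Newick string is
#'   returned.
#' @param digits Significant digits for branch lengths.
#' @return Newick string (invisibly when written to `path`).
#' @export
write_newick <- function(tree, path = NULL, digits = 10L) {
  stopifnot(inherits(tree, "phylo"))
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' @rdname write_newick
#' @param x Newick string, or path to a file containing one.
#' @export
read_newick <- function(x) {
  text <- if (file.exists(x) && !grepl("[();]", basename(x))) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else x
  depth <- 0L
  cs <- chars(text)
  for (i in seq_along(cs)) {
    if (cs[i] == "(") depth <- depth + 1L
    if (cs[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        cx_stop("coralox_parse_error",
                sprintf("unbalanced ')' at position %d", i))
    }
  }
  if (depth != 0L)
    cx_stop("coralox_parse_error",
            sprintf("%d unclosed '(' at end of string", depth))
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree))
    cx_stop("coralox_parse_error", "not a parseable Newick string")
  tree
}
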