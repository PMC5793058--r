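#' Conserved LOX motif table
#'
#' The default motif set used to recognise lipoxygenase catalytic domains:
#' `WLLAK` (the hard anchor used for trimming partial sequences), `YRDD` and
#' `HAAVN` (supporting conserved motifs), and the C-terminal motif. Coral
#' literature spells the C-terminal motif both `PNGTAI` and `PNSIAI`; both are
#' shipped as accepted terminal patterns and reports surface which one
#' matched.
#'
#' @param wllak_mismatch Allowed mismatches for the WLLAK anchor (default 0;
#'   it is the hard presence filter).
#' @param support_mismatch Allowed mismatches for YRDD/HAAVN/C-terminal
#'   motifs (default 1).
#' @param cterm_patterns Accepted C-terminal motif spellings.
#' @return Data frame with columns `name`, `pattern`, `max_mismatch`, `role`.
#' @export
motif_table <- function(wllak_mismatch = 0L, support_mismatch = 1L,
                        cterm_patterns = c("PNGTAI", "PNSIAI")) {
  defs <- rbind(
    data.frame(name = "WLLAK", pattern = "WLLAK",
               max_mismatch = as.integer(wllak_mismatch), role = "anchor",
               stringsAsFactors = FALSE),
    data.frame(name = "YRDD", pattern = "YRDD",
               max_mismatch = as.integer(support_mismatch), role = "support",
               stringsAsFactors = FALSE),
    data.frame(name = "HAAVN", pattern = "HAAVN",
               max_mismatch = as.integer(support_mismatch), role = "support",
               stringsAsFactors = FALSE),
    data.frame(name = "CTERM", pattern = cterm_patterns,
               max_mismatch = as.integer(support_mismatch), role = "terminal",
               stringsAsFactors = FALSE)
  )
  validate_motif_table(defs)
  defs
}

validate_motif_table <- function(defs) {
  stopifnot(is.data.frame(defs),
            all(c("name", "pattern", "max_mismatch", "role") %in% names(defs)))
  if (any(nchar(defs$pattern) < 4L))
    cx_stop("coralox_config_error", "motif patterns must be >= 4 aa")
  if (any(defs$max_mismatch >= nchar(defs$pattern)))
    cx_stop("coralox_config_error", "max_mismatch must be < pattern length")
  invisible(defs)
}

#' Read a motif table from TSV
#'
#' Columns `name`, `pattern`, `max_mismatch`, `role` (tab-separated, header
#' row required).
#'
#' @param path TSV file path.
#' @return Validated motif table data frame.
#' @export
read_motif_table <- function(path) {
  defs <- utils::read.delim(path, stringsAsFactors = FALSE)
  defs$pattern <- toupper(defs$pattern)
  validate_motif_table(defs)
  defs
}

#' Scan a protein for conserved motifs
#'
#' Reports every window whose Hamming distance to a motif pattern is within
#' that motif's `max_mismatch` (no indels), sorted by start position.
#'
#' @param protein A [protein_candidate()], [seq_record()] or string.
#' @param defs Motif table (see [motif_table()]).
#' @return Data frame with columns `motif`, `pattern`, `start`, `end`,
#'   `observed`, `n_mismatch` (0 rows when nothing matches).
#' @export
scan_motifs <- function(protein, defs = motif_table()) {
  res <- as_residues(protein)
  if (!nzchar(res))
    cx_stop("coralox_type_error", "empty protein sequence")
  validate_motif_table(defs)
  subject <- Biostrings::AAString(res)
  hits <- lapply(seq_len(nrow(defs)), function(k) {
    pat <- defs$pattern[k]
    if (nchar(pat) > nchar(res)) return(NULL)
    m <- Biostrings::matchPattern(pat, subject,
                                  max.mismatch = defs$max_mismatch[k],
                                  with.indels = FALSE)
    if (!length(m)) return(NULL)
    starts <- IRanges::start(m)
    observed <- substring(res, starts, starts + nchar(pat) - 1L)
    nm <- vapply(observed, function(o)
      sum(chars(o) != chars(pat)), integer(1), USE.NAMES = FALSE)
    data.frame(motif = defs$name[k], pattern = pat, start = starts,
               end = starts + nchar(pat) - 1L, observed = observed,
               n_mismatch = nm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(motif = character(), pattern = character(),
                      start = integer(), end = integer(),
                      observed = character(), n_mismatch = integer(),
                      stringsAsFactors = FALSE)
  out <- out[order(out$start, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Trim a partial LOX to its WLLAK-to-C-terminus core
#'
#' Partial lipoxygenase sequences are trimmed from the conserved WLLAK motif
#' to the end of the sequence before identity/tree analyses. When several
#' WLLAK hits exist the rightmost exact hit is used (the catalytic-domain
#' motif lies in the final third of a full-length sequence), falling back to
#' the rightmost inexact hit.
#'
#' @param protein A [protein_candidate()], [seq_record()] or string.
#' @param defs Motif table; only its WLLAK (anchor) rows are used.
#' @param warn_window Expected core-length window, `c(min, max)`; cores
#'   outside it trigger a warning, never an error.
#' @return An object of class `core_region`: list with `parent_id`, `span`
#'   (1-based inclusive), `residues`, `length`.
#' @export
trim_core <- function(protein, defs = motif_table(), warn_window = c(280L, 400L)) {
  res <- as_residues(protein)
  anchor <- defs[defs$role == "anchor", , drop = FALSE]
  hits <- scan_motifs(res, anchor)
  if (!nrow(hits)) {
    near <- best_near_miss(res, anchor$pattern[1])
    cx_stop("coralox_trim_error",
            sprintf("no %s hit; best near-miss '%s' at %d (%d mismatches)",
                    anchor$pattern[1], near$observed, near$start, near$n_mismatch),
            near_miss = near)
  }
  exact <- hits[hits$n_mismatch == 0L, , drop = FALSE]
  pick <- if (nrow(exact)) exact[which.max(exact$start), ]
          else hits[which.max(hits$start), ]
  span <- c(pick$start, nchar(res))
  core <- substr(res, span[1], span[2])
  len <- span[2] - span[1] + 1L
  if (len < warn_window[1] || len > warn_window[2])
    warning(sprintf("core of '%s' is %d aa, outside the expected %d-%d window",
                    seq_label(protein), len, warn_window[1], warn_window[2]),
            call. = FALSE)
  structure(list(parent_id = seq_label(protein), span = span,
                 residues = core, length = len),
            class = "core_region")
}

#' @export
print.core_region <- function(x, ...) {
  cat(sprintf("<core_region> %s  span %d-%d (%d aa)\n",
              x$parent_id, x$span[1], x$span[2], x$length))
  invisible(x)
}

# closest window to `pattern` anywhere in `res` (diagnostics for trim errors)
best_near_miss <- function(res, pattern) {
  p <- chars(pattern)
  n <- nchar(res)
  w <- length(p)
  if (n < w) return(list(observed = res, start = 1L, n_mismatch = w))
  r <- chars(res)
  mism <- vapply(seq_len(n - w + 1L), function(i)
    sum(r[i:(i + w - 1L)] != p), integer(1))
  i <- which.min(mism)
  list(observed = substr(res, i, i + w - 1L), start = i,
       n_mismatch = mism[i])
}

#' Test for the lipoxygenase sequence signature
#'
#' A sequence carries the LOX signature when (1) a WLLAK anchor hit exists,
#' (2) a terminal-role motif matches within the final `cterm_window` residues,
#' and (3) the final residue belongs to `terminal_set` (Ile/Thr are the
#' common coral C-terminal residues; Ser is a known single exception).
#'
#' @param protein A [protein_candidate()], [seq_record()] or string.
#' @param defs Motif table.
#' @param terminal_set Allowed final residues (default `c("I","T","S")`).
#' @param cterm_window Terminal-motif search window from the C-terminus.
#' @return List with `signature` (logical) and `evidence` (character vector
#'   naming each passed/failed requirement), plus the underlying `hits`.
#' @export
has_lox_signature <- function(protein, defs = motif_table(),
                              terminal_set = c("I", "T", "S"),
                              cterm_window = 15L) {
  res <- as_residues(protein)
  hits <- scan_motifs(res, defs)
  L <- nchar(res)
  evidence <- character()

  wllak <- hits[hits$motif == "WLLAK", , drop = FALSE]
  ok_wllak <- nrow(wllak) > 0L
  evidence <- c(evidence, if (ok_wllak)
    sprintf("WLLAK hit at %d", max(wllak$start)) else "no WLLAK hit")

  cterm <- hits[hits$motif == "CTERM" & hits$end > L - cterm_window, , drop = FALSE]
  ok_cterm <- nrow(cterm) > 0L
  evidence <- c(evidence, if (ok_cterm)
    sprintf("C-terminal motif %s at %d", cterm$observed[nrow(cterm)],
            cterm$start[nrow(cterm)])
    else sprintf("no C-terminal motif within the final %d residues", cterm_window))

  last <- substr(res, L, L)
  ok_last <- last %in% terminal_set
  evidence <- c(evidence, if (ok_last)
    sprintf("terminal residue %s allowed", last)
    else sprintf("terminal residue %s not in {%s}", last,
                 paste(terminal_set, collapse = ",")))

  list(signature = ok_wllak && ok_cterm && ok_last,
       evidence = evidence, hits = hits)
}
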