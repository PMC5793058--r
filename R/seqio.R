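#' Construct a sequence record
#'
#' Lightweight container for an input sequence with provenance. Records are
#' what [read_fasta()] and [read_genbank()] return and what [to_protein()]
#' consumes.
#'
#' @param id Accession or contig identifier (first whitespace-delimited token
#'   of a FASTA header, or `accession.version` for GenBank records).
#' @param residues Uppercase residue string (IUPAC alphabet).
#' @param moltype `"nucleotide"`, `"protein"`, or `"auto"` to infer from the
#'   residue alphabet.
#' @param organism Optional organism name.
#' @param description Free-text description.
#' @param cds_features Optional data frame with columns `start`, `end`,
#'   `strand` (1-based inclusive spans; only valid for nucleotide records).
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, residues, moltype = "auto", organism = NULL,
                       description = "", cds_features = NULL) {
  stopifnot(is_string(id), is_string(residues))
  residues <- toupper(residues)
  if (!nzchar(residues))
    cx_stop("coralox_format_error", sprintf("record '%s': empty sequence", id))
  letters_used <- unique(chars(residues))
  moltype <- match.arg(moltype, c("auto", "nucleotide", "protein"))
  if (moltype == "auto") {
    moltype <- if (all(letters_used %in% NT_ALPHABET)) "nucleotide" else "protein"
  }
  allowed <- if (moltype == "nucleotide") NT_ALPHABET else AA_ALPHABET_EXT
  bad <- setdiff(letters_used, allowed)
  if (length(bad))
    cx_stop("coralox_format_error",
            sprintf("record '%s': illegal %s characters: %s",
                    id, moltype, paste(bad, collapse = ", ")))
  if (!is.null(cds_features)) {
    if (moltype != "nucleotide")
      cx_stop("coralox_format_error",
              sprintf("record '%s': cds_features on a protein record", id))
    stopifnot(is.data.frame(cds_features),
              all(c("start", "end", "strand") %in% names(cds_features)))
    if (any(cds_features$start < 1L) || any(cds_features$end > nchar(residues)) ||
        any(cds_features$start > cds_features$end))
      cx_stop("coralox_format_error",
              sprintf("record '%s': CDS span outside sequence", id))
  }
  structure(
    list(id = id, organism = organism, moltype = moltype, residues = residues,
         description = description, cds_features = cds_features),
    class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s  %s, %d %s\n", x$id, x$moltype,
              nchar(x$residues),
              if (x$moltype == "nucleotide") "nt" else "aa"))
  invisible(x)
}

#' Construct a protein candidate
#'
#' A translated (or as-is) protein sequence derived from a [seq_record()],
#' carrying its provenance: `annotated_cds` (translated from a GenBank CDS
#' feature), `longest_orf` (six-frame longest open reading frame), or `as_is`
#' (the parent record was already protein).
#'
#' @param parent_id Identifier of the parent record.
#' @param residues Amino-acid string; internal stop symbols are not allowed.
#' @param provenance One of `"annotated_cds"`, `"longest_orf"`, `"as_is"`.
#' @param frame Reading frame in `-3..-1, 0, 1..3` (0 for `as_is` and
#'   annotated translations).
#' @param parent_span Optional 1-based inclusive nucleotide span on the parent.
#' @return An object of class `protein_candidate`.
#' @export
protein_candidate <- function(parent_id, residues,
                              provenance = c("as_is", "annotated_cds", "longest_orf"),
                              frame = 0L, parent_span = NULL) {
  provenance <- match.arg(provenance)
  residues <- toupper(residues)
  if (grepl("*", residues, fixed = TRUE))
    cx_stop("coralox_format_error",
            sprintf("candidate from '%s': internal stop symbol", parent_id))
  stopifnot(frame %in% -3:3)
  structure(
    list(parent_id = parent_id, residues = residues, provenance = provenance,
         frame = as.integer(frame), parent_span = parent_span),
    class = "protein_candidate")
}

#' @export
print.protein_candidate <- function(x, ...) {
  cat(sprintf("<protein_candidate> %s  %d aa (%s%s)\n", x$parent_id,
              nchar(x$residues), x$provenance,
              if (x$frame != 0L) sprintf(", frame %+d", x$frame) else ""))
  invisible(x)
}

#' Read a FASTA file
#'
#' @param path Path to a (multi-record, arbitrarily wrapped) FASTA file.
#' @param moltype Passed to [seq_record()]; default `"auto"`.
#' @return List of [seq_record()] objects.
#' @export
read_fasta <- function(path, moltype = "auto") {
  if (!file.exists(path))
    cx_stop("coralox_io_error", sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank))
    cx_stop("coralox_format_error", sprintf("%s: empty file", path))
  first <- nonblank[1L]
  if (!startsWith(lines[first], ">"))
    cx_stop("coralox_format_error",
            sprintf("%s: line %d: expected '>' header, got '%s'",
                    path, first, substr(lines[first], 1, 20)))
  headers <- which(startsWith(lines, ">"))
  bounds <- c(headers, length(lines) + 1L)
  records <- vector("list", length(headers))
  for (k in seq_along(headers)) {
    h <- headers[k]
    header <- sub("^>", "", lines[h])
    id <- strsplit(trimws(header), "\\s+")[[1]][1]
    if (is.na(id) || !nzchar(id))
      cx_stop("coralox_format_error",
              sprintf("%s: line %d: malformed header (no id)", path, h))
    body <- if (h + 1L > bounds[k + 1L] - 1L) character()
            else lines[seq.int(h + 1L, bounds[k + 1L] - 1L)]
    body <- gsub("\\s", "", body)
    seq <- paste(body, collapse = "")
    if (!nzchar(seq))
      cx_stop("coralox_format_error",
              sprintf("%s: line %d: record '%s' has no sequence lines",
                      path, h, id))
    rec <- tryCatch(
      seq_record(id, seq, moltype = moltype,
                 description = trimws(sub("^\\S+\\s*", "", trimws(header)))),
      coralox_format_error = function(e)
        cx_stop("coralox_format_error",
                sprintf("%s: line %d: %s", path, h, conditionMessage(e))))
    records[[k]] <- rec
  }
  records
}

#' Write sequences as FASTA
#'
#' @param x List of [seq_record()] / [protein_candidate()] objects, or a named
#'   character vector of sequences.
#' @param path Output file path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (is.character(x)) {
    ids <- names(x)
    seqs <- unname(x)
  } else {
    ids <- vapply(x, seq_label, character(1))
    seqs <- vapply(x, function(r)
      if (inherits(r, "seq_record")) r$residues else as_residues(r), character(1))
  }
  stopifnot(length(ids) == length(seqs), !anyNA(ids))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(ids)) {
    writeLines(paste0(">", ids[k]), con)
    s <- seqs[k]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a GenBank flat file
#'
#' Minimal parser for GenBank/GenPept flat files: extracts the LOCUS moltype,
#' ACCESSION.VERSION id, ORGANISM, CDS feature spans and the ORIGIN sequence.
#' Joined-span and complement CDS locations are supported.
#'
#' @param path Path to a GenBank flat file (may contain several records
#'   separated by `//`).
#' @return List of [seq_record()] objects.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path))
    cx_stop("coralox_io_error", sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(startsWith(lines, "LOCUS")))
    cx_stop("coralox_format_error", sprintf("%s: not a GenBank flat file", path))
  ends <- which(trimws(lines) == "//")
  if (!length(ends))
    cx_stop("coralox_format_error",
            sprintf("%s: truncated file (no record terminator '//')", path))
  starts <- c(1L, head(ends, -1L) + 1L)
  mapply(function(s, e) parse_genbank_record(lines[s:e], path),
         starts, ends, SIMPLIFY = FALSE)
}

parse_genbank_record <- function(lines, path) {
  locus <- grep("^LOCUS", lines, value = TRUE)[1]
  if (is.na(locus))
    cx_stop("coralox_format_error", sprintf("%s: record without LOCUS line", path))
  is_aa <- grepl("\\baa\\b", locus)
  version <- grep("^VERSION", lines, value = TRUE)
  id <- if (length(version)) strsplit(trimws(sub("^VERSION", "", version[1])),
                                      "\\s+")[[1]][1]
        else strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1]][1]
  org_line <- grep("^\\s+ORGANISM", lines, value = TRUE)
  organism <- if (length(org_line)) trimws(sub("^\\s+ORGANISM", "", org_line[1])) else NULL
  def <- grep("^DEFINITION", lines, value = TRUE)
  description <- if (length(def)) trimws(sub("^DEFINITION", "", def[1])) else ""

  origin <- grep("^ORIGIN", lines)
  if (!length(origin))
    cx_stop("coralox_format_error",
            sprintf("%s: record '%s' has no ORIGIN block", path, id))
  seq_lines <- lines[seq.int(origin[1] + 1L, length(lines))]
  seq_lines <- seq_lines[!startsWith(trimws(seq_lines), "//")]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(seq))
    cx_stop("coralox_format_error",
            sprintf("%s: record '%s' has an empty ORIGIN block", path, id))

  cds <- NULL
  if (!is_aa) {
    feat <- grep("^\\s{5}CDS\\s", lines)
    if (length(feat)) {
      spans <- do.call(rbind, lapply(feat, function(i) {
        loc <- trimws(sub("^\\s{5}CDS\\s+", "", lines[i]))
        j <- i + 1L
        while (j <= length(lines) && grepl("^\\s{21}[^/]", lines[j]) &&
               !grepl("^\\s{5}\\S", lines[j])) {
          loc <- paste0(loc, trimws(lines[j])); j <- j + 1L
        }
        strand <- if (grepl("complement", loc)) "-" else "+"
        nums <- as.integer(unlist(regmatches(loc, gregexpr("[0-9]+", loc))))
        if (length(nums) < 2L) return(NULL)
        data.frame(start = min(nums), end = max(nums), strand = strand,
                   stringsAsFactors = FALSE)
      }))
      cds <- spans
    }
  }
  seq_record(id, seq, moltype = if (is_aa) "protein" else "nucleotide",
             organism = organism, description = description,
             cds_features = cds)
}

#' Translate a record to protein candidates
#'
#' Protein records pass through unchanged (`as_is`). Nucleotide records with
#' CDS annotation are translated with the standard genetic code (terminal stop
#' stripped, ambiguous codons as `X`). Unannotated nucleotide records are
#' scanned for the longest start-to-stop open reading frame across all six
#' frames; frame order `+1, +2, +3, -1, -2, -3` breaks length ties (earliest
#' start within a frame).
#'
#' @param record A [seq_record()].
#' @param min_aa Minimum ORF length in amino acids for the longest-ORF policy
#'   (default 100); shorter ORFs yield an empty list.
#' @return List of [protein_candidate()] objects (length 0 or 1 under the
#'   default policies).
#' @export
to_protein <- function(record, min_aa = 100L) {
  stopifnot(inherits(record, "seq_record"))
  if (record$moltype == "protein") {
    return(list(protein_candidate(record$id, record$residues, "as_is")))
  }
  if (!is.null(record$cds_features) && nrow(record$cds_features)) {
    out <- lapply(seq_len(nrow(record$cds_features)), function(k) {
      f <- record$cds_features[k, ]
      nt <- substr(record$residues, f$start, f$end)
      dna <- Biostrings::DNAString(gsub("U", "T", nt))
      if (f$strand == "-") dna <- Biostrings::reverseComplement(dna)
      len <- length(dna) - length(dna) %% 3L
      aa <- as.character(Biostrings::translate(
        Biostrings::subseq(dna, 1L, len), if.fuzzy.codon = "solve"))
      aa <- sub("\\*$", "", aa)
      protein_candidate(record$id, aa, "annotated_cds",
                        parent_span = c(f$start, f$end))
    })
    return(out)
  }
  orf <- longest_orf(record$residues, min_aa = min_aa)
  if (is.null(orf)) return(list())
  list(protein_candidate(record$id, orf$protein, "longest_orf",
                         frame = orf$frame, parent_span = orf$span))
}

# Longest start-to-stop ORF over six frames. Returns NULL if none >= min_aa.
longest_orf <- function(nt, min_aa = 100L) {
  nt <- gsub("U", "T", toupper(nt))
  L <- nchar(nt)
  fwd <- Biostrings::DNAString(nt)
  rev <- Biostrings::reverseComplement(fwd)
  best <- NULL
  for (frame in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    strand_seq <- if (frame > 0L) fwd else rev
    off <- abs(frame) - 1L
    flen <- length(strand_seq) - off
    flen <- flen - flen %% 3L
    if (flen < 3L) next
    aa <- chars(as.character(Biostrings::translate(
      Biostrings::subseq(strand_seq, off + 1L, off + flen),
      if.fuzzy.codon = "solve", no.init.codon = TRUE)))
    starts <- which(aa == "M")
    stops <- which(aa == "*")
    for (s in starts) {
      nxt <- stops[stops > s]
      if (!length(nxt)) next
      e <- nxt[1L] - 1L            # last coding residue
      len <- e - s + 1L
      if (len < min_aa) next
      if (is.null(best) || len > best$len) {
        # nt span of the coding region on the original (+) sequence
        nt_start <- off + 3L * (s - 1L) + 1L
        nt_end <- off + 3L * e
        span <- if (frame > 0L) c(nt_start, nt_end)
                else c(L - nt_end + 1L, L - nt_start + 1L)
        best <- list(protein = paste(aa[s:e], collapse = ""),
                     frame = frame, span = span, len = len)
      }
    }
  }
  best
}

#' Extract a domain slice from a protein
#'
#' 1-based inclusive slicing, e.g. the AOS domain (aa 1-373) and the LOX
#' domain (aa 374-1066) of a coral AOS-LOX fusion protein.
#'
#' @param protein A [protein_candidate()], [seq_record()] or string.
#' @param start,end 1-based inclusive bounds.
#' @return Amino-acid string of length `end - start + 1`.
#' @export
extract_domain <- function(protein, start, end) {
  res <- as_residues(protein)
  L <- nchar(res)
  if (!(start >= 1L && start <= end && end <= L))
    cx_stop("coralox_bounds_error",
            sprintf("span (%d, %d) outside sequence of length %d", start, end, L))
  substr(res, start, end)
}
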