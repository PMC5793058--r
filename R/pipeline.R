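CAVEAT <- paste("sequence-based prediction only: stereospecificity is",
                "Coffa-predicted and positional specificity is not claimed;",
                "catalytic activity requires biochemical confirmation")

#' Annotate a sequence panel end to end
#'
#' Reads sequences, translates nucleotide candidates, evaluates motif and
#' residue evidence and classifies every candidate. One report row per input
#' candidate, in input order; a malformed individual sequence yields a
#' row-level `error` status and never aborts the run. Every report carries a
#' `caveat` column stating that all verdicts are sequence-based predictions.
#'
#' @param input Path to a FASTA/GenBank file, or a list of [seq_record()] /
#'   [protein_candidate()] objects.
#' @param references List with `lox` (required), `aos`, `cox` (see
#'   [classify_sequence()]).
#' @param rules Residue rule table.
#' @param config [classify_config()].
#' @param params [align_params()].
#' @param motifs Motif table.
#' @param min_aa Minimum ORF length for translation.
#' @return List of class `annotate_run`: `report` (data frame),
#'   `classifications` (list), `log` (character vector of stage counts).
#' @export
run_annotate <- function(input, references, rules = residue_rules(),
                         config = classify_config(), params = align_params(),
                         motifs = motif_table(), min_aa = 100L) {
  records <- load_records(input)
  if (!length(records))
    cx_stop("coralox_io_error", "no sequences in input")
  log <- sprintf("candidates in: %d", length(records))

  candidates <- list()
  for (rec in records) {
    if (inherits(rec, "protein_candidate")) {
      candidates <- c(candidates, list(rec))
    } else {
      candidates <- c(candidates, to_protein(rec, min_aa = min_aa))
    }
  }
  log <- c(log, sprintf("translated candidates: %d", length(candidates)))

  rows <- vector("list", length(candidates))
  classifications <- vector("list", length(candidates))
  for (k in seq_along(candidates)) {
    p <- candidates[[k]]
    cl <- tryCatch(
      classify_sequence(p, references, rules, config, params, motifs),
      coralox_error = function(e) e)
    if (inherits(cl, "condition")) {
      rows[[k]] <- data.frame(
        id = p$parent_id, architecture = "error", completeness = NA_character_,
        stereospecificity = NA_character_, predicted_active = NA,
        failed_rules = "", notes = conditionMessage(cl), caveat = CAVEAT,
        stringsAsFactors = FALSE)
      next
    }
    classifications[[k]] <- cl
    failed <- if (!is.null(cl$lox_checks)) {
      bad <- cl$lox_checks[cl$lox_checks$status != "match", , drop = FALSE]
      paste(sprintf("%s@%d:%s", bad$role, bad$ref_pos, bad$status),
            collapse = ";")
    } else ""
    rows[[k]] <- data.frame(
      id = cl$seq_id, architecture = cl$architecture,
      completeness = cl$completeness,
      stereospecificity = cl$stereospecificity,
      predicted_active = cl$predicted_active, failed_rules = failed,
      notes = paste(cl$notes, collapse = "; "), caveat = CAVEAT,
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  log <- c(log,
           sprintf("signature-positive: %d",
                   sum(report$architecture %in% c("LOX", "AOS_LOX_fusion"))),
           sprintf("classified %s: %d",
                   c("AOS_LOX_fusion", "LOX", "COX_like", "non_dioxygenase"),
                   vapply(c("AOS_LOX_fusion", "LOX", "COX_like",
                            "non_dioxygenase"),
                          function(a) sum(report$architecture == a),
                          integer(1))))
  structure(list(report = report, classifications = classifications,
                 log = log),
            class = "annotate_run")
}

load_records <- function(input) {
  if (is.character(input) && length(input) == 1L) {
    if (!file.exists(input))
      cx_stop("coralox_io_error", sprintf("input not found: %s", input))
    first <- readLines(input, n = 1L, warn = FALSE)
    if (length(first) && startsWith(first, "LOCUS")) read_genbank(input)
    else read_fasta(input)
  } else if (is.list(input)) input
  else cx_stop("coralox_io_error", "input must be a file path or record list")
}

#' Write an annotation report
#'
#' @param run An `annotate_run` from [run_annotate()].
#' @param tsv Path for the TSV report (one row per candidate).
#' @param json Optional path for the JSON evidence bundle (full residue
#'   checks and motif evidence).
#' @return `tsv` invisibly.
#' @export
write_report <- function(run, tsv, json = NULL) {
  utils::write.table(run$report, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json)) {
    evidence <- lapply(run$classifications, function(cl) {
      if (is.null(cl)) return(NULL)
      list(seq_id = cl$seq_id, architecture = cl$architecture,
           completeness = cl$completeness,
           stereospecificity = cl$stereospecificity,
           predicted_active = cl$predicted_active,
           lox_checks = strip_attr(cl$lox_checks),
           aos_checks = strip_attr(cl$aos_checks),
           signature_evidence = cl$signature$evidence, notes = cl$notes)
    })
    jsonlite::write_json(evidence, json, auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null")
  }
  invisible(tsv)
}

strip_attr <- function(df) {
  if (is.null(df)) return(NULL)
  attr(df, "alignment") <- NULL
  df
}

#' Identity matrix and neighbor-joining tree over a panel
#'
#' Builds the all-pairs identity matrix and NJ tree over the classified
#' LOX/AOS-LOX sequences. In `"core"` mode (the default, matching how
#' partial sequences are analysed) every sequence is first trimmed to its
#' WLLAK-to-C-terminus core; `"full"` mode aligns the untrimmed sequences.
#'
#' @param proteins Named list of proteins (strings, [seq_record()] or
#'   [protein_candidate()] objects); typically the signature-positive
#'   candidates of an annotation run.
#' @param mode `"core"` or `"full"`.
#' @param params [align_params()].
#' @param motifs Motif table for trimming.
#' @return List with `identity` (matrix) and `tree` (`ape::phylo`).
#' @export
run_tree <- function(proteins, mode = c("core", "full"),
                     params = align_params(), motifs = motif_table()) {
  mode <- match.arg(mode)
  seqs <- lapply(proteins, as_residues)
  ids <- names(proteins)
  if (is.null(ids)) ids <- vapply(proteins, seq_label, character(1))
  names(seqs) <- ids
  if (length(seqs) < 3L)
    cx_stop("coralox_contract_error",
            "need >= 3 eligible sequences for a tree")
  if (mode == "core") {
    seqs <- lapply(seqs, function(s) trim_core(s, motifs)$residues)
  }
  m <- identity_matrix(stats::setNames(unlist(seqs), ids), params)
  list(identity = m, tree = nj_tree(m))
}

#' Assign peaks and compute conversion rates per condition
#'
#' Splits the peak table by its `condition` tag (e.g. standard vs EDTA),
#' assigns every peak against the reference anchors, and computes the
#' substrate conversion rate from the radio channel of each condition. When
#' a condition has no radio peaks its conversion rate is `NA` with a note
#' that the rate is unavailable.
#'
#' @param peaks Peak data frame or CSV path (see [read_peaks()]).
#' @param refs Reference table.
#' @param rt_tol,mz_tol Assignment tolerances.
#' @param substrate Substrate metabolite name for conversion rates.
#' @return List with `assignments` (data frame over all conditions) and
#'   `conversion` (data frame: `condition`, `conversion_pct`, `note`).
#' @export
run_peaks <- function(peaks, refs = eicosanoid_refs(), rt_tol = 0.2,
                      mz_tol = 0.05, substrate = "AA") {
  if (is.character(peaks)) peaks <- read_peaks(peaks)
  peaks <- validate_peaks(peaks)
  assignments <- assign_peaks(peaks, refs, rt_tol, mz_tol)
  conv <- do.call(rbind, lapply(split(peaks, peaks$condition), function(sub) {
    has_radio <- any(sub$channel == "radio")
    data.frame(
      condition = sub$condition[1],
      conversion_pct = if (has_radio)
        conversion_rate(sub, substrate, refs, rt_tol) else NA_real_,
      note = if (has_radio) "" else "no radio channel; rate unavailable",
      stringsAsFactors = FALSE)
  }))
  rownames(conv) <- NULL
  list(assignments = assignments, conversion = conv)
}
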