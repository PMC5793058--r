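#' Alignment parameters
#'
#' Defaults follow Clustal W-era protein settings: BLOSUM62 with affine gap
#' penalties of 10 (open) and 0.5 (extend); a gap run of length L costs
#' `open + L * extend`. The percent-identity denominator is configurable:
#' `"columns"` (all alignment columns, the default) or `"shorter"` (length of
#' the shorter input), for comparison against identity ranges computed by
#' other tools.
#'
#' @param matrix Substitution matrix name (`"BLOSUM62"`, `"BLOSUM45"`,
#'   `"BLOSUM80"`, `"PAM250"`, ...) or a numeric matrix.
#' @param gap_open Gap opening penalty (> 0).
#' @param gap_extend Gap extension penalty (> 0, `<= gap_open`).
#' @param identity_denominator `"columns"` or `"shorter"`.
#' @return List of class `align_params`.
#' @export
align_params <- function(matrix = "BLOSUM62", gap_open = 10, gap_extend = 0.5,
                         identity_denominator = c("columns", "shorter")) {
  stopifnot(gap_open > 0, gap_extend > 0)
  if (gap_extend > gap_open)
    cx_stop("coralox_config_error", "gap_extend must be <= gap_open")
  structure(list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
                 identity_denominator = match.arg(identity_denominator)),
            class = "align_params")
}

substitution_matrix <- function(params) {
  if (is.matrix(params$matrix)) return(params$matrix)
  e <- new.env()
  utils::data(list = params$matrix, package = "Biostrings", envir = e)
  get(params$matrix, envir = e)
}

#' Global pairwise alignment
#'
#' Optimal global (Needleman-Wunsch) alignment with affine gap penalties,
#' deterministic traceback.
#'
#' @param a,b Protein sequences ([protein_candidate()], [seq_record()] or
#'   strings).
#' @param params [align_params()].
#' @return Object of class `pairwise_alignment`: list with `aligned_a`,
#'   `aligned_b` (equal-length gapped strings, gap `-`), `score`,
#'   `identity_pct`, `n_columns`, `n_identical`.
#' @export
global_align <- function(a, b, params = align_params()) {
  ra <- as_residues(a)
  rb <- as_residues(b)
  if (!nzchar(ra) || !nzchar(rb))
    cx_stop("coralox_type_error", "cannot align an empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(ra), Biostrings::AAString(rb),
    substitutionMatrix = substitution_matrix(params),
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    type = "global")
  ga <- as.character(Biostrings::alignedPattern(aln))
  gb <- as.character(Biostrings::alignedSubject(aln))
  ca <- chars(ga)
  cb <- chars(gb)
  ident <- sum(ca == cb & ca != "-")
  denom <- switch(params$identity_denominator,
                  columns = length(ca),
                  shorter = min(nchar(ra), nchar(rb)))
  structure(list(aligned_a = ga, aligned_b = gb,
                 score = Biostrings::score(aln),
                 identity_pct = 100 * ident / denom,
                 n_columns = length(ca), n_identical = ident,
                 n_aligned_pairs = sum(ca != "-" & cb != "-")),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> score %.1f, identity %.1f%% over %d columns\n",
              x$score, x$identity_pct, x$n_columns))
  invisible(x)
}

#' Map a reference position onto the query
#'
#' Given an alignment whose first row is the numbering reference, returns the
#' query residue index in the column carrying reference residue `ref_pos`.
#' A query gap in that column is `unaligned`; a column outside the query's
#' aligned extent (before its first or after its last residue) is
#' `truncated`.
#'
#' @param aln A `pairwise_alignment` with `aligned_a` = reference.
#' @param ref_pos 1-based position in ungapped reference numbering.
#' @return List with `status` (`"mapped"`, `"unaligned"`, `"truncated"`),
#'   `query_pos` (integer or `NA`), `query_residue` (character or `NA`).
#' @export
map_position <- function(aln, ref_pos) {
  ca <- chars(aln$aligned_a)
  cb <- chars(aln$aligned_b)
  ref_idx <- cumsum(ca != "-")
  n_ref <- ref_idx[length(ref_idx)]
  if (ref_pos < 1L || ref_pos > n_ref)
    cx_stop("coralox_bounds_error",
            sprintf("ref_pos %d outside reference of length %d", ref_pos, n_ref))
  col <- match(TRUE, ref_idx == ref_pos & ca != "-")
  q_nongap <- which(cb != "-")
  if (col < q_nongap[1] || col > q_nongap[length(q_nongap)])
    return(list(status = "truncated", query_pos = NA_integer_,
                query_residue = NA_character_))
  if (cb[col] == "-")
    return(list(status = "unaligned", query_pos = NA_integer_,
                query_residue = NA_character_))
  list(status = "mapped", query_pos = sum(cb[1:col] != "-"),
       query_residue = cb[col])
}

#' Catalytic residue rule table
#'
#' The default rules in *Gersemia fruticosa* AOS-LOX numbering: the LOX iron
#' ligands His757, His762, His943, Asn947, the catalytically required
#' C-terminal residue at 1066, and the AOS catalytic tetrad Thr66, His67,
#' Arg349, Tyr353 (AOS-domain numbering, aa 1-373 of the fusion). The Coffa
#' stereochemistry determinant position is not part of the published
#' numbering and must be supplied by the caller (`coffa_pos`).
#'
#' @param coffa_pos Reference position of the Coffa Gly/Ala determinant, or
#'   `NULL` to omit the rule.
#' @param mammalian_asn If `TRUE`, widen position 947 to the mammalian
#'   tolerance set Asn/His/Ser; the coral default is Asn only.
#' @param terminal_set Allowed residues for the C-terminal rule.
#' @return Data frame with columns `ref_pos`, `expected` (string of accepted
#'   residues), `role`, `domain`.
#' @export
residue_rules <- function(coffa_pos = NULL, mammalian_asn = FALSE,
                          terminal_set = c("I", "T", "S")) {
  rules <- data.frame(
    ref_pos = c(757L, 762L, 943L, 947L, 1066L, 66L, 67L, 349L, 353L),
    expected = c("H", "H", "H", if (mammalian_asn) "NHS" else "N",
                 paste(terminal_set, collapse = ""),
                 "T", "H", "R", "Y"),
    role = c(rep("iron_ligand", 4L), "cterm", rep("aos_catalytic", 4L)),
    domain = c(rep("LOX", 5L), rep("AOS", 4L)),
    stringsAsFactors = FALSE)
  if (!is.null(coffa_pos)) {
    stopifnot(coffa_pos >= 1L)
    rules <- rbind(rules,
                   data.frame(ref_pos = as.integer(coffa_pos), expected = "GA",
                              role = "coffa", domain = "LOX",
                              stringsAsFactors = FALSE))
  }
  validate_rule_table(rules)
  rules
}

validate_rule_table <- function(rules) {
  stopifnot(is.data.frame(rules),
            all(c("ref_pos", "expected", "role", "domain") %in% names(rules)))
  if (any(!nzchar(rules$expected)))
    cx_stop("coralox_config_error", "rule with empty expected residue set")
  if (any(rules$ref_pos < 1L))
    cx_stop("coralox_config_error", "rule ref_pos must be >= 1")
  invisible(rules)
}

#' Read a residue rule table from TSV
#'
#' Columns `ref_pos`, `expected`, `role`, `domain`.
#'
#' @param path TSV file path.
#' @return Validated rule table data frame.
#' @export
read_rule_table <- function(path) {
  rules <- utils::read.delim(path, stringsAsFactors = FALSE)
  rules$expected <- toupper(rules$expected)
  validate_rule_table(rules)
  rules
}

#' Evaluate residue rules against a numbering reference
#'
#' Aligns the query to the reference once, maps every rule position through
#' the alignment, and reads off the observed query residue. Statuses:
#' `match` (observed in the expected set), `substitution` (mapped but
#' unexpected), `unaligned` (reference position falls in a query gap),
#' `truncated` (position beyond the query's aligned extent).
#'
#' All rules passed here must be in the numbering of `reference`; callers
#' with separate LOX/AOS references invoke this once per domain.
#'
#' @param protein Query ([protein_candidate()], [seq_record()] or string).
#' @param reference Numbering reference sequence.
#' @param rules Rule table (see [residue_rules()]).
#' @param params [align_params()].
#' @return Data frame with columns `ref_pos`, `expected`, `role`, `domain`,
#'   `query_pos`, `observed`, `status`, plus the alignment as attribute
#'   `"alignment"`.
#' @export
check_rules <- function(protein, reference, rules, params = align_params()) {
  validate_rule_table(rules)
  aln <- global_align(reference, protein, params)
  out <- rules
  out$query_pos <- NA_integer_
  out$observed <- NA_character_
  out$status <- NA_character_
  for (k in seq_len(nrow(rules))) {
    m <- map_position(aln, rules$ref_pos[k])
    if (m$status != "mapped") {
      out$status[k] <- m$status
      next
    }
    out$query_pos[k] <- m$query_pos
    out$observed[k] <- m$query_residue
    expected <- chars(rules$expected[k])
    out$status[k] <- if (m$query_residue %in% expected) "match" else "substitution"
  }
  attr(out, "alignment") <- aln
  out
}

#' Predicted stereospecificity from the Coffa determinant
#'
#' Gly at the Coffa position predicts *R*-stereospecificity, Ala predicts
#' *S*; any other residue (or an unaligned/truncated position) is
#' indeterminate, since the chirality consequence of those replacements is
#' unknown.
#'
#' @param check A single row of a [check_rules()] result with
#'   `role == "coffa"`, or a character vector of observed residues.
#' @return `"R"`, `"S"`, or `"indeterminate"` (vectorised over observations).
#' @export
coffa_call <- function(check) {
  observed <- if (is.data.frame(check)) {
    stopifnot(all(check$role == "coffa"))
    check$observed
  } else as.character(check)
  out <- rep("indeterminate", length(observed))
  out[!is.na(observed) & observed == "G"] <- "R"
  out[!is.na(observed) & observed == "A"] <- "S"
  out
}

#' Predict catalytic competence from residue checks
#'
#' A LOX domain is predicted catalytically active when every iron-ligand
#' check and the C-terminal-residue check has status `match`. Any
#' substitution, unaligned position or truncation fails the prediction, with
#' the failures enumerated.
#'
#' @param checks A [check_rules()] result covering all `iron_ligand` and
#'   `cterm` rules.
#' @return List with `active` (logical) and `failures` (character vector,
#'   e.g. `"iron_ligand@757 H->K"`).
#' @export
predict_activity <- function(checks) {
  req <- checks[checks$role %in% c("iron_ligand", "cterm"), , drop = FALSE]
  if (!any(checks$role == "iron_ligand") || !any(checks$role == "cterm"))
    cx_stop("coralox_contract_error",
            "checks must cover iron_ligand and cterm rules")
  bad <- req[req$status != "match", , drop = FALSE]
  failures <- vapply(seq_len(nrow(bad)), function(k) {
    if (bad$status[k] == "substitution")
      sprintf("%s@%d %s->%s", bad$role[k], bad$ref_pos[k],
              bad$expected[k], bad$observed[k])
    else sprintf("%s@%d %s", bad$role[k], bad$ref_pos[k], bad$status[k])
  }, character(1))
  list(active = nrow(bad) == 0L, failures = failures)
}
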