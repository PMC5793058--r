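#' Classification thresholds
#'
#' @param fusion_min Minimum length (aa) for a signature-positive sequence to
#'   be considered an AOS-LOX fusion candidate (default 950; full coral
#'   fusions run ~1037-1081 aa with an 810-aa shortest outlier, standalone
#'   LOXs are far shorter).
#' @param aos_min_mappable Minimum number of the four AOS catalytic residues
#'   that must be mappable (matched or substituted, not unaligned/truncated)
#'   to call a fusion (default 3).
#' @param cox_min_identity,cox_min_overlap COX-similarity screen thresholds:
#'   global identity percentage and minimum aligned residue pairs (defaults
#'   30% over 200 pairs, the classic twilight-zone homology convention).
#' @param coverage_full Minimum fraction of the reference LOX-domain span the
#'   query alignment must cover to be called full-length (default 0.9).
#' @param lox_domain,aos_domain 1-based inclusive spans of the LOX and AOS
#'   domains in the full-length fusion reference numbering.
#' @return List of class `classify_config`.
#' @export
classify_config <- function(fusion_min = 950L, aos_min_mappable = 3L,
                            cox_min_identity = 30, cox_min_overlap = 200L,
                            coverage_full = 0.9,
                            lox_domain = c(374L, 1066L),
                            aos_domain = c(1L, 373L)) {
  structure(list(fusion_min = fusion_min, aos_min_mappable = aos_min_mappable,
                 cox_min_identity = cox_min_identity,
                 cox_min_overlap = cox_min_overlap,
                 coverage_full = coverage_full,
                 lox_domain = lox_domain, aos_domain = aos_domain),
            class = "classify_config")
}

# fraction of reference positions inside [dom_start, dom_end] aligned to a
# query residue, in an alignment with aligned_a = reference
domain_coverage <- function(aln, domain) {
  ca <- chars(aln$aligned_a)
  cb <- chars(aln$aligned_b)
  ref_idx <- cumsum(ca != "-")
  aligned <- ca != "-" & cb != "-"
  in_dom <- ref_idx >= domain[1] & ref_idx <= domain[2] & ca != "-"
  sum(aligned & in_dom) / (domain[2] - domain[1] + 1)
}

#' COX similarity screen
#'
#' Flags a sequence as cyclooxygenase-like when its global-alignment identity
#' to a supplied COX reference reaches `min_identity` percent over at least
#' `min_overlap` aligned residue pairs.
#'
#' @param protein Query sequence.
#' @param cox_reference COX reference protein (user-supplied; e.g. the
#'   *Plexaura homomalla* COX).
#' @param params [align_params()].
#' @param min_identity,min_overlap Thresholds (see [classify_config()]).
#' @return List with `is_cox` (logical), `identity_pct`, `n_aligned_pairs`.
#' @export
detect_cox <- function(protein, cox_reference, params = align_params(),
                       min_identity = 30, min_overlap = 200L) {
  if (is.null(cox_reference))
    cx_stop("coralox_config_error", "detect_cox requires a COX reference")
  aln <- global_align(cox_reference, protein, params)
  list(is_cox = aln$identity_pct >= min_identity &&
         aln$n_aligned_pairs >= min_overlap,
       identity_pct = aln$identity_pct,
       n_aligned_pairs = aln$n_aligned_pairs)
}

#' Classify a protein as LOX, AOS-LOX fusion, COX-like or non-dioxygenase
#'
#' Decision cascade: a sequence carrying the LOX signature
#' ([has_lox_signature()]) is an `AOS_LOX_fusion` when it is at least
#' `fusion_min` aa long and at least `aos_min_mappable` of the four AOS
#' catalytic residues are mappable onto the AOS-domain reference, otherwise
#' a `LOX`. Signature-negative sequences are screened against the COX
#' reference ([detect_cox()]) and fall through to `non_dioxygenase`.
#' Completeness, Coffa-predicted stereospecificity and predicted catalytic
#' competence are evaluated from the residue checks. AOS-LOX and HPL-LOX
#' fusions cannot be distinguished by these rules; both are labelled
#' `AOS_LOX_fusion` (see `notes`).
#'
#' @param protein Query ([protein_candidate()], [seq_record()] or string).
#' @param references List with elements `lox` (full-length numbering
#'   reference, required), `aos` (AOS-domain reference, optional) and `cox`
#'   (COX reference, optional).
#' @param rules Rule table in the `lox` reference numbering for
#'   `domain == "LOX"` rows and AOS-domain numbering for `domain == "AOS"`
#'   rows (see [residue_rules()]).
#' @param config [classify_config()].
#' @param params [align_params()].
#' @param motifs Motif table for the signature test.
#' @return Object of class `classification`: list with `seq_id`,
#'   `architecture`, `completeness` (`NA` for non-LOX architectures),
#'   `stereospecificity`, `predicted_active` (`NA` for non-LOX),
#'   `lox_checks`, `aos_checks`, `notes`, `signature`.
#' @export
classify_sequence <- function(protein, references, rules = residue_rules(),
                              config = classify_config(),
                              params = align_params(),
                              motifs = motif_table()) {
  if (is.null(references$lox))
    cx_stop("coralox_config_error", "references$lox (numbering reference) is required")
  res <- as_residues(protein)
  id <- seq_label(protein)
  notes <- character()
  sig <- has_lox_signature(protein, motifs)

  lox_rules <- rules[rules$domain == "LOX", , drop = FALSE]
  aos_rules <- rules[rules$domain == "AOS", , drop = FALSE]
  lox_checks <- NULL
  aos_checks <- NULL
  completeness <- NA_character_
  stereo <- "indeterminate"
  active <- NA

  if (sig$signature) {
    lox_checks <- check_rules(protein, references$lox, lox_rules, params)
    n_aos_mappable <- 0L
    if (!is.null(references$aos) && nrow(aos_rules)) {
      aos_checks <- check_rules(protein, references$aos, aos_rules, params)
      n_aos_mappable <- sum(aos_checks$status %in% c("match", "substitution"))
    }
    is_fusion <- nchar(res) >= config$fusion_min &&
      n_aos_mappable >= config$aos_min_mappable
    architecture <- if (is_fusion) "AOS_LOX_fusion" else "LOX"
    if (is_fusion)
      notes <- c(notes, "AOS-LOX and HPL-LOX fusions are not distinguishable by sequence rules")
    if (!is_fusion) aos_checks <- NULL

    aln <- attr(lox_checks, "alignment")
    coverage <- domain_coverage(aln, config$lox_domain)
    completeness <- if (!any(lox_checks$status == "truncated") &&
                        coverage >= config$coverage_full)
      "full_length" else "partial"

    coffa <- lox_checks[lox_checks$role == "coffa", , drop = FALSE]
    if (nrow(coffa)) stereo <- coffa_call(coffa)[1]

    act <- predict_activity(lox_checks)
    active <- act$active
    notes <- c(notes, act$failures)
    subs <- lox_checks[lox_checks$status == "substitution" &
                         lox_checks$role == "coffa", , drop = FALSE]
    if (nrow(subs))
      notes <- c(notes, sprintf("coffa@%d observed %s (stereochemistry unknown)",
                                subs$ref_pos, subs$observed))
    if (!is.null(aos_checks)) {
      asubs <- aos_checks[aos_checks$status == "substitution", , drop = FALSE]
      if (nrow(asubs))
        notes <- c(notes, sprintf("aos_catalytic@%d %s->%s", asubs$ref_pos,
                                  asubs$expected, asubs$observed))
    }
  } else if (!is.null(references$cox)) {
    cox <- detect_cox(protein, references$cox, params,
                      config$cox_min_identity, config$cox_min_overlap)
    architecture <- if (cox$is_cox) "COX_like" else "non_dioxygenase"
    notes <- c(notes, sprintf("COX screen: %.1f%% identity over %d pairs",
                              cox$identity_pct, cox$n_aligned_pairs))
  } else {
    architecture <- "non_dioxygenase"
    notes <- c(notes, "no COX reference supplied; COX screen skipped")
  }

  structure(list(seq_id = id, architecture = architecture,
                 completeness = completeness, stereospecificity = stereo,
                 predicted_active = active, lox_checks = lox_checks,
                 aos_checks = aos_checks, notes = notes, signature = sig),
            class = "classification")
}

#' @export
print.classification <- function(x, ...) {
  cat(sprintf("<classification> %s: %s%s, stereo %s, active %s\n",
              x$seq_id, x$architecture,
              if (!is.na(x$completeness)) paste0(" (", x$completeness, ")") else "",
              x$stereospecificity,
              ifelse(is.na(x$predicted_active), "NA", x$predicted_active)))
  invisible(x)
}

#' Single-linkage identity clustering
#'
#' Groups sequences whose pairwise identity reaches `cut` percent into
#' single-linkage clusters (connected components of the thresholded identity
#' graph) and reports each cluster's off-diagonal identity range.
#'
#' @param matrix Symmetric percent-identity matrix with dimnames (see
#'   [identity_matrix()]).
#' @param cut Identity threshold in percent.
#' @return Data frame with columns `cluster`, `label`, plus attribute
#'   `"ranges"`: per-cluster data frame of `cluster`, `n`, `min_identity`,
#'   `max_identity` (`NA` for singletons).
#' @export
group_by_identity <- function(matrix, cut) {
  validate_identity_matrix(matrix)
  n <- nrow(matrix)
  labels <- rownames(matrix)
  adj <- matrix >= cut
  # connected components by BFS
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  out <- data.frame(cluster = comp, label = labels, stringsAsFactors = FALSE)
  ranges <- do.call(rbind, lapply(seq_len(cur), function(k) {
    idx <- which(comp == k)
    vals <- matrix[idx, idx, drop = FALSE]
    off <- vals[upper.tri(vals)]
    data.frame(cluster = k, n = length(idx),
               min_identity = if (length(off)) min(off) else NA_real_,
               max_identity = if (length(off)) max(off) else NA_real_)
  }))
  attr(out, "ranges") <- ranges
  out
}
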