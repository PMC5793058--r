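#' Planted coordinate layout of the synthetic numbering reference
#'
#' The synthetic 1066-aa pseudo-reference mirrors the coral AOS-LOX fusion
#' coordinate system: AOS domain aa 1-373 with the catalytic tetrad at
#' 66/67/349/353, LOX domain aa 374-1066 with WLLAK at 737-741 (so the
#' WLLAK-to-C-terminus core is 330 aa), iron ligands at 757/762/943/947, the
#' supporting motifs YRDD and HAAVN inside the core, the C-terminal motif
#' ending at 1066, and the Coffa determinant planted at 780 - inside the
#' core, where it must lie for core-only partial sequences to carry it.
#'
#' @param coffa_pos Planted Coffa determinant position (default 780).
#' @return Named list of planted coordinates.
#' @export
reference_layout <- function(coffa_pos = 780L) {
  list(length = 1066L,
       aos_domain = c(1L, 373L), lox_domain = c(374L, 1066L),
       aos_residues = c("66" = "T", "67" = "H", "349" = "R", "353" = "Y"),
       wllak = 737L, iron = c(757L, 762L, 943L, 947L),
       iron_residues = c("757" = "H", "762" = "H", "943" = "H", "947" = "N"),
       coffa = as.integer(coffa_pos),
       yrdd = 800L, haavn = 850L,
       cterm_start = 1061L, cterm_motif = "PNGTAI")
}

#' Synthetic panel configuration
#'
#' @param seed Integer seed; identical configurations produce identical
#'   output.
#' @param n_sequences Panel size.
#' @param class_mix Named proportions over
#'   `AOS_LOX_fusion, LOX_full, LOX_partial, COX_like, decoy` (must sum
#'   to 1).
#' @param divergence Range of per-sequence substitution rates applied to
#'   non-planted positions of template copies.
#' @param coffa_mix Named sampling probabilities for the planted Coffa
#'   residue (G predicts *R*, A predicts *S*; I/F/V/L are the observed
#'   indeterminate replacements).
#' @param mutation_spec Optional data frame with columns `role`, `target`,
#'   `prob`: each rule of `role` is substituted to `target` with probability
#'   `prob` in LOX-class sequences (the generated truth records the
#'   consequences).
#' @param partial_len Length range of partial-LOX fragments; defaults to
#'   330-340 aa, i.e. the WLLAK-to-C-terminus core with up to 10 upstream
#'   residues, the retained-partial regime (shorter fragments lose the
#'   C-terminal motif and would be excluded by the presence filter itself).
#' @param coffa_pos Planted Coffa position, passed to [reference_layout()].
#' @return List of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_sequences = 200L,
                         class_mix = c(AOS_LOX_fusion = 0.30, LOX_full = 0.20,
                                       LOX_partial = 0.20, COX_like = 0.15,
                                       decoy = 0.15),
                         divergence = c(0.05, 0.25),
                         coffa_mix = c(G = 0.5, A = 0.3, I = 0.1, F = 0.05,
                                       V = 0.05),
                         mutation_spec = NULL,
                         partial_len = c(330L, 340L),
                         coffa_pos = 780L) {
  if (abs(sum(class_mix) - 1) > 1e-8)
    cx_stop("coralox_config_error", "class_mix must sum to 1")
  if (abs(sum(coffa_mix) - 1) > 1e-8)
    cx_stop("coralox_config_error", "coffa_mix must sum to 1")
  structure(list(seed = as.integer(seed), n_sequences = as.integer(n_sequences),
                 class_mix = class_mix, divergence = divergence,
                 coffa_mix = coffa_mix, mutation_spec = mutation_spec,
                 partial_len = as.integer(partial_len),
                 layout = reference_layout(coffa_pos)),
            class = "synth_config")
}

# positions carrying planted features on the full-length template
planted_positions <- function(layout) {
  sort(unique(c(
    as.integer(names(layout$aos_residues)),
    seq.int(layout$wllak, layout$wllak + 4L),
    layout$iron, layout$coffa,
    seq.int(layout$yrdd, layout$yrdd + 3L),
    seq.int(layout$haavn, layout$haavn + 4L),
    seq.int(layout$cterm_start, layout$cterm_start + nchar(layout$cterm_motif) - 1L))))
}

# remove accidental exact occurrences of `pattern` (except one at `keep`)
# by mutating an unprotected residue inside each offending window
scrub_pattern <- function(x, pattern, keep = NA_integer_, protected = integer()) {
  p <- chars(pattern)
  w <- length(p)
  repeat {
    if (length(x) < w) return(x)
    hits <- which(vapply(seq_len(length(x) - w + 1L), function(i)
      all(x[i:(i + w - 1L)] == p), logical(1)))
    hits <- setdiff(hits, keep)
    if (!length(hits)) return(x)
    for (i in hits) {
      window <- setdiff(i:(i + w - 1L), protected)
      if (!length(window)) next
      j <- window[1L]
      x[j] <- setdiff(AMINO_ACIDS, c(x[j], p[j - i + 1L]))[1L]
    }
  }
}

# build the full-length template with all layout features planted into the
# supplied background characters
plant_features <- function(bg, layout, coffa_residue = "G") {
  x <- bg
  for (pos in names(layout$aos_residues))
    x[as.integer(pos)] <- layout$aos_residues[[pos]]
  x[layout$wllak:(layout$wllak + 4L)] <- chars("WLLAK")
  for (pos in names(layout$iron_residues))
    x[as.integer(pos)] <- layout$iron_residues[[pos]]
  x[layout$coffa] <- coffa_residue
  x[layout$yrdd:(layout$yrdd + 3L)] <- chars("YRDD")
  x[layout$haavn:(layout$haavn + 4L)] <- chars("HAAVN")
  x[layout$cterm_start:(layout$cterm_start + 5L)] <- chars(layout$cterm_motif)
  prot <- planted_positions(layout)
  x <- scrub_pattern(x, "WLLAK", keep = layout$wllak, protected = prot)
  # no second C-terminal-motif-like window near the end
  x <- scrub_pattern(x, layout$cterm_motif, keep = layout$cterm_start,
                     protected = prot)
  x
}

#' Synthetic numbering reference
#'
#' A deterministic 1066-aa pseudo-reference with every layout feature
#' planted over a uniform random background: a stand-in for a real
#' full-length coral AOS-LOX numbering reference so that the pipeline is
#' testable without any database download. The sequence is synthetic; it
#' shares coordinates, not residues, with any real protein.
#'
#' @param config [synth_config()].
#' @return A [protein_candidate()] with id `pseudo_ref`.
#' @export
make_pseudo_reference <- function(config = synth_config()) {
  layout <- config$layout
  bg <- with_seed(config$seed,
                  sample(AMINO_ACIDS, layout$length, replace = TRUE))
  protein_candidate("pseudo_ref",
                    paste(plant_features(bg, layout), collapse = ""), "as_is")
}

#' Synthetic COX-like reference
#'
#' A deterministic 600-aa random protein free of the WLLAK anchor, used as
#' the similarity target for the COX screen and as the template for
#' COX-like panel decoys. Synthetic stand-in; carries no real COX residues.
#'
#' @param config [synth_config()].
#' @return A [protein_candidate()] with id `pseudo_cox`.
#' @export
make_pseudo_cox <- function(config = synth_config()) {
  x <- with_seed(config$seed + 1L, sample(AMINO_ACIDS, 600L, replace = TRUE))
  x <- scrub_pattern(x, "WLLAK")
  protein_candidate("pseudo_cox", paste(x, collapse = ""), "as_is")
}

# substitute non-protected positions of a template at the given rate
diverge <- function(x, rate, protected) {
  free <- setdiff(seq_along(x), protected)
  hit <- free[stats::runif(length(free)) < rate]
  if (length(hit)) {
    x[hit] <- vapply(x[hit], function(r)
      sample(setdiff(AMINO_ACIDS, r), 1L), character(1))
  }
  x
}

#' Generate a synthetic sequence panel with planted ground truth
#'
#' Emits `n_sequences` protein records in fixed class proportions: full
#' AOS-LOX fusions (divergent copies of the pseudo-reference), standalone
#' full-length LOXs (the LOX-domain slice), retained-style partial LOXs
#' (WLLAK-to-C-terminus fragments), COX-like sequences (divergent copies of
#' the COX pseudo-reference) and unrelated decoys. Every record is emitted
#' together with a truth row stating its architecture, completeness,
#' Coffa stereospecificity and predicted-activity ground truth, plus any
#' planted substitutions.
#'
#' @param config [synth_config()].
#' @return List with `records` (list of protein [seq_record()]s), `truth`
#'   (data frame), `reference`, `cox_reference`.
#' @export
generate_panel <- function(config = synth_config()) {
  stopifnot(config$n_sequences >= 1L)
  layout <- config$layout
  ref <- make_pseudo_reference(config)
  cox <- make_pseudo_cox(config)
  ref_chars <- chars(ref$residues)
  cox_chars <- chars(cox$residues)
  prot <- planted_positions(layout)

  counts <- largest_remainder(config$class_mix, config$n_sequences)
  classes <- rep(names(counts), counts)

  with_seed(config$seed + 2L, {
    records <- vector("list", length(classes))
    truth <- vector("list", length(classes))
    idx_in_class <- stats::setNames(rep(0L, length(counts)), names(counts))
    for (k in seq_along(classes)) {
      cls <- classes[k]
      idx_in_class[cls] <- idx_in_class[cls] + 1L
      id <- sprintf("%s_%03d", tolower(cls), idx_in_class[cls])
      rate <- stats::runif(1L, config$divergence[1], config$divergence[2])

      if (cls %in% c("AOS_LOX_fusion", "LOX_full", "LOX_partial")) {
        coffa_res <- sample(names(config$coffa_mix), 1L,
                            prob = config$coffa_mix)
        x <- ref_chars
        x[layout$coffa] <- coffa_res
        x <- diverge(x, rate, prot)
        x <- scrub_pattern(x, "WLLAK", keep = layout$wllak, protected = prot)

        subs <- character()
        active <- TRUE
        if (!is.null(config$mutation_spec)) {
          for (m in seq_len(nrow(config$mutation_spec))) {
            spec <- config$mutation_spec[m, ]
            pos_tab <- rule_positions(layout, spec$role)
            for (p in pos_tab$pos) {
              if (stats::runif(1L) < spec$prob) {
                old <- x[p]
                x[p] <- spec$target
                subs <- c(subs, sprintf("%s@%d %s->%s", spec$role, p, old,
                                        spec$target))
                if (spec$role %in% c("iron_ligand", "cterm") &&
                    !spec$target %in% chars(pos_tab$expected[pos_tab$pos == p]))
                  active <- FALSE
              }
            }
          }
        }

        span <- switch(cls,
          AOS_LOX_fusion = c(1L, layout$length),
          LOX_full = layout$lox_domain,
          LOX_partial = {
            len <- sample(seq.int(config$partial_len[1], config$partial_len[2]), 1L)
            c(layout$length - len + 1L, layout$length)
          })
        residues <- paste(x[span[1]:span[2]], collapse = "")
        # drop substitutions planted outside the emitted span
        keep_sub <- vapply(subs, function(s) {
          p <- as.integer(sub("^.*@([0-9]+) .*$", "\\1", s))
          p >= span[1] && p <= span[2]
        }, logical(1))
        subs <- subs[keep_sub]
        architecture <- if (cls == "AOS_LOX_fusion") "AOS_LOX_fusion" else "LOX"
        completeness <- if (cls == "LOX_partial") "partial" else "full_length"
        stereo <- coffa_call(coffa_res)
        truth[[k]] <- data.frame(
          seq_id = id, class = cls, architecture = architecture,
          completeness = completeness, stereospecificity = stereo,
          predicted_active = active,
          substitutions = paste(subs, collapse = ";"),
          length = nchar(residues), stringsAsFactors = FALSE)
        records[[k]] <- seq_record(id, residues, moltype = "protein")
      } else if (cls == "COX_like") {
        x <- diverge(cox_chars, min(rate, 0.2), integer())
        x <- scrub_pattern(x, "WLLAK")
        truth[[k]] <- data.frame(
          seq_id = id, class = cls, architecture = "COX_like",
          completeness = NA_character_, stereospecificity = "indeterminate",
          predicted_active = NA, substitutions = "",
          length = length(x), stringsAsFactors = FALSE)
        records[[k]] <- seq_record(id, paste(x, collapse = ""),
                                   moltype = "protein")
      } else { # decoy
        len <- sample(400:800, 1L)
        x <- sample(AMINO_ACIDS, len, replace = TRUE)
        x <- scrub_pattern(x, "WLLAK")
        truth[[k]] <- data.frame(
          seq_id = id, class = cls, architecture = "non_dioxygenase",
          completeness = NA_character_, stereospecificity = "indeterminate",
          predicted_active = NA, substitutions = "",
          length = len, stringsAsFactors = FALSE)
        records[[k]] <- seq_record(id, paste(x, collapse = ""),
                                   moltype = "protein")
      }
    }
    list(records = records, truth = do.call(rbind, truth),
         reference = ref, cox_reference = cox)
  })
}

# positions and expected sets of the layout rules belonging to a role
rule_positions <- function(layout, role) {
  switch(role,
    iron_ligand = data.frame(pos = layout$iron,
                             expected = unname(layout$iron_residues),
                             stringsAsFactors = FALSE),
    cterm = data.frame(pos = layout$length, expected = "ITS",
                       stringsAsFactors = FALSE),
    aos_catalytic = data.frame(pos = as.integer(names(layout$aos_residues)),
                               expected = unname(layout$aos_residues),
                               stringsAsFactors = FALSE),
    coffa = data.frame(pos = layout$coffa, expected = "GA",
                       stringsAsFactors = FALSE),
    cx_stop("coralox_config_error", sprintf("unknown rule role '%s'", role)))
}

largest_remainder <- function(mix, n) {
  raw <- mix * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_frac <- order(raw - base, decreasing = TRUE)
    base[order_frac[seq_len(rem)]] <- base[order_frac[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(mix))
}

#' Generate a synthetic peak table from a truth assignment
#'
#' One peak per truth row, with retention time (and m/z for MS-channel
#' peaks) jittered around the metabolite's reference anchors by centred
#' Gaussian noise.
#'
#' @param truth Data frame with columns `metabolite` and `area`.
#' @param sigma_rt,sigma_mz Noise standard deviations (minutes / m-z units).
#' @param seed Integer seed.
#' @param channel `"ms"` (rt + m/z) or `"radio"` (rt and area only).
#' @param refs Reference table; every truth metabolite must have an rt
#'   anchor, and an m/z anchor for the ms channel.
#' @param condition Condition tag carried through (e.g. `"EDTA"`).
#' @return List with `peaks` (data frame ready for [assign_peaks()]) and
#'   `truth` (input truth with the anchor values attached).
#' @export
generate_peak_table <- function(truth, sigma_rt = 0, sigma_mz = 0, seed = 1L,
                                channel = c("ms", "radio"),
                                refs = eicosanoid_refs(),
                                condition = "standard") {
  channel <- match.arg(channel)
  if (!nrow(truth)) {
    return(list(peaks = data.frame(rt = numeric(), mz = numeric(),
                                   area = numeric(), channel = character(),
                                   condition = character(),
                                   stringsAsFactors = FALSE),
                truth = truth))
  }
  idx <- match(truth$metabolite, refs$name)
  if (anyNA(idx))
    cx_stop("coralox_config_error",
            sprintf("unknown metabolite(s): %s",
                    paste(truth$metabolite[is.na(idx)], collapse = ", ")))
  rt0 <- refs$rt[idx]
  mz0 <- refs$mz[idx]
  if (anyNA(rt0))
    cx_stop("coralox_config_error",
            "every truth metabolite needs a retention-time anchor")
  if (channel == "ms" && anyNA(mz0))
    cx_stop("coralox_config_error",
            "ms-channel peaks need metabolites with m/z anchors")
  n <- nrow(truth)
  with_seed(seed, {
    rt <- rt0 + stats::rnorm(n, 0, sigma_rt)
    mz <- if (channel == "ms") mz0 + stats::rnorm(n, 0, sigma_mz) else NA_real_
    peaks <- data.frame(rt = rt, mz = mz, area = truth$area,
                        channel = channel, condition = condition,
                        stringsAsFactors = FALSE)
    truth$rt_anchor <- rt0
    truth$mz_anchor <- mz0
    list(peaks = validate_peaks(peaks), truth = truth)
  })
}
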