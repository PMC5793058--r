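---
title: "Curating coral dioxygenase sequences and annotating their eicosanoid products"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating coral dioxygenase sequences and annotating their eicosanoid products}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coralox)
```

## The problem

Corals synthesise eicosanoids — oxygenated C20 fatty-acid signals — through
two dioxygenase families: lipoxygenases (LOX) and, uniquely in corals,
natural fusion proteins coupling a catalase-related allene oxide synthase
(AOS) domain to an 8*R*-lipoxygenase domain (AOS-LOX). Transcriptome and
genome archives for stony corals contain many sequences annotated as "LOX"
or "AOS-LOX" by automated pipelines, but those labels are unreliable: many
records are partial, some lack the residues required for catalysis, and a
few are not dioxygenases at all. `coralox` implements a reproducible
curation pipeline built entirely from sequence-level evidence:

1. **Motif filter.** A candidate LOX must contain the conserved catalytic-
   domain motif **WLLAK** and a recognisable C-terminal motif (**PNGTAI**;
   the variant spelling **PNSIAI** is also accepted — see "Open choices"),
   ending in Ile, Thr or, as a single known exception, Ser.
2. **Catalytic-residue mapping.** The non-heme iron of a LOX is held by
   three histidines, an asparagine, and the carboxylate of the C-terminal
   isoleucine. In the full-length fusion numbering used here these are
   His757, His762, His943, Asn947 and Ile1066; the AOS domain has its own
   catalytic tetrad Thr66, His67, Arg349, Tyr353. Query residues are read
   off at these positions after a global pairwise alignment to a numbering
   reference.
3. **Stereochemistry.** A single position (the Coffa determinant)
   distinguishes *R*- from *S*-specific lipoxygenases: Gly predicts *R*,
   Ala predicts *S*; any other residue leaves the call indeterminate, since
   the chirality consequence of those replacements is unknown.
4. **Architecture and completeness.** Fusion proteins are recognised by
   full-protein length plus mappable AOS residues; completeness by
   truncation status of the residue checks and coverage of the LOX domain.
5. **Identity matrices and trees.** All-pairs global-alignment identity,
   with partial sequences first trimmed from WLLAK to the C-terminus (the
   ~330-aa core), followed by neighbor-joining on `100 - identity`.
6. **Eicosanoid peak annotation.** LC-MS / radiochromatogram peaks are
   matched to reference anchors by retention time and negative-mode
   [M−H]⁻ m/z, and substrate conversion rates are computed as product-area
   fractions.

Every verdict the pipeline emits is a *sequence-based prediction*. The
report carries a mandatory caveat saying so: positional specificity
(8- vs 11- vs 5-LOX) is never claimed, and stereospecificity is always
labelled Coffa-predicted.

## The decision cascade

`classify_sequence()` applies, in order:

* **Signature** (`has_lox_signature()`): a WLLAK hit, a terminal-role motif
  within the final 15 residues, and an allowed final residue
  (`{I, T, S}`).
* **Architecture**: signature-positive sequences of at least `fusion_min`
  amino acids (default **950 aa**) with at least 3 of the 4 AOS catalytic
  residues mappable are `AOS_LOX_fusion`; other signature-positive
  sequences are `LOX`. Signature-negative sequences with at least
  `cox_min_identity` percent global identity (default **30%**) over at
  least `cox_min_overlap` aligned residue pairs (default **200**) to a
  user-supplied COX reference are `COX_like`; the rest are
  `non_dioxygenase`.
* **Completeness**: `full_length` when no LOX-domain rule check is
  truncated *and* at least `coverage_full` (default **0.9**) of the
  reference LOX-domain positions (374–1066) are aligned to query residues.
  Coverage counts aligned residue pairs, not the extent between the first
  and last aligned columns: a global alignment occasionally strands a few
  fragment residues far upstream, which would otherwise inflate the extent.
  Coverage is measured against the LOX-domain span rather than the full
  fusion reference so that a standalone full-length LOX (the 693-aa
  domain equivalent) counts as full length.
* **Stereospecificity** from the Coffa check; **predicted activity** true
  only when all four iron ligands and the C-terminal residue check
  `match`.

The fusion length threshold of 950 aa sits between the longest plausible
standalone LOX (~700 aa) and the observed fusion range (mostly 1037–1081
aa, with an 810-aa truncated outlier); it is configurable, and raising it
can only demote fusions to LOX, never the reverse. AOS-LOX and HPL-LOX
fusions cannot be separated by any of these rules — the hydroperoxide-lyase
fusion is sequence-similar throughout — so both are labelled
`AOS_LOX_fusion` with a note.

## Alignment and numbering

Pairwise global alignment uses BLOSUM62 with affine gap penalties of 10
(open) and 0.5 (extend); a gap run of length L costs `open + L·extend`.
These are classic Clustal W-era protein defaults. Percent identity is, by
default, identical columns over *all* alignment columns; a
shorter-sequence denominator is selectable through
`align_params(identity_denominator = "shorter")` for comparison against
identity ranges computed by other programs, which rarely document their
formula. The COX screen uses the column denominator as well; with it, the
empirical identity of composition-preserving shuffles of a 600-aa protein
against itself sits near 20%, comfortably below the 30% screen threshold
(the classic twilight-zone convention), which the test suite verifies
empirically.

Reference-numbered positions are mapped through the alignment column that
carries the reference residue: a query gap in that column is `unaligned`, a
column outside the query's aligned extent is `truncated`, anything else
reads off the query residue directly. Whether the original analyses
evaluated residues on a multiple alignment or pairwise to the reference is
not documented; pairwise-to-reference is implemented, which suffices for
every check performed. Traceback determinism comes from the alignment
backend; scores are verified against an independent affine-gap dynamic
program, itself anchored to exhaustive enumeration of all gapped alignments
on tiny inputs.

## Trees

The original trees were produced by a commercial package's
"maximum-likelihood" setting on Clustal W alignments — an undocumented
procedure. `coralox` substitutes standard neighbor joining on
`100 − identity` distances: fully reproducible, exact on additive
matrices (property-tested: topology and branch lengths recovered to 1e-9
on random positive-length trees of 4–8 taxa, with 5-taxon cases
cross-checked against brute force over all 15 unrooted topologies).
Clade-level agreement is therefore the only claim made for tree output;
branch lengths are on the identity-distance scale and are not evolutionary
distances. Negative NJ branch lengths (possible on non-additive input) are
clamped to zero and counted in an attribute.

## Peak annotation

The reference anchor table (`eicosanoid_refs()`) holds the printed
retention times and [M−H]⁻ m/z values: AA at 19.9 min; 8-HETE at 17.2 min
/ 319.2; the trace HETE isomers 15-, 11- and 5-HETE at 16.8, 17.0 and 17.4
min (all 319.2); α-ketol 335.2 and cyclopentenone 317.2 (no printed
retention times); PGF2α 6.9 min / 353.2; PGE2 8.5 min / 351.2; PGD2 351.2
with no printed retention time. Default tolerances are **rt_tol = 0.2
min** and **mz_tol = 0.05**: the retention-time tolerance preserves the
0.2-min HETE isomer ladder, and the m/z tolerance reflects anchors printed
to one decimal. Matching gates each field only when both peak and
reference carry it, prefers candidates matched on more fields, and flags
ties — and m/z-only matches at an m/z shared by several references (the
PGE2/PGD2 pair at 351.2) — as ambiguous rather than forcing a choice.

The **conversion rate** is defined as the product-area fraction of the
radiochromatogram: `100 × (area outside the substrate window) / (total
area)`. The alternative reading (fraction of substrate consumed) is not
distinguishable from printed data; the product-area definition reproduces
the published worked values (53%, 60%, and 0% for unconverted samples)
and is invariant under uniform scaling of areas.

## The synthetic generator

Real coral transcriptome records cannot be bundled, so the test bed is a
seeded generator (`synth_config()`, `generate_panel()`) that plants every
feature the pipeline exploits at known coordinates in a 1066-aa
pseudo-reference: the AOS tetrad at 66/67/349/353, WLLAK at 737–741 (so
the WLLAK-to-C-terminus core is 330 aa, matching the reported ~318–330-aa
core window), iron ligands at 757/762/943/947, YRDD and HAAVN inside the
core, PNGTAI ending at 1066, and the Coffa determinant at **780**. The
Coffa position is not part of any published numbering; 780 places it
inside the trimmed core, where it must lie for core-only partial sequences
to carry a stereochemistry call, as the curated partial sequences do. For
real data the Coffa position is a mandatory configuration value
(`residue_rules(coffa_pos = ...)`) with no shipped biological default.

Panel classes and their defaults:

* `AOS_LOX_fusion` (30%): full-length divergent copies of the reference.
* `LOX_full` (20%): the 693-aa LOX-domain slice.
* `LOX_partial` (20%): WLLAK-to-C-terminus fragments of 330–340 aa —
  the *retained-partial* regime. Fragments shorter than the core lose the
  C-terminal motif and would be excluded by the motif filter itself, so
  emitting them would only exercise the reject path; that path is covered
  separately by decoys.
* `COX_like` (15%): divergent copies of a synthetic COX stand-in.
* `decoy` (15%): unrelated random proteins.

Divergent copies substitute 5–25% of non-planted positions (uniform
random background, no indels). Uniform residue composition is deliberate:
planted motifs dominate detection, so composition realism adds nothing the
tests would notice. Accidental WLLAK or C-terminal-motif copies created by
the background or by divergence are scrubbed so planted truth stays exact.
What the generator does **not** emulate: realistic substitution processes,
indels, frameshifts, compositional bias, and genuinely homologous COX
sequences. Passing the closed-loop tests therefore demonstrates that the
decision rules are implemented exactly as specified — not that they are
robust to every artefact of real transcriptome assemblies.

The peak-table generator jitters anchors with centred Gaussian noise. The
Monte-Carlo robustness claim (≥ 99% recovery at σ_rt = 0.05 min,
σ_mz = 0.01 over 1000 seeded draws) is made for the main-product panel
(8-HETE, PGF2α, PGE2 against the well-separated anchors): with anchors at
least 1.3 min or 2.0 m/z units apart, the failure probability per peak is
below 1e-4. The trace HETE isomers, 0.2 min apart, are *by construction*
not separable at that noise level by retention time alone — their original
identification relied on daughter-ion spectra that are not part of the
printed anchor set — so they are excluded from the recovery claim, and
m/z-only or near-boundary matches surface as alternatives/ambiguity flags
instead.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere, matching residue-numbering
  conventions ("His757").
* Translation uses the standard genetic code only; frame scanning
  disables initiator-codon special-casing (a frame-initial CTG is Leu, not
  Met), while annotated CDS translation keeps the default initiator
  handling. Longest-ORF ties break by frame order +1, +2, +3, −1, −2, −3,
  then earliest start; the minimum ORF length defaults to 100 aa.
* Multiple WLLAK hits: the rightmost exact hit wins (the catalytic-domain
  motif lies in the final third of the protein), falling back to the
  rightmost inexact hit; a failed trim carries the best near-miss for
  diagnostics.
* Mismatch budgets: 0 for WLLAK (it is the hard filter), 1 for
  YRDD/HAAVN and the C-terminal motif. Core lengths outside 280–400 aa
  warn but never filter.
* Empty sequences, zero-area radiochromatograms, sub-3-taxon trees, and
  non-symmetric matrices raise classed errors (`coralox_*_error`) rather
  than returning sentinel values; one failing sequence in a panel run is
  reported as a row-level error without aborting the run.

## Open choices

* **PNGTAI vs PNSIAI**: the literature spells the C-terminal motif both
  ways. Both patterns ship as accepted terminal motifs; reports name
  whichever matched rather than resolving the discrepancy.
* **Identity denominator**: all columns by default, configurable, because
  the identity formula behind published ranges is undocumented.
* **Conversion-rate definition**: product-area fraction (see above).
* **Clusters** (`group_by_identity()`): published "groups" were read off
  trees by eye; single-linkage components at an identity cut are the
  formalisation used here.

## Problem sizes

The shipped tests run the generator at 200 sequences (closed-loop
recovery), 500 random pairs for the alignment oracle, 200 random trees for
NJ exactness, and 1000 seeded draws for peak-assignment robustness; the
committed 20-sequence fixture panel exercises the end-to-end report
byte-for-byte. These sizes were chosen to estimate each rate tightly while
keeping a full test run around a minute of alignment work.

## Worked example

```{r example}
cfg <- synth_config(seed = 7, n_sequences = 12)
panel <- generate_panel(cfg)
refs <- list(
  lox = panel$reference,
  aos = protein_candidate("aos_ref",
                          extract_domain(panel$reference, 1, 373), "as_is"),
  cox = panel$cox_reference)
run <- run_annotate(panel$records, refs, residue_rules(coffa_pos = 780))
table(run$report$architecture)

res <- run_peaks(data.frame(rt = c(17.2, 19.9), mz = NA_real_,
                            area = c(53, 47), channel = "radio"))
res$conversion
```

## Limitations

Sequence-level curation can never confirm catalysis: the report's caveat
field is load-bearing. The COX screen needs a user-supplied COX reference
and reports only similarity, not orthology. Trees are identity-distance
NJ, suitable for clade membership questions only. Peak assignment uses
printed anchors, not spectral libraries; isomers co-eluting within the
retention-time tolerance can only be flagged, not resolved.
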