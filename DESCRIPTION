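Package: coralox
Title: Curation of Coral Lipoxygenase and AOS-LOX Fusion Sequences and
    Eicosanoid Peak Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Motif- and catalytic-residue-based identification and
    classification of coral lipoxygenase (LOX), allene oxide
    synthase-lipoxygenase fusion (AOS-LOX), and cyclooxygenase-like
    sequences. Detects the conserved LOX motifs (WLLAK, YRDD, HAAVN and
    the C-terminal motif), maps reference-numbered catalytic positions
    (iron ligands, the AOS catalytic tetrad, the Coffa stereochemistry
    determinant) onto query sequences by global pairwise alignment,
    classifies architecture, completeness, predicted stereospecificity
    and catalytic competence, builds all-pairs percent-identity matrices
    and neighbor-joining trees, and annotates LC-MS eicosanoid peak
    tables by retention time and m/z against reference anchors,
    including substrate conversion rates from radiochromatogram peak
    areas. A seeded synthetic-data generator with planted ground truth
    makes the whole pipeline testable without any database download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    phangorn,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
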