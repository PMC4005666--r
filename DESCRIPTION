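Package: kjunction
Title: Geometric Search and Annotation of Kink-Turn and k-Junction Motifs in RNA Structures
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Detects kink-turn (k-turn) and k-junction architecture in RNA
    coordinate files by geometric pattern matching. Watson-Crick and G-U wobble
    base pairs are identified from atomic coordinates, stacked two-pair helix
    segments are abstracted to orthonormal coordinate frames (origin, helix
    axis, Watson-Crick hydrogen-bond direction and their normal), and pairs of
    segments are scored against reference relative transforms describing the
    tight kink between the canonical (C) and non-canonical (NC) helices of
    known k-turns. Matched motifs can be annotated with the standard k-turn
    nomenclature (-1b/-1n, L1-L3, 1b/1n, 2b/2n, ...), canonical cross-strand
    hydrogen bonds measured, the N1/N3 class assigned, and role-wise backbone
    superpositions computed. Also included: a one-site isothermal titration
    calorimetry simulator and fitter with thermodynamic audits, per-column and
    joint conservation statistics for structure-guided alignments, and a
    synthetic A-form duplex/scene generator so the whole pipeline is testable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    minpack.lm,
    Biostrings,
    withr,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
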