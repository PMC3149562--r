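Package: yinyang
Title: Phosphorylation/O-GlcNAc Interplay Site Mapping for Linker Histones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Proposes candidate "Yin-Yang" sites -- Ser/Thr residues where
    phosphorylation and O-beta-GlcNAc modification can alternately occupy the
    same hydroxyl -- on protein sequences, with human linker histone H1
    subtypes as the motivating system. Provides consensus-motif scanning for
    the proline-directed kinase motifs (S/T)PXK and (S/T)PXZ, per-column
    conservation classification from multiple sequence alignments with
    by-similarity evidence transfer, a sliding-window one-hot neural scorer
    for phosphorylation and O-GlcNAc potential (or import of external
    predictor score tables), a rule-based interplay caller producing
    Yin-Yang / false-negative Yin-Yang site reports, a synthetic ortholog
    family generator with planted motifs and correlated dual-modification
    ground truth for end-to-end validation, and a pipeline orchestrating all
    stages with a thin command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    nnet,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
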