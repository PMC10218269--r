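Package: neuromethylome
Title: Methylome Maturation Analysis for Stem-Cell-Derived Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for whole-genome bisulfite sequencing of
    stem-cell-derived neurons maturing in culture versus in vivo neurons.
    Computes per-context (CG, CA, CC, CT, pooled CH) weighted methylation
    levels with spike-in based bisulfite nonconversion correction, aggregates
    them over genes, genomic feature classes, metagene profiles and 100 kb
    bins, scores in vitro/in vivo differences (hyper/hypomethylated gene
    fractions, cross-context correlation, Spearman correlation clustering),
    ranks genes by a neuron-similarity score and runs a from-scratch
    preranked gene set enrichment analysis with permutation NES, filters
    candidate differentially methylated regions with coverage, density and
    effect-size rules and computes genomic-feature and developmental-DMR
    enrichment, and integrates gene-body non-CG methylation with expression
    (sliding-window anticorrelation, enhancer deltas, transcription-factor
    panel). Ships a seeded synthetic methylome generator emulating the study
    design (ESC, NPC, in vitro and in vivo neurons, glia, fetal cortex at
    around 30x coverage with an unmethylated spike-in) so the whole pipeline
    is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
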