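Package: clonoreact
Title: Clonotype-Level Identification of Neuron-Reactive CD8+ T Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for identifying neuron-reactive CD8+ T cell
    clonotypes from coupled bulk and single-cell T-cell receptor (TCR)
    repertoire data. Computes TCR-beta repertoire diversity (Shannon entropy
    and 1-Pielou clonality), calls clonotype expansion across a
    PBMC-neuron coculture timecourse with pseudo-frequency handling for
    clonotypes undetected ex vivo, links bulk clonotypes to single-cell
    expression clusters via CDR3-beta amino-acid identity, selects candidate
    clonotypes by cluster residency, classifies NFAT-reporter luminescence
    readouts into HLA-dependent neuron-reactivity calls, and performs
    cell-level Wilcoxon differential expression with Benjamini-Hochberg
    correction plus pseudobulk per-million summaries. A synthetic-data
    generator with planted ground truth exercises every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
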