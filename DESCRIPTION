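Package: proteoshape
Title: Transcriptome-Proteome Time-Course Integration with Shape-Based Distance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integration of label-free-quantification (LFQ) proteome and FPKM
    transcriptome time courses from nitrogen-starvation experiments in
    oleaginous microalgae. Provides Perseus-style preprocessing (log2
    transform, minimum-quantification filtering, down-shifted normal
    imputation, replicate-mean log2 fold changes, per-timepoint Welch tests
    with Benjamini-Hochberg control), hierarchical phase/cluster structure
    discovery of fold-change profiles, a shape-based distance (SBD) engine
    built on coefficient-normalized cross-correlation with quartile-based
    transcript-protein concordance classes, full k-shape iterative-refinement
    clustering, per-cluster functional-category summaries, majority-consensus
    subcellular localization, and a synthetic-data generator emulating
    delayed paired trajectories and intensity-dependent missingness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
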