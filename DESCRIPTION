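Package: ripeomics
Title: Integrative Transcriptome-Proteome Analysis of Fruit Ripening Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for paired bulk RNA-seq and TMT-style
    quantitative proteomics time courses, built around a non-climacteric fruit
    ripening design (four stages, three replicates). Provides median-of-ratios
    count normalization, FPKM computation and expressed-gene filtering,
    per-contrast differential expression (genes) and differential abundance
    (proteins) calling, two-tailed Fisher over-representation with
    Benjamini-Hochberg correction and enrichment-matrix clustering, fuzzy
    c-means temporal clustering, Ward hierarchical co-clustering, mRNA-protein
    correlation analysis at the stage and gene level, correlation-ranked gene
    set enrichment analysis (GSEA) with a permutation null, and a paired
    multi-omics simulator with planted temporal templates, pathway structure,
    and a stage-decaying mRNA-protein coupling schedule so every downstream
    method has a ground-truth recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
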