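Package: m5Cforest
Title: Random-Forest Ensemble Prediction and Annotation of RNA 5-Methylcytosine Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting RNA 5-methylcytosine (m5C) modification sites
    from flanking sequence. Builds labeled training sets from bisulfite-derived
    per-cytosine counts (proportion statistic with pseudo-counts, FDR filtering,
    GC-matched negative sampling), encodes fixed-width RNA windows with binary,
    k-mer and pseudo dinucleotide composition (PseDNC) schemes, trains an
    ensemble of ten random forests on balanced negative subsets with averaged
    scoring and specificity-anchored confidence thresholds, optimizes window
    geometry and feature count by information gain and cross-validated AUC,
    and annotates transcriptomes with sequence context, mRNA region and
    start-codon distance for every scored cytosine. Includes a synthetic
    transcriptome generator with plantable G-enriched flanking signal so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    ranger
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Epitranscriptomics, MachineLearning, Classification, Sequencing
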