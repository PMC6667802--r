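Package: methylStates
Title: Methylome-State Segmentation and Promoter Hypermethylation Analysis
    for Whole-Genome Bisulfite Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments per-CpG whole-genome bisulfite sequencing (WGBS)
    methylation signal into ordered methylome states using change-point
    detection with exact one-dimensional clustering, calls unmethylated and
    low-methylated regions (UMRs/LMRs) with false-discovery-rate calibration
    against randomized methylomes, labels partially methylated domains with
    a two-state hidden Markov model, and classifies gene promoters as
    hypermethylated from the resulting segment classes and regions.
    Aggregates promoter calls to gene-set hypermethylation percentages,
    methylation heatmap matrices, and TSS-proximal per-CpG profiles.
    Includes a synthetic bisulfite-methylome generator with planted ground
    truth for end-to-end validation, readers and writers for Bismark-style
    cytosine reports and coverage files, and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Epigenetics, DNAMethylation, Sequencing, HiddenMarkovModel
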