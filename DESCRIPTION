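Package: ocscore
Title: Cell-Free DNA Fragmentomic Scoring for Ovarian Cancer Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome-scale plasma cell-free DNA (cfDNA) scoring pipeline for
    liquid-biopsy detection of ovarian cancer. Computes four fragmentomic
    feature families from aligned fragment coordinates: 5'-end 4-mer motif
    frequencies, per-megabase short/long fragmentation ratios, nucleosome
    footprint scores at transcription start sites, and copy-number z-scores
    against a healthy baseline panel. Features pass through a Wilcoxon /
    LASSO selection cascade into per-family support vector machine scorers,
    which are integrated by a logistic stacking model and combined with the
    copy-number burden into a single "OC score". A synthetic cfDNA cohort
    simulator with a machine-readable truth set makes every stage testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    data.table,
    e1071,
    glmnet,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
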