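Package: endkit
Title: Discrete RNA 5'-End Feature Calling and Small-RNA Cleavage Site
    Detection from Paired 5P/BODY Sequencing Libraries
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies discrete capped and noncapped RNA 5'-end features
    from paired 5'-end (5P) and gene-body (BODY) sequencing libraries by
    subtractive Laplace kernel density estimation, classifies features as
    capped or noncapped from upstream-untemplated-guanosine (uuG)
    frequencies, projects cap-masked 5'-end signal into transcript
    coordinates, and detects small-RNA-guided cleavage sites with an
    empirical-null statistic built from shuffled small RNA cohorts.
    Includes multimapping-read rescue, k-mer bias correction, a
    low-complexity read filter, and a synthetic-data generator with known
    ground truth for closed-loop validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    rtracklayer,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Transcriptomics, Sequencing, GeneRegulation, Coverage
RoxygenNote: 7.3.3
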