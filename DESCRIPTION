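Package: promsig
Title: Promoter Chromatin-Signature Discovery from Pol-II and H3K4me2 ChIP-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns common promoter profile shapes of RNA polymerase II and
    H3K4me2 ChIP-seq coverage around annotated transcription start sites by
    k-means clustering with correlation distance, models each shape as a finite
    mixture of two double-exponential (Laplace) components and a uniform
    component fitted by Kullback-Leibler minimization with a generalized
    pattern search, and scans a genome for regions matching the fitted
    signatures. Called regions are thresholded against a permutation null
    distribution and annotated hierarchically against promoter, transcript and
    regulatory interval catalogs. Includes a seeded synthetic-data generator
    producing coverage tracks with planted signatures for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    jsonlite,
    lhs,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    Rsamtools,
    GenomicAlignments,
    optparse,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
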