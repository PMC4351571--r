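Package: clichunter
Title: Detection of Co-Localized Insertion Clusters from Hi-C and
    Insertional Mutagenesis Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects 3D hotspots of recurrent retroviral insertions by
    integrating insertional mutagenesis screens with Hi-C chromatin
    contact maps. Implements rank-based distance normalization of
    intra-chromosomal contact maps, chromatin compartment tracks from
    the first principal component of the contact correlation matrix,
    insertion-cluster calling by Gaussian kernel convolution, detection
    of co-localized insertion clusters (CLICs) against a
    distance-matched null with Holm family-wise error control, and
    downstream statistics: mutual exclusion of insertions
    (Mean-Manhattan distance), gene-set enrichment, transcription
    factor binding site carrier calling, and insertion-expression
    association scores. Includes a synthetic-data generator producing
    contact maps with power-law distance decay and plaid compartment
    structure, insertion cohorts with planted clusters, and expression
    matrices with planted cis- and trans-acting effects, so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
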