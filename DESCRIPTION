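Package: apsitemap
Title: Single-Nucleotide Mapping of Abasic Sites from Tailing-Based Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Converts paired-end reads from a 3'OH tailing-based abasic-site
    sequencing protocol into single-nucleotide abasic (AP) site calls, with
    spike-in quality control, global abundance metrics, single-nucleotide
    hotspot catalogs with permutation null models, and interval enrichment
    statistics (odds ratios with exact binomial tests). Includes an in-silico
    simulator of the molecular protocol (tagged read structure, planted
    lesions, unblocked 3'OH background, PCR duplicates, spike-in amplicons)
    so the whole pipeline can be exercised and validated without external
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
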