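Package: cnvminer
Title: Error-Tolerant Subspace Pattern Mining of Copy-Number Variation Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers copy-number variation (CNV) regions shared by arbitrary
    sample subsets in probe-by-sample SNP-array matrices. Continuous
    log-intensity-ratio matrices are binarized at a threshold (gain and loss
    separately), then a level-wise, error-tolerant frequent-itemset search
    constrained to runs of consecutive probes reports maximal frequent
    intervals together with their supporting sample subsets. Includes
    brute-force reference oracles for testing, a synthetic cohort generator
    with implanted aberrations and known ground truth, per-pattern
    group-specificity chi-squared tests, genomic region mapping, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
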