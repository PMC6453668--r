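Package: targetedCNV
Title: Targeted Copy-Number Genotyping from SNP Array BAF and LRR Signals
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Locus-targeted genotyping of a known copy-number variant (CNV)
    from SNP-array B-allele frequency (BAF) and log R ratio (LRR) signals.
    Copy number 1, 2 or 3 is called at a known interval by combining Welch
    t-tests of LRR inside the CNV breakpoints against flanking windows with
    a fit-ratio statistic against the expected BAF cluster positions of each
    copy-number state. Includes a synthetic signal simulator with known
    ground truth, case-control carrier association statistics (odds ratios
    with Woolf confidence intervals, chi-square tests, subgroup
    heterogeneity, Mantel-Haenszel combination across strata), Monte-Carlo
    replication power, and three-panel BAF/LRR/cumulative-LRR review plots.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
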