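Package: bxdeqtl
Title: Expression QTL Mapping with Probe-Level Artifact Correction for
    Recombinant Inbred Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for systems-genetics analysis of transcript abundance in
    biallelic recombinant-inbred (RI) panels such as the BXD family. The
    package simulates RI genotypes (Haldane map function with the sib-mated
    RI map expansion) and probe-level expression panels with planted cis and
    trans eQTLs, region-specific 3' UTR effects, module structure and
    SNP-overlap hybridization artifacts; removes variant-contaminated probes
    and reconstructs probe-set values from the first principal component;
    estimates broad-sense heritability from strain replicates; performs
    single-marker likelihood-ratio-statistic (LRS) scans with permutation
    thresholds, LOD conversion, allele direction and the 10-Mb cis/trans
    classification rule; builds signed coexpression networks with
    probe-set collapsing and module eigengenes; and prioritizes candidate
    regulators inside trans-eQTL intervals by marker-controlled partial
    correlation with cross-species support.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
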