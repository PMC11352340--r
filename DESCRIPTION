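Package: oligosig
Title: Private Oligogenic Germline Signatures from Discordant Sib-Pair
    Exome and Transcriptome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes rare deleterious germline variants private to
    affected members of phenotypically discordant sibling pairs, compares
    blood and tumor exomes to extract somatic mutations and detect loss of
    heterozygosity at candidate loci, and integrates tumor/normal/control
    FPKM expression profiles to classify each candidate variant as a
    second hit (tumor downregulation), a likely oncogene (tumor
    upregulation), or transcript instability (downregulation in both
    tissues), yielding a per-patient predisposing signature report.
    Includes gene-set over-representation and interaction-network
    connectivity analyses for candidate genes, a synthetic sib-pair cohort
    simulator with planted ground truth for validation, and a packaged
    worked example of a four-pair never-smoker lung cancer cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    igraph,
    vcfR,
    withr,
    fgsea,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
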