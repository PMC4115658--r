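Package: imprintomics
Title: Imprinted Gene and Differentially Methylated Region Calling from
    Reciprocal Crosses
Version: 0.1.0
Authors@R:
    person("Imprintomics", "Developers", email = "imprintomics@example.org",
           role = c("aut", "cre"))
Description: Calls maternally and paternally expressed imprinted genes
    (MEGs/PEGs) from allele-specific read counts of reciprocal crosses
    between inbred plant strains, using a dosage-aware Fisher exact test
    against the 2:1 endosperm null, an imprinting-factor filter, a
    seed-coat expression filter and maternal-fraction cutoff rules.
    Detects strain-dependent (allele-specific) imprinting via a parental
    bias factor on the reciprocal ratio plane. Calls differentially
    methylated regions (DMRs) from per-cytosine bisulfite counts in
    sliding windows with context-specific thresholds, scores merged DMRs
    across a population of strains and classifies their methylation
    variability into five classes. Includes SNP-based read
    strain-of-origin classification, SNP list derivation and filtering,
    and a synthetic-data generator with planted truth so the whole
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
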