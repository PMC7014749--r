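Package: irdprio
Title: Variant Prioritization for Inherited Retinal Dystrophy Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tertiary analysis of whole-genome sequencing data for families
    with inherited retinal dystrophy (IRD). Implements a five-step variant
    filtering cascade (ClinVar phenotype rescue, pseudo-control recurrence,
    population frequency, gene-panel and pedigree filters), region
    classification against exon models with splice-predictor thresholding,
    compound-heterozygote pairing with trio-based cis/trans phase inference,
    and extended-pedigree segregation verdicts. Ships a deterministic cohort
    simulator with planted causal and decoy variants for end-to-end
    validation, and a worked fixture reconstructing a large pseudo-dominant
    retinitis pigmentosa family resolved by compound heterozygosity in USH2A.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    jsonlite,
    yaml,
    withr,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
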