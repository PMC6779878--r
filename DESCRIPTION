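Package: rhucscreen
Title: Recessive Variant Filtering and Founder-Panel Screening for Renal Hypouricemia
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the genetic diagnosis of renal hypouricemia
    (RHUC) from annotated exome variant calls: case ascertainment by a serum
    uric-acid threshold, a four-step variant-filtering cascade under an
    autosomal- or X-linked-recessive model (allele frequency, in-house
    homozygote, consequence class, bi-allelic requirement), two-variant
    founder-panel classification of SLC22A12 (URAT1) genotypes with
    diagnostic-yield and prevalence statistics, ortholog conservation
    profiling of candidate missense variants, and a synthetic cohort
    generator with a genotype truth table so every stage is testable
    without access to human data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    optparse,
    VariantAnnotation,
    S4Vectors
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
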