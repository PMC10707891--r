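Package: mutmapr
Title: MutMap+ Bulked-Segregant SNP-Index Filtering and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for isolating causal EMS-induced mutations from bulked
    segregant sequencing of selfed progeny (MutMap+/QTL-seq style). Computes
    per-bulk SNP/Indel-indices from allele depths, applies the three-stage
    filtering cascade used to pinpoint recessive causal variants, reads and
    writes minimal VCF/TSV variant tables, tests Mendelian segregation
    ratios, quantifies photosynthetic pigments from absorbance readings, and
    ships a forward-genetic simulator (heterozygous parent selfing with
    Haldane recombination, phenotype bulking, Poisson-binomial read
    sampling) together with Monte-Carlo power evaluation of the cascade.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
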