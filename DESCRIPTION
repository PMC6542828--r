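Package: g2pfilter
Title: Panel-Driven Diagnostic Filtering of Annotated Genomic Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genotype-aware prioritisation of plausibly causative variants
    from VEP-annotated multi-sample VCFs using curated gene panels that pair
    each gene-disease association with an allelic requirement (for example
    monoallelic or biallelic) and a mutation consequence mechanism.
    Implements panel readers for G2P-style CSV downloads and PanelApp
    exports, VEP CSQ annotation parsing, genotype- and sample-level quality
    control, the core filtering engine with compound-heterozygote aware
    genotype aggregation, case:control background-noise statistics (carrier
    burden odds ratios, per-gene proportions, CADD enrichment), a
    sensitivity/precision evaluation framework with MAF-sweep ROC and
    precision-recall points, and a deterministic synthetic cohort generator
    for end-to-end testing without access to managed clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
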