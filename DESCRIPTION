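Package: regvar
Title: Fine-Mapping and Allele-Specific Functional Assay Statistics for
    Regulatory Risk Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical workflows for characterising an allele-specific
    regulatory variant in a GWAS risk region: single-SNP and conditional
    case-control association by the logistic score test, linkage
    disequilibrium (r2, D') from phased haplotypes or EM on unphased
    genotypes, variant quality-control filtering, calling of
    allele-preferential DNA-binding proteins from label-swap quantitative
    proteomics pulldowns by a concordant interquartile-range outlier rule,
    delta-delta-Ct relative expression, allelic-discrimination expression
    ratios with genomic copy-number adjustment, per-allele knockdown
    contrasts, an exact Fisher siRNA-specificity test, ChIP-qPCR percent
    input enrichment, dual-luciferase reporter normalisation, and relative
    telomere length from telomere/single-copy-gene qPCR. Includes seeded
    synthetic-data generators (LD-structured haplotype pools, logistic
    case-control phenotypes, label-swap pulldown intensities, Ct tables)
    so every analysis stage is testable against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
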