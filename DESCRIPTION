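Package: gsforward
Title: Forward-Validated Genomic and Pedigree BLUP Evaluation for Breeding Programs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating genomic selection in closed breeding populations
    with discrete generations, modelled on commercial Pekin duck lines. Provides a
    gene-dropping simulator of multi-generation pedigrees, SNP genotypes and
    quantitative traits; SNP quality control (minor allele frequency and exact
    Hardy-Weinberg tests); pedigree (A) and VanRaden genomic (G) relationship
    matrices with principal component analysis of markers; fixed-effect
    pre-correction of phenotypes; a single-kernel animal model fitted by restricted
    maximum likelihood via eigendecomposition, with BLUP breeding-value prediction
    ('gblup' objects); and forward-prediction validation statistics (predictive
    correlation, accuracy, dispersion bias and standardized bias).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    methods,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    e1071,
    withr
Config/testthat/edition: 3
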