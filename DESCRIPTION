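Package: pleioscan
Title: Cross-Disorder Pleiotropy Analysis of GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for cross-trait analysis of genome-wide association
    summary statistics: harmonization of two studies against a shared
    reference panel, LD score regression estimates of SNP heritability and
    genetic correlation with block-jackknife errors, liability-scale
    conversion, a Gaussian-mixture estimator of polygenicity and
    discoverability, sample-overlap-aware weighted-Z meta-analysis with LD
    clumping into genomic risk loci, bidirectional two-sample Mendelian
    randomization with heterogeneity-based outlier removal, sign-concordance
    testing, eigenvalue-corrected gene-based association, competitive
    gene-set enrichment, and a block-LD bivariate polygenic simulator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
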