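Package: gxescan
Title: QTL-by-Environment Interaction Scans for Multi-Environment RIL Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of QTL-by-environment (GxE) interactions in
    biparental recombinant inbred line (RIL) populations phenotyped in
    multiple environments. Implements a linear mixed model comparison
    approach: per SNP, a model with a constant SNP effect is tested
    against a model with correlated per-environment random intercepts
    and SNP slopes via a likelihood-ratio test, with Benjamini-Hochberg
    FDR control across markers. Also provides variance-component
    decomposition with a Hadamard-product GxE kernel, broad-sense
    heritability, SNP-by-environment variance shares conditional on a
    fixed SNP effect, windowed weather covariate construction and fixed
    genotype-by-environmental-factor interaction tests, a VanRaden
    additive relationship matrix, marker thinning, and a single-seed
    descent RIL simulator for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
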