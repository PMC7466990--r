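Package: goosepop
Title: Population Genomics of Goose Domestication and Wild-Domestic Gene Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing genotyping-by-sequencing SNP data from wild
    graylag geese and their domestic descendants: variant and individual
    filtering with monomorphic-site accounting, per-population expected
    heterozygosity, Weir-Cockerham pairwise F_ST and hierarchical AMOVA with
    permutation tests, the three-population admixture statistic f3 with
    block-jackknife standard errors, PCA with Tracy-Widom axis significance,
    neighbor-joining trees from allele-sharing distances, and site-frequency
    spectrum based demographic inference for two-population divergence models
    with epoch-switching migration (structured coalescent simulation,
    composite-likelihood ECM fitting, Akaike-weight model selection and
    parametric bootstrap). A synthetic-data generator with known ground truth
    supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    vcfR,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
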