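Package: hairqtl
Title: Genetics of Hair Steroid Levels and Coping Behaviour in Crossbred Pigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for mapping the genetic architecture of
    stress-hormone concentrations measured in pig hair (cortisol, cortisone,
    DHEA, DHEA-S) and piglet backtest coping behaviour. Covers assay
    preprocessing (replicate summaries, concentration back-calculation,
    upper-tail IQR outlier filtering, composite traits and log ratios),
    VanRaden method-1 genomic relationship matrices combined block-diagonally
    across breeding companies, average-information REML for genomic animal
    models with common-litter and pen effects, Bayesian variable-selection
    GWAS (BayesB and BayesCpi) with 1-Mb window summaries of the percentage
    of genetic variance explained, a bivariate BayesB scan for pleiotropic
    windows via the absolute difference in posterior sign probabilities of
    0.25-Mb window covariances, lead-SNP fine-mapping arithmetic, and
    preranked gene-set enrichment of genomic windows. A synthetic two-breed
    F1 cohort generator with planted QTL makes every stage testable without
    confidential data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    jsonlite,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    vcfR,
    optparse,
    withr
Config/testthat/edition: 3
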