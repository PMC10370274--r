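Package: pleiograph
Title: Graphical Integration of Multi-Trait GWAS Summary Statistics with
    Functional Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint Bayesian analysis of genome-wide association study (GWAS)
    summary statistics for multiple phenotypes. Latent per-SNP association
    indicators are coupled across phenotypes through an auto-logistic Markov
    random field whose graph encodes genetic correlation between phenotypes,
    and binary functional annotations enter as modifiers of the per-SNP
    association propensity with spike-and-slab selection of relevant
    annotations. Inference is by Metropolis-within-Gibbs MCMC with exact
    enumeration of the MRF normalizing constant. The package estimates the
    phenotype graph, flags phenotype-relevant annotations, and produces
    FDR-controlled single-trait and pleiotropic association calls via the
    direct posterior probability approach. A simulator generates synthetic
    multi-phenotype summary statistics with known truth for calibration
    studies, and preprocessing utilities cover the p-value to z-score
    transform, annotation binarization, SNP thinning, and sample-overlap
    decorrelation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
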