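Package: adaptrate
Title: Adaptive and Non-Adaptive Protein Substitution Rates from
    Polymorphism and Divergence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimation of the adaptive (omega-a) and non-adaptive (omega-na)
    rates of nonsynonymous substitution from site frequency spectra and
    divergence counts in the McDonald-Kreitman framework, using Poisson
    maximum-likelihood fits of distribution-of-fitness-effects (DFE) models
    (Neutral, Gamma, Gamma-Exponential) compared by AIC.  Includes a codon-
    alignment site-frequency-spectrum builder with Nei-Gojobori opportunity
    counting, outgroup polarization and hypergeometric down-sampling;
    covariate annotation and categorization of genes and residues (relative
    solvent accessibility, secondary structure, intrinsic disorder, Grantham
    substitution classes, equal-count binning); bootstrap resampling with
    replicate trimming, Kendall trend tests, pairwise bootstrap tests with
    FDR correction, and sequential-sum-of-squares variance partitioning; and
    a synthetic-data generator with analytically known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
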