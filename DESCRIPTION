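Package: carotidgeom
Title: Bilateral Carotid Artery Geometry Phenotypes and Stroke Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Median-split classification of common carotid artery (CCA)
    intima-media thickness and external diameter into four per-side geometric
    patterns, reduction of right-left pattern pairs to ten non-overlapping
    bilateral phenotypes and six combined phenotype sets, right-left
    concordance statistics (Cohen's kappa, category-specific agreement),
    diagnostic-accuracy measures (sensitivity, specificity, positive and
    negative likelihood ratios with log-method confidence intervals,
    cumulative incidence, relative risk), and from-scratch Cox
    proportional-hazards estimation with Wald inference and
    change-in-estimate covariate selection. Includes a synthetic cohort
    generator with a Gaussian-copula arterial model calibrated by
    bivariate-normal orthant probabilities and exponential
    proportional-hazards event times, so the full pipeline is testable
    without restricted subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
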