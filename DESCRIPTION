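Package: noiavar
Title: Functional Genetic Effects and Bias-Corrected Variance Components
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates single-locus and pairwise-epistatic genetic effects
    from nearly-isogenic-line (NIL) and double-NIL phenotype data using the
    functional NOIA parameterization fitted by REML, and maps those effects
    to population genetic variance components (total genetic variance,
    additive genetic variance, and locus-specific average effects) as
    functions of allele frequencies under Hardy-Weinberg and linkage
    equilibrium. Because effect estimates are squared and cross-multiplied
    when variances are computed, estimation error inflates naive variance
    predictions; the package implements an estimation-error bias correction
    based on the full sampling (co)variance matrix of the effect estimates,
    and validates it by parametric bootstrap. Includes allele-frequency
    ensemble samplers (uniform and U-shaped), a study-like synthetic data
    generator, and summaries of epistatic deviations, pleiotropy
    correlations, and average-effect trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
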