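Package: eta2w
Title: Standardized Effect Sizes for Pairwise-Comparison Designs and Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes standardized effect sizes for the 2 x 2 and pairwise
    experimental designs common in behavioral research: Cohen's d, d_z and
    d_av with noncentral-t confidence intervals; eta squared and partial eta
    squared from a from-scratch repeated-measures ANOVA sum-of-squares
    decomposition; and eta squared within (the share of within-unit variance
    explained by an effect), obtained either as a within-stratum
    sum-of-squares ratio in ANOVA or via unit-centered refits of linear
    mixed-effects models. Mixed models with crossed participant and stimulus
    random effects are fit by REML through 'lme4'/'lmerTest'; marginal and
    per-term semi-partial R2 follow the Nakagawa-Schielzeth-Johnson variance
    decomposition. Includes the worked toy datasets, a synthetic-data
    generator with known variance components for parameter-recovery checks,
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    lmerTest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
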