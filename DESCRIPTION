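Package: twinfalcon
Title: Twin-Based Causal Inference for Metabolite-Lipid Associations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for monozygotic-twin metabolomics studies of blood
    lipids. Provides a synthetic MZ-twin cohort and targeted-metabolome generator
    with known causal structure; quality-control filtering (analytical CV and QC
    occurrence), limit-of-detection imputation and variable transforms;
    pair-clustered metabolite-lipid association screens with Benjamini-Hochberg
    false discovery rate control, BMI sensitivity and overweight-stratified
    interaction tests; the ICE FALCON three-model co-twin regression procedure
    with pair-resampling bootstrap change tests and evidence-pattern
    classification; and bidirectional causal mediation analysis linking lipids,
    metabolites and cardiometabolic traits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
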