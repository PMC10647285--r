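Package: metstab
Title: Multi-Model Genotype-by-Environment Stability Analysis for Multi-Environment Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing balanced multi-environment yield trials
    (MET): joint ANOVA with the AMMI (additive main effects and
    multiplicative interaction) decomposition and per-axis Gollob F-tests,
    AMMI stability values (ASV) and biplot coordinates, mixed-model
    variance components with BLUP-based WAASB/WAASBY simultaneous
    selection indices, RMSPD cross-validation of the AMMI family against
    BLUP predictors, the full set of GGE biplot interpretation patterns
    (which-won-where, mean vs stability, genotype ranking,
    discriminativeness vs representativeness, pairwise comparison,
    per-genotype environment evaluation) as coordinate and ranking tables,
    and scalar stress/stability indices (Fischer-Maurer heat
    susceptibility index with tolerance classes, Annicchiarico
    recommendation index, environmental index). Includes a synthetic MET
    generator with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    lme4
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
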