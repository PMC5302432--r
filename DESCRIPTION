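Package: nutristab
Title: Nutritional Yield, Stability and Selection Analysis for
    Multi-Environment Wheat Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for organically grown wheat multi-environment
    trials. Computes mineral nutritional yield (adults fed per hectare per
    year) and nutrient density from grain yield and mineral concentrations,
    with dehulling correction for spelt and primitive wheats; partitions
    variance into genotype, environment and interaction components; fits the
    AMMI (additive main effects and multiplicative interaction) model with
    stability rankings and biplot export; predicts genotypic values by BLUP
    with the HMGV, RPGV and HMRPGV stability and adaptability statistics;
    ranks genotypes by Elston's multiplicative index and the Pesek-Baker
    desired-gains index; and aggregates all methods into a combined
    "balanced genotype" ranking. Includes a seeded simulator of balanced
    trials with low-rank genotype-by-environment interaction and
    yield-concentration dilution, plus reference tables from a published
    Swedish organic winter-wheat trial.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
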