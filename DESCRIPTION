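Package: haplodyn
Title: Gene Dynamics of Haplodiploidy and the Origin of Eusociality
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exact population-genetic analysis of how haplodiploidy shapes
    the spread of an allele for reproductive altruism in subsocial
    Hymenoptera lifecycles. Provides exact rational allele-copy invasion
    accounting over single-copy introduction crosses, help thresholds with
    and without per-pair Fisherian sex-ratio adjustment, weak-selection
    fixation probabilities and substitution-rate comparisons between ploidy
    systems, deterministic mated-pair recursions over breeding seasons, a
    finite-population stochastic lifecycle simulator for validation and
    synthetic-data generation, and a chi-square test of first-brood
    sex-ratio bias against social organization in sweat bees.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
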