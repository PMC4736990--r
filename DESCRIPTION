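Package: rguc
Title: Selection of Relevant Genetic Units for Conservation from Dominant Marker Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Conservation-genetics prioritization of populations from dominant
    (presence/absence) multilocus marker data such as AFLP. Computes
    per-population diversity and rarity descriptors (Nei's gene diversity,
    frequency down-weighted marker values, rare-band counts), one-level and
    hierarchical analysis of molecular variance (AMOVA) with permutation tests
    and marker-bootstrap confidence intervals, rare-allele loss probabilities
    and the slope-ratio capture statistic R, preferred-sampling-area
    assignment and largest-remainder apportionment of conservation effort
    across regions, haplotype-sampling completeness via the Stirling
    probability distribution, and a final ranked selection of populations.
    Includes a seeded F-model (Balding-Nichols) generator of synthetic marker
    matrices for testing and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
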