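Package: octadkit
Title: Meiotic Segregation, Heterokaryon, and RIP Simulation for Neurospora
    Chromosome Rearrangements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulation and inference tools for Neurospora crosses
    heterozygous for chromosome translocations.  Models insertional,
    quasiterminal and reciprocal translocations at chromatid resolution
    through meiosis (alternate versus adjacent-1 disjunction, interstitial
    crossovers, ordered octads), species-specific ascospore packaging for
    N. crassa and the pseudohomothallic N. tetrasperma, vegetative
    heterokaryon dynamics (nuclear-ratio evolution, conidial sampling,
    self-cross wiring, meiotic silencing by unpaired DNA), breakpoint
    junction PCR genotyping of [T + N] versus [Dp + Df] heterokaryons with
    an exact-binomial skewed-segregation statistic, and simulation plus
    strand-polarity classification of repeat-induced point (RIP) mutations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
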