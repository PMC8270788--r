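Package: hicarch
Title: Chromosome Architecture Analysis for Hi-C Contact Maps
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing chromosome architecture from chromosome
    conformation capture (Hi-C) contact maps at the scale of a single
    chromosome: contact-matrix input/output and normalization (vanilla
    coverage, square-root vanilla coverage, and iterative balancing),
    distance-decay expected profiles and observed/expected transforms,
    per-bin directionality index and insulation score, per-domain diamond
    and arrowhead-style corner scores, multi-caller consensus calling of
    topologically associating domains (TADs) with diamond-score, size and
    contact-density filters, loop filtering and loop-domain annotation,
    k-means clustering of TAD borders by directionality-index asymmetry,
    rescaled aggregate-TAD maps and condition ratio maps, A/B compartment
    score projection and switch tracking, and spike-in scale factors for
    ChIP-seq and RNA-seq libraries.  A seeded synthetic-data generator
    plants TADs, corner loops, compartments and border-biased signal
    tracks with Poisson noise so every analysis step can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
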