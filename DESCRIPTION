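Package: fragilenuc
Title: Fragment-Length-Resolved MNase-ChIP Analysis of Fragile Nucleosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing paired-end MNase-ChIP-seq chromatin fragments
    with fragment-length resolution: size fractionation into subnucleosomal and
    mononucleosomal classes, spike-in and sequencing-depth normalisation,
    anchor-centred meta-profiles, nucleosome-depleted-region (NDR) scaling,
    fragment-length V-plots with highest-density-region contours, CTCF
    motif-oriented occupancy and 3'-asymmetry statistics, differential
    gain/loss classification with congruence enrichment, and A/T-content
    comparison of fragment populations. Includes a synthetic chromatin
    simulator (phased nucleosome arrays flanking NDRs, fragile particles
    carrying H3K115ac, spike-in barcoded nucleosomes) so every stage of the
    pipeline can be exercised and validated against ground truth without
    external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
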