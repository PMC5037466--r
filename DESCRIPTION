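Package: chorusem
Title: Emergent Chorus Timing: Resetting Males, Precedence Females, and
    Phylogenetic Contrasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether male call-timing adjustments coevolve
    with female preference windows in chorusing acoustic species. Implements
    an event-driven inhibitory-resetting oscillator model of male chorusing,
    estimators for the male minimum post-stimulus call delay (m) and the
    female leading-call preference window (f) from playback experiments,
    microsatellite population genetics (allele frequencies, Nei's DA
    distance, neighbor-joining population trees with locus bootstrap,
    Weir-Cockerham FST), phylogenetically independent contrasts with
    polytomy-adjusted degrees of freedom, and a synthetic-data generator
    that emulates the full study design so the pipeline can be exercised
    and calibrated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    ape,
    phangorn,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
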