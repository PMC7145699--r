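Package: mybdna
Title: MYB Transcription Factor DNA Recognition and Methylation Sensitivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how R2R3-MYB transcription factors read their
    DNA targets and how cytosine (5mC) and adenine (6mA) methylation interfere
    with that readout. Provides degenerate-motif scanning over promoter
    windows with strand-aware intersection of per-base 5mC/6mA methylation
    calls; enumeration of direct and water-mediated protein-DNA hydrogen bonds
    and apolar proximities from atomic coordinates, with geometric rules
    flagging bases whose methylation would sterically clash with, or occlude a
    hydrogen-bond donor used by, the bound protein; forward simulation and
    nonlinear least-squares fitting of the one-site isothermal titration
    calorimetry (ITC) isotherm; and seeded synthetic-data generators (genome,
    methylome, interface coordinate fixtures, thermograms) with recorded
    ground truth so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    bio3d,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
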