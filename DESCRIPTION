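Package: crestwave
Title: Quantitative Analysis of Two-Wave Ocular Neural Crest Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for 4D live imaging of the two
    cranial neural crest waves that colonize the zebrafish eye. Provides a
    ground-truth embryo simulator (two populations with distinct origins,
    schedules, routes, divisions, photoconvertible-reporter dynamics and
    genotype-dependent behaviour), light-sheet-like rendering of nuclear
    stacks with anisotropic PSF and Poisson-Gaussian noise, blob detection
    and division-aware frame linking into lineage forests, backward/forward
    fate propagation with proximal/distal destination classification,
    lineage-homogeneity and penetrance statistics, circular migration-angle
    statistics (circular median, Wallraff rank test), photoconversion
    recovery expression classification, and Welch two-sample tests from
    summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    ape,
    clue,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
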