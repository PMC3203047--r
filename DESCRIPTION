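Package: bilayertools
Title: Single-Channel Analysis of Planar Lipid Bilayer Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of single-channel current recordings from planar lipid
    bilayer experiments with reconstituted membrane proteins: noise-robust
    trace idealization and gating-event extraction, conductance-class
    assignment and per-class current-voltage fitting, fully-open (total)
    conductance estimation, reversal-potential extraction from voltage ramps,
    Goldman-Hodgkin-Katz permeability-ratio inversion, Hille-style pore-size
    estimation, and liposome swelling-assay summaries. A continuous-time
    Markov single-channel simulator generates synthetic recordings with known
    ground truth so that every analysis stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
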