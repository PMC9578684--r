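Package: meaburst
Title: Spike-Train Analytics for Long-Term High-Density Microelectrode
    Array Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing sorted spike trains from long-term
    high-density microelectrode array (HD-MEA) recordings of developing
    neuronal cultures. Provides automated unit curation (interspike-interval
    violations, signal-to-noise ratio, firing rate), action-potential
    frequency and instantaneous-frequency analytics with fast-spiking
    classification, Poisson-surprise burst detection with surprise
    maximization, network-burst participation, electrode-grid activity maps
    with active-electrode selection, soma-displacement analytics from
    tracking tables, and nonparametric condition comparison
    (Kruskal-Wallis with Dunn post hoc). A seeded synthetic-session
    generator with ground truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
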