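Package: hallmarkCA
Title: Hallmark-Based Cellular Automaton Model of Avascular Tumor Growth
    with Cancer Stem Cells
Version: 1.0.0
Authors@R:
    person("Joan", "Carver", email = "jcarver@example.org",
           role = c("aut", "cre"))
Description: Event-driven 3D cellular-automaton simulation of avascular
    tumor growth in which cells acquire five binary cancer hallmarks
    (self-growth, ignore growth inhibit, evade apoptosis, effective
    immortality, genetic instability) through mutation at division, with a
    telomere-limited replicative potential, a hierarchical cancer-stem-cell
    compartment dividing symmetrically or asymmetrically, and parameterized
    treatment schedules (pulse, continuous and periodic, optionally gated
    on a tumor-burden threshold) that kill differentiated cancer cells
    only. Provides named experiment presets, regrowth metrics, time-series
    and snapshot output, a JSON configuration format and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
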