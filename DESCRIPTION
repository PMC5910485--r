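Package: poredirection
Title: Directional Asymmetry of Small-Molecule Uptake into Electropermeabilized Cells
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies directionally asymmetric dye uptake into
    electropermeabilized cells from time-lapse fluorescence image stacks.
    Provides electrode-aligned regional photometry (anode/middle/cathode
    row-partition of each cell mask), lysate-based fluorescence-to-
    concentration calibration, anode-cathode asymmetry-difference kinetics
    with decaying-exponential fitting, Einstein-Smoluchowski and
    Stokes-Einstein diffusion arithmetic for the dyes involved, and a
    ground-truthed reaction-diffusion image simulator emulating
    microsecond- and nanosecond-pulse influx regimens for pipeline
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), yaml, withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
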