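Package: mfakit
Title: Marker Frequency Analysis of Bacterial Replication Profiles
Version: 0.1.0
Authors@R:
    person("MFA", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for marker frequency analysis (MFA) of circular bacterial
    chromosomes from binned sequencing coverage. Implements windowed read
    binning, normalization against a run-out control, circular loess
    smoothing, and detection of replication features: origin peaks (oriC and
    R-loop-dependent oriK origins), polar Ter/Tus fork-trap asymmetry,
    DNA amplification segments, and replication "steps" at head-on
    transcription barriers. Includes a population-level replication
    simulator for circular genomes (origin firing, fork progression with
    polar trapping, structural variants, Poisson sampling) so every analysis
    stage can be validated against known ground truth, plus qPCR 2^-dCt
    marker-ratio utilities and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
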