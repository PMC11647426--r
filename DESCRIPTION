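Package: parkfield
Title: Open-Field Phenotyping of Acute Dopamine-Antagonist-Induced Parkinsonism
Version: 0.1.0
Authors@R:
    person("Park", "Field", email = "maintainer@parkfield.dev", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for open-field locomotion studies
    of acute parkinsonian motor phenotypes induced by dopamine D1 (SCH23390) or
    D2 (haloperidol) receptor antagonists.  Provides a synthetic trajectory
    generator (two-state semi-Markov correlated random walk with Emax/Hill
    pharmacodynamic suppression and Bateman onset/washout kinetics), motor
    metrics (distance travelled, rotations from the body axis, maximum speed
    with jitter filtering, immobility and freezing episode segmentation, mobile
    episodes), thigmotaxis zone occupancy on a 5x5 arena grid, and the
    dose-response statistical layer (one-way ANOVA with Dunnett's comparisons
    against a saline control, two-way treatment-by-time ANOVA with Sidak-adjusted
    per-bin contrasts rendered as p-value heatmaps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
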