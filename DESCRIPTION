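Package: brushfoul
Title: Trajectory Analysis of Grafted Zwitterionic Polymer Brushes under
    Foulant Adsorption
Version: 1.0.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds coarse-grained models of grafted zwitterionic
    (sulfobetaine-like) polymer-brush surfaces at low and high grafting
    density, generates synthetic multi-frame trajectories with scripted
    foulant detachment, anchoring and penetration mechanisms, and analyses
    trajectories with the standard brush/foulant characterizations:
    per-chain topography heights, root-mean-square fluctuation, hydration
    shell water counting, foulant detachment height, Kabsch superposition
    RMSD, electrostatic and hydrogen-bond occurrence statistics with a
    neglect floor, and periodic-boundary-aware smoothed surface topography
    maps. Trajectories are exchanged as multi-model PDB files with a
    delimited role-annotation sidecar.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
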