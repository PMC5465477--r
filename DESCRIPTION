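Package: channelprobe
Title: Trajectory Analysis of Anesthetic Binding to Pentameric Ligand-Gated Ion Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing volatile-anesthetic interactions with
    pentameric ligand-gated ion channels from molecular dynamics trajectories:
    ligand-residue contact probabilities, binding/unbinding event detection with
    residence-time and fluctuation statistics, pore radius profiling along the
    channel axis, hydrophobic-gate hydration counting, M2 helix tilt angles,
    backbone RMSD comparisons over named residue ranges, ligand phase
    partitioning between water, membrane and protein, and reconstruction of
    one-dimensional potentials of mean force from umbrella-sampling windows by
    the weighted histogram analysis method (WHAM). A synthetic toy-channel
    generator produces C5-symmetric test systems and scripted trajectories with
    known ground truth so every analysis stage can be validated without
    running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
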