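Package: bridgeswitch
Title: Salt-Bridge Shuttle Network Analysis for Protein MD Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses the dynamics of intramolecular salt-bridge networks in
    protein molecular-dynamics trajectories, focused on "shuttle" motifs in
    which a central basic residue (e.g. a conserved lysine in ubiquitin
    E2-conjugating enzymes) alternates between an interface acidic partner
    and a remote acidic partner, gating a binding-competent "open" and a
    binding-impaired "bridged" conformation. Provides multi-model PDB and
    distance-series I/O, charged-group identification under a protonation
    policy, per-frame minimum inter-group distances with hysteretic
    formed/broken state calling, time-resolved salt-bridge networks and
    shuttle-motif detection via distance anticorrelation, open/bridged
    occupancy and exchange kinetics, running-average smoothing, Kabsch
    superposition and cross-RMSD matrices, moving-block bootstrap confidence
    intervals, and a ground-truth-labelled two-state Gillespie simulator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
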