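#!/usr/bin/env Rscript
# Generate the ground-truth-labelled fixture suite: five two-state shuttle
# scenarios (balanced wild-type-like, bridged-biased wild-type-like, an
# interface-disabled variant, a locked-bridged variant, and an uncoupled
# control), each 20 000 frames at 10 ps (200 ns), written as toy multi-model
# PDB + distance TSVs + truth JSON under scratch/fixtures. The manifest
# (small, seeds and expected ranges) is copied to results/.

suppressPackageStartupMessages(library(bridgeswitch))

seed <- 1L
out_dir <- "scratch/fixtures"
suite <- make_fixture_suite(out_dir, seed = seed, n_frames = 20000,
                            dt_ps = 10, write_pdb = TRUE)
dir.create("results", showWarnings = FALSE)
invisible(file.copy(file.path(out_dir, "manifest.json"),
                    "results/fixture_manifest.json", overwrite = TRUE))

for (case in names(suite$truths)) {
  tr <- suite$truths[[case]]
  message(sprintf("%-18s BRIDGED fraction %.3f, %d transitions in 200 ns",
                  case, mean(tr$states == "BRIDGED"),
                  length(tr$transition_times_ns)))
}
message("fixtures under ", out_dir, "; manifest copied to results/")
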