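---
title: "Methods: quantifying salt-bridge shuttle equilibria in MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying salt-bridge shuttle equilibria in MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bridgeswitch)
```

## The problem

Ubiquitin-conjugating (E2) enzymes of the UbcH6/UbcH8 family carry an acidic
residue in loop L1 of the E3-binding surface whose availability is gated by an
intramolecular salt-bridge network. A conserved central lysine alternates
("shuttles") between two acidic partners: when it binds the *interface* acid,
that side chain is sequestered away from the E3 RING surface (a **bridged**,
binding-impaired conformation); when it binds a *remote* acid instead, the
interface acid is released (an **open**, binding-competent conformation).
The observable signature in an MD trajectory is a pair of strongly
anticorrelated minimum side-chain distances: central–interface and
central–remote.

`bridgeswitch` turns that signature into numbers: per-frame minimum
inter-group distances, hysteretic formed/broken calls, a time-resolved
salt-bridge network, shuttle-motif detection by Pearson anticorrelation,
open/bridged occupancies, exchange kinetics, and bootstrap uncertainty — with
a ground-truth-labelled two-state simulator so every stage is testable
without running MD.

## The model

### Charged groups and protonation

Ionizable side chains are reduced to their charge-carrying terminal atoms:
Asp/Glu carboxylate oxygens (OD1/OD2, OE1/OE2), Lys NZ, Arg NE/NH1/NH2, His
ND1/NE2. Histidine is counted as charged (imidazolium) when the pH of the
`protonation_policy()` lies below 6 — appropriate for the mildly acidic
intracellular environment of yeast (pH ≈ 5.5), where solvent-exposed
histidines are expected to be protonated. Chain termini are opt-in; the
networks of interest here are side-chain mediated. No pKa prediction is
attempted: the policy is a user-controlled assumption, not an estimate.

### Bridge calling with hysteresis

The distance between two groups in a frame is the minimum over all pairs of
their charge atoms. A bridge is **FORMED** when that distance falls below
`d_on` and **BROKEN** when it exceeds `d_off`; between the two thresholds the
previous label is held. Defaults are `d_on = 4.0` Å — the common
structural-biology criterion for a salt bridge (minimum N–O distance < 4 Å) —
and `d_off = 6.0` Å. Distance traces of this system oscillate between ~3 Å
contact and a broken state beyond 8 Å, so any cutoff inside the gap separates
the two modes; the hysteresis band exists to keep dwell and exchange
statistics from being shredded by threshold-grazing noise. The first frame is
resolved by the midpoint rule (FORMED iff below `(d_on + d_off)/2`). Both
thresholds are configurable because a single published cutoff does not exist
for this class of analysis.

### Shuttle motifs and state classification

Opposite-charge pairs whose FORMED occupancy reaches `min_occupancy`
(default 0.05) become network edges. Every basic node with at least two
acidic edges is screened: a partner pair whose distance-series Pearson
correlation is at most `rho_max` (default −0.5) is a shuttle motif.
Correlations are computed on raw, unsmoothed values: running-average
smoothing inflates |ρ| by construction, so the conservative choice is raw
data, with smoothing (default 100 ps window) reserved for presentation.

Which acidic partner is the "interface" one is a structural fact that cannot
be inferred from distances alone; it is supplied by annotation
(`interface_residues`). Frames are then classified:

| interface bridge | remote bridge | state |
|---|---|---|
| FORMED | BROKEN | BRIDGED (binding-impaired) |
| BROKEN | FORMED | OPEN (binding-competent) |
| FORMED | FORMED | BIFURCATED |
| BROKEN | BROKEN | UNBOUND |

Occupancies are label fractions over all retained frames. Exchange counting
is gap-tolerant: BIFURCATED/UNBOUND frames between an OPEN and a BRIDGED
visit do not reset the transition, because real exchanges pass through
transient intermediates and strict adjacency would undercount. Dwell times
are contiguous run lengths times the frame interval; the exchange rate is
the exchange count over the analysed duration.

### Trajectory statistics

* **Equilibration exclusion.** All analyses drop frames before `exclude_ps`
  (default 1000 ps), the convention of discarding the first nanosecond of a
  trajectory.
* **Superposition.** Kabsch's SVD solution restricted to proper rotations
  (determinant-sign correction), uniform weights by default. Fewer than three
  atoms or a collinear selection is a degenerate-geometry error rather than a
  silent answer.
* **Cross-RMSD.** RMSD between every frame pair after superposition over a
  named-atom selection (default `"CA,CB"`). The matrix is computed once per
  unordered pair, so symmetry and the zero diagonal are exact. A flat, low
  matrix is the signature of a conformationally stable protein. The pair loop
  is quadratic in frames; the pipeline subsamples to
  `max_rmsd_frames` (default 60) frames for its summary.
* **Uncertainty on ρ.** A circular moving-block bootstrap over paired frames
  (percentile 95% interval), deterministic given its seed. MD frames are
  autocorrelated, so i.i.d. resampling would be overconfident; the block
  length is user-chosen (the pipeline default is 100 frames) and should
  exceed the correlation time. No automatic correlation-time estimation is
  attempted.

## The synthetic generator

`simulate_shuttle()` draws an exact Gillespie path of a two-state
continuous-time Markov chain (rates `k_ob`, `k_bo` in ns⁻¹), assigns each
frame the state at its interval *midpoint* — endpoint sampling biases dwell
statistics more at coarse frame spacing — and emits per-frame Gaussian
distances: in BRIDGED frames the interface distance comes from the "formed"
distribution and the remote one from "broken", and vice versa in OPEN
frames. Defaults are formed 3.0 ± 0.4 Å and broken 8.5 ± 1.2 Å, mimicking
the bimodal oscillation of real salt-bridge traces between ~3 Å and > 8 Å;
emissions are truncated at a 0.5 Å physical floor. Optional AR(1) noise
(`phi`) produces temporally correlated residuals for stress-testing the
block bootstrap. If the expected transitions per frame exceed 0.5 the
simulator warns about aliasing.

The fixture presets encode the study conditions: a balanced fast-exchange
shuttle (`k_ob = k_bo = 5 ns⁻¹`), a BRIDGED-biased slower one
(`k_ob = 3, k_bo = 1 ns⁻¹`, stationary bridged fraction 0.75 — a shuttle
with a higher population of the binding-impaired conformation and rarer
exchange toward the open form), an interface-disabled variant (interface
emissions forced broken, the analogue of replacing the central lysine with a
shorter, stiffer histidine that can no longer bridge the interface acid), a
locked-BRIDGED variant (`k_ob = 20, k_bo = 0.1 ns⁻¹`, as when the remote
acid is replaced by a like-charged residue and repels the central lysine),
and an uncoupled control (two independent two-state processes, ρ → 0). True
exchange rates in real E2 trajectories are not published; these values are
chosen for statistical power at 200 ns of simulated time, not as physical
estimates. Mutation presets encode qualitative outcomes as parameter shifts,
not physics.

**What the generator does and does not emulate.** It reproduces two-state
exchange kinetics, state-conditional bimodal distance distributions,
equilibration exclusion, and (optionally) noise autocorrelation. It does not
reproduce force-field realism, solvent, side-chain rotamer geometry,
multi-state intermediates, or slow conformational drift. Passing tests
therefore demonstrate that the *analysis* recovers the truth of this
generative model, not that the model captures everything in real MD data.

## Numerical choices

* Frame times are `t0 + i·dt` exactly (0-based frames, ps units throughout);
  the frame interval is user metadata since PDB files carry no time record
  (default 10 ps).
* PDB I/O follows fixed wwPDB v3.3 columns; alternate locations other than
  blank/'A' are skipped, insertion codes rejected. Coordinates are written to
  3 decimals, so file round-trips are exact to 5×10⁻⁴ Å.
* The running-average window is the largest odd frame count whose span does
  not exceed `window_ps`; at the edges it shrinks symmetrically.
* Occupancies sum to 1 by construction; motif lists are sorted by ascending
  ρ, networks by (chain, residue number), so all outputs are deterministic.
* All stochastic steps (simulation, bootstrap) take explicit seeds;
  `run_analysis()` with the same config and inputs reproduces its report
  byte for byte.

## Problem sizes

The validation suite simulates 20 000-frame (200 ns at 10 ps) series for
occupancy/kinetics recovery and motif screening, 10 replicate seeds for the
recovery checks, and 2 000-frame trajectories at 100 ps spacing for
end-to-end PDB runs; cross-RMSD summaries use 60-frame subsamples. These
sizes give Monte-Carlo errors comfortably inside the assertion tolerances
(e.g. across-seed mean occupancy error ≈ 0.007 against a ±0.03 bound) while
keeping the whole suite inside a few minutes on a laptop.

## Known limitations

* Dwell-time estimates carry a small discretization bias: excursions shorter
  than one frame interval are invisible, which merges adjacent dwells of the
  opposite state. At the preset rates this bias is a few percent; at
  `k·dt > 0.5` it dominates (hence the aliasing warning).
* Interface/remote role assignment is annotation, not inference.
* The hysteresis thresholds are conventions; dwell statistics (not
  occupancies) are sensitive to them when emission modes overlap.
* The block bootstrap assumes the block length exceeds the correlation time;
  it is not estimated automatically.
* Like-charge distance series can be computed (for repulsion analyses) but
  are never called bridges and never enter motifs.
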