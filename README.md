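# bridgeswitch

Analysis of intramolecular **salt-bridge shuttle networks** in protein
molecular-dynamics trajectories, for structural bioinformaticians studying
conformational gating of protein–protein interfaces — in particular the
E2 ubiquitin-conjugating enzyme family, where a conserved lysine at the rim
of the E3-binding surface alternates between an interface acid (Glu/Asp in
loop L1) and a remote acid, switching the enzyme between an **open**
(binding-competent) and a **bridged** (binding-impaired) conformation.

## The statistic at the core

For a central basic group *c* and two acidic partners *p₁*, *p₂*, let
*d₁(t)*, *d₂(t)* be the per-frame minimum charge-atom distances
*d(c,p₁)*, *d(c,p₂)*. A shuttle motif is a triple whose distances are
strongly anticorrelated,

ρ = Σₜ(d₁−d̄₁)(d₂−d̄₂) / √(Σₜ(d₁−d̄₁)² · Σₜ(d₂−d̄₂)²) ≤ ρ_max,

because the central residue is bound to one partner or the other, never
both. Bridges are called with hysteresis (FORMED < 4 Å, BROKEN > 6 Å,
previous label held in between); frames are classified
OPEN / BRIDGED / BIFURCATED / UNBOUND from the two bridge states, giving
state occupancies, OPEN↔BRIDGED exchange rates and dwell times. A two-state
Gillespie simulator with state-conditional distance emissions provides
ground-truth-labelled trajectories so every stage is verifiable without MD.

## Worked example

Simulate a bridged-biased shuttle (k_ob = 3, k_bo = 1 ns⁻¹, 200 ns at
100 ps), embed it as a multi-model PDB, and run the full pipeline:

```r
library(bridgeswitch)

truth <- simulate_shuttle(shuttle_params(k_ob = 3, k_bo = 1,
                                         n_frames = 2000, dt_ps = 100,
                                         seed = 1))
pdb <- tempfile(fileext = ".pdb")
write_multimodel_pdb(embed_toy_trajectory(truth), pdb)

report <- run_analysis(list(trajectory = pdb, dt_ps = 100,
                            interface_residues = "E105", seed = 1,
                            bootstrap = list(n_boot = 1000, block_frames = 20),
                            output_dir = "results/report"))
str(report$motif[c("central", "interface", "remote", "rho")])
```

```
List of 4
 $ central  : chr "K109"
 $ interface: chr "E105"
 $ remote   : chr "D137"
 $ rho      : num -0.882
```

The detected motif is the planted one: K109 shuttling between E105
(interface) and D137 (remote), with ρ = −0.882 (95% CI −0.892 to −0.868) —
binding of the two partners is mutually exclusive. The report also carries
the state occupancies (OPEN 0.242, BRIDGED 0.754, matching the stationary
k_ob/(k_ob+k_bo) = 0.75 of the generator), 261 OPEN↔BRIDGED exchanges
(1.31 /ns), per-state dwell times, and a cross-RMSD summary over the static
CA anchors (≈ 0 Å, a conformationally rigid frame of reference). Recovered
per-frame states agree with the generative truth for 99.6% of frames.

## Analysis workflow

The `analysis/` directory holds numbered drivers that reproduce the whole
study on synthetic data, writing small tables under `results/` (large
fixture files go to `scratch/`):

| script | what it does |
|---|---|
| `01_simulate_fixtures.R` | generate the five-case labelled fixture suite (wild-type-like balanced & bridged-biased, interface-disabled, locked-bridged, uncoupled control) |
| `02_distance_dynamics.R` | distance traces, 100 ps running averages, ρ with block-bootstrap CI |
| `03_shuttle_equilibrium.R` | networks, motif detection, occupancies, exchange kinetics per case |
| `04_cross_rmsd.R` | cross-RMSD conformational-stability summary |
| `05_full_report.R` | end-to-end `run_analysis()` from a PDB file |

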