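# mdpost

Comparative post-processing of molecular dynamics trajectories of protein
complexes, built around the analysis sequence used to contrast a stable
binder–target complex with a destabilized point-mutant variant: fluctuation
metrics, correlated motions, essential dynamics, interface interaction
statistics, implicit-solvent binding energetics, and residue community
networks. A synthetic trajectory generator with fully known planted
structure makes every stage testable end to end.

## Who this is for

Computational structural biologists who have (or simulate) trajectories of a
two-chain protein–protein complex — for example an engineered binding
scaffold against an enzyme domain — and want a reproducible, scriptable way
to quantify *why* one variant binds more stably than another.

## What it computes

Given a topology (PDB), a coordinate trajectory (multi-model PDB or DCD, in
Å) and a per-atom parameter table:

- **RMSD / RMSF** — Kabsch least-squares superposition; per-frame deviations
  and per-residue fluctuations, with both initial-structure and
  mean-structure reference conventions.
- **DCCM** — the dynamic cross-correlation matrix of Cα displacement
  vectors, C<sub>ij</sub> = ⟨Δr<sub>i</sub>·Δr<sub>j</sub>⟩ /
  √(⟨Δr<sub>i</sub>²⟩⟨Δr<sub>j</sub>²⟩) ∈ [−1, 1], about the trajectory mean
  after superposition.
- **Essential dynamics** — eigendecomposition of the 3N×3N Cartesian
  covariance; a *shared* PCA space for two systems (pooled superposed
  frames), per-component variance fractions, projections, RMSIP and overlap
  matrices over the first k = 10 components, porcupine displacement output,
  and free-energy landscapes G<sub>i</sub> = −k<sub>B</sub>T ln(N<sub>i</sub>/N<sub>max</sub>)
  over any one or two reaction coordinates, plus seeded k-means
  representative conformations.
- **Interactions** — Shrake–Rupley SASA (deterministic golden-spiral
  quadrature), buried interface area (half-buried-SASA convention),
  and exact frame-counted occupancies of contacts (4.5 Å), hydrogen bonds
  (heavy-atom D–A ≤ 3.5 Å), salt bridges (N–O ≤ 4.0 Å) and hydrophobic
  contacts, with a ≥ 70 % stable-contact flag.
- **Energetics** — single-trajectory end-point binding free energy
  ΔG = ΔE<sub>vdW</sub> + ΔE<sub>ele</sub> + ΔE<sub>polar</sub> +
  ΔE<sub>nonpolar</sub> (entropy excluded and marked so), with a
  generalized-Born polar term (HCT effective radii, Still pairwise form),
  γ·SASA + b nonpolar term (γ = 0.00542 kcal mol⁻¹ Å⁻², b = 0.92 kcal/mol),
  and an exactly conservative per-residue decomposition.
- **Community networks** — residues as nodes, edges where contacts persist
  ≥ 75 % of frames, weights d<sub>ij</sub> = −log|C<sub>ij</sub>|;
  Girvan–Newman divisive communities kept at maximum modularity (minimum
  reported size 3), weighted betweenness, and intercommunity coupling
  strengths.
- **`run_compare()`** — the whole sequence for two systems at once, with a
  paired metric report and per-stage TSV outputs.

## Worked example

The synthetic generator builds a matched pair of datasets: a "wt-like"
system (tight interface, approaching drift, high interaction occupancies, an
active hub residue bridging the chains) and a "mutant-like" system (one
dominant large-amplitude motion, departing drift, low occupancies, hub
contacts lost):

```r
library(mdpost)
pair <- make_scenario_pair(seed = 1, frames = 500)
rep <- run_compare(run_config(label = "wt"), run_config(label = "mut"),
                   datasetA = pair$wt, datasetB = pair$mut, hub_id = "P:459")
print(rep)
```

```
compare_report: wt vs mut
  subspace RMSIP (first 10 PCs): 0.623
  mean_rmsd_A                      0.8614      1.6654
  mean_rmsf_A                      0.8557      1.7035
  pc1_fraction                     0.1983      0.5757
  pc2_fraction                     0.1159      0.0551
  interface_mode_A2              122.5000      1.0000
  dG_binding                      -7.1537     -3.7147
  max_saltbridge_occupancy         0.7780      0.2440
  max_hbond_occupancy              0.7780      0.2440
  max_hydrophobic_occupancy        0.9000      0.3000
  n_stable_contacts                3.0000      0.0000
  n_communities                    6.0000      6.0000
  interchain_strength              1.0805      0.0000
  hub_spanning_community           1.0000      0.0000
```

Reading the report: the wt-like system fluctuates half as much (mean RMSD
0.86 vs 1.67 Å), keeps its planted salt bridge at exactly 77.8 % occupancy
(the mutant-like run decays to 24.4 % at best), binds ~3.4 kcal/mol more
favorably, buries a ~120 Å² interface where the mutant buries essentially
none, and its residue network contains a community that spans both chains
and includes the planted hub residue P:459 — while the mutant-like network
has no inter-chain coupling left at all. The mutant-like system concentrates
58 % of its motion in a single principal component (vs 20 %), the signature
of one dominant collective mode.

Every number above is recomputed from the trajectory by the corresponding
stage; `run_compare(..., outdir = "out")` writes each stage's table
(`rmsd.tsv`, `dccm.tsv`, `fel.tsv`, `interactions.tsv`, `energy.tsv`,
`network_edges.tsv`, `communities.tsv`, ...) so each report row can be traced
to a file.

## Documentation

The methods vignette (`vignettes/trajectory-comparison.Rmd`) describes the
models, their assumptions, all tunable thresholds with units and defaults,
what the synthetic generator does and does not emulate, and the package's
numerical conventions.
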