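---
title: "Comparative trajectory analysis with mdpost: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative trajectory analysis with mdpost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mdpost post-processes molecular dynamics trajectories of two-chain protein
complexes and compares two systems — typically a stable complex against a
destabilized variant — across fluctuations, correlated motions, essential
dynamics, interface interactions, implicit-solvent energetics and residue
community networks. This vignette is the package's account of the science
behind each stage: the model, its assumptions, the tunable parameters, and
the design decisions taken where conventions genuinely diverge.

## 1. Data model and conventions

Coordinates are always in Ångström internally; readers convert on input.
Author residue numbering and chain identifiers are preserved end to end, so
outputs can name residues the way structural papers do (D27, R151, C459).
Atom order is stable: every derived matrix or table refers to atoms in
topology order. Trajectories carry an analysis-start index realizing the
usual equilibration discard; all statistics use only post-equilibration
frames. The default is no discard, because the synthetic generator produces
stationary ensembles; for real trajectories the start frame is the user's
judgement call from the RMSD series.

Supported trajectory formats are multi-model PDB and DCD. XTC is not read:
no installed R-side reader exists for its compressed coordinate codec, and
shelling out to a second language runtime for a core input path would make
the package's behaviour environment-dependent. DCD and multi-model PDB
cover the interchange need; conversion from XTC is a one-liner in common MD
toolchains.

## 2. Fluctuation metrics

Superposition is uniform-weight Kabsch (SVD with a determinant guard, so the
rotation is always proper). RMSF supports two references: the position in
the initial analysis frame, and the trajectory-mean position. Both exist in
the literature and they differ for drifting systems, so the convention used
is recorded on the result object (`attr(x, "reference")`) rather than left
implicit. Fitting before measuring is a flag (`fit`), because whether global
rotation/translation should be removed before measuring "fluctuation about
the initial position" is itself a convention choice; the default removes it.

## 3. Dynamic cross-correlation

For selected atoms (one per residue, Cα by convention) the correlation of
3-D displacement vectors is

$$C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j\rangle}
  {\sqrt{\langle \Delta r_i^2\rangle \langle \Delta r_j^2\rangle}} \in [-1, 1].$$

Displacements are taken about the trajectory mean after frame-wise
superposition — the standard convention of trajectory toolkits — with the
initial frame available by flag. Atoms with zero variance have undefined
correlations and are reported as missing, never as zero: a zero would
silently enter downstream averages. Display masking (|C| below a threshold
blanked, 0.3 by default) is a *copy* operation; the computation-facing
matrix is never masked, because network edge weights must use the unmasked
values.

## 4. Essential dynamics

PCA is the eigendecomposition of the 3N×3N covariance of pooled, superposed
frames. When two systems are supplied, the model is fitted on their pooled
post-equilibration frames against a single common reference — this is the
package's construction of a "shared PCA space" in which both systems'
projections are directly comparable. The alternative (project system B onto
system A's modes) is available by simply fitting on one system and
projecting the other.

Numerical choices:

- The decomposition uses SVD of the centered frame matrix rather than
  forming the covariance, for stability and speed.
- Eigenvector signs are fixed so the largest-magnitude loading is positive,
  making projections reproducible across platforms (eigenvectors are
  otherwise defined only up to sign).
- Sample covariance uses the n−1 denominator; a warning is raised when the
  frame count does not exceed 3N, where the covariance is rank-deficient.

Subspace similarity uses RMSIP over the first k = 10 components,
$\mathrm{RMSIP} = \sqrt{\tfrac1k \sum_{i,j \le k} (v_i^A \cdot v_j^B)^2}$,
with the full k×k overlap matrix available for inspection.

Free-energy landscapes convert bin populations to relative free energies,
$G_i = -k_B T \ln(N_i / N_{\max})$ with
$k_B = 0.0019872041\ \mathrm{kcal\,mol^{-1}K^{-1}}$ and T = 310 K by default
(a physiological-temperature simulation). The most populated bin sits at
exactly zero; empty bins are undefined (NA), not capped at a large constant,
so plotting layers can decide how to render them. Default grid 100×100 for
PC-space landscapes; any one or two per-frame series (PCs, RMSD, distances)
can serve as reaction coordinates.

Representative conformations come from k-means on the projections
(k = 5 by default, mirroring the common five-cluster presentation of
conformational families). The implementation is `stats::kmeans` with 50
random restarts under a fixed seed — a mature, well-tested optimizer; with
50 restarts the choice of initialization scheme is immaterial for the small,
well-separated clusters this stage encounters, and determinism comes from
the seed. Clusters are reported largest-first with exact occupancy
percentages and the medoid frame (nearest to each centroid).

## 5. Interface interactions

SASA is Shrake–Rupley with a deterministic golden-spiral point set
(960 points per atom by default, probe 1.4 Å); the quadrature is implemented
in the package because no installed R package provides SASA. A Bondi-type
element radius table is shipped and overridden by any per-atom radii in the
parameter file. Interface area per frame is
(SASA(A) + SASA(B) − SASA(A∪B))/2 — the half-buried-SASA convention, stated
in the output header since both the half and the full convention circulate.

Occupancies are exact frame counts — occupancy × frames is always an
integer — with no smoothing, so planted or reported percentages can be
checked to the last frame. Criteria, all configurable:

| interaction | criterion | default |
|---|---|---|
| contact | any-heavy-atom minimum distance | ≤ 4.5 Å |
| hydrogen bond | donor–acceptor heavy atoms (template-assigned) | ≤ 3.5 Å (≥ 135° D–H···A when H present) |
| salt bridge | Asp/Glu carboxylate O to Lys NZ / Arg NH,NE (His optional) | ≤ 4.0 Å |
| hydrophobic | apolar side-chain C to apolar side-chain C | ≤ 4.5 Å |
| stable flag | occupancy threshold, inclusive | ≥ 0.70 |

Hydrogen-bond geometry uses the heavy-atom fallback when structures carry no
hydrogens (the synthetic fixtures are heavy-atom only); the mode used is
recorded in the table's metadata so occupancies remain interpretable. A
residue pair can legitimately appear both as hydrogen bond and as salt
bridge — the two detectors apply independent criteria to overlapping atom
sets, and both records are reported rather than arbitrating between them.
The stable-contact threshold (0.70) and the network persistence threshold
(0.75, §7) are deliberately two distinct knobs.

## 6. Binding energetics

The end-point decomposition is

$$\Delta G_{\mathrm{bind}} = \underbrace{\Delta E_{\mathrm{vdW}} +
\Delta E_{\mathrm{ele}} + \Delta E_{\mathrm{int}}}_{\Delta E_{\mathrm{MM}}}
+ \underbrace{\Delta E_{\mathrm{polar}} +
\Delta E_{\mathrm{nonpolar}}}_{\Delta G_{\mathrm{sol}}},$$

evaluated per frame in the single-trajectory protocol: receptor-alone and
ligand-alone conformations are taken from the complex frames, so the
intramolecular term cancels identically and is reported as exactly zero.
The conformational entropy term is excluded and the output says so — for
comparing similar systems the enthalpic and solvation contrast carries the
signal, and end-point entropy estimates add cost and noise faster than
information.

Terms:

- Electrostatics: Coulomb with 332.0636 kcal Å mol⁻¹ e⁻², no cutoff
  (fixtures are small; a cutoff would add a convergence knob to every test).
- van der Waals: Lennard-Jones in r_min/ε form with arithmetic r_min and
  geometric ε combination.
- Polar solvation: a generalized-Born model — Still's pairwise functional
  form over HCT pairwise-descreening effective radii (element-specific
  screening factors, no radius offset, so an isolated atom's effective
  radius equals its intrinsic radius *exactly*). GB fills the polar slot of
  the solvation decomposition; the slot is an interface, and a
  Poisson–Boltzmann backend could be substituted without changing any
  caller. GB was chosen because it has analytic limits (the Born ion, far
  additivity) that permit exact tests. Dielectrics default to 1 (solute) and
  80 (solvent); zero ionic strength.
- Nonpolar solvation: γ·SASA + b with γ = 0.00542 kcal mol⁻¹ Å⁻² and
  b = 0.92 kcal/mol.

The per-residue decomposition splits every cross-group pair term half to
each partner residue, attributes GB self/pair differences through per-atom
row sums in complex vs. isolated states, assigns γ·ΔSASA per atom, and
spreads the constant −b offset in proportion to |per-residue ΔSASA|. The
construction is exactly conservative: row sums reproduce the total binding
energy up to roundoff, and the test suite enforces agreement within
0.05 kcal/mol.

## 7. Community networks

Residues are nodes; an edge joins residues whose minimum interatomic
distance stays within 4.5 Å for at least 75 % of analysis frames
(inclusive). The contact test uses any-heavy-atom distances by default — a
Cα–Cα 4.5 Å criterion would exclude nearly all non-bonded pairs — with the
Cα mode available for sensitivity checks, never silently mixed. Edge weights
are d = −log |C| from the *unmasked* correlation matrix: the magnitude is
used because anti-correlated motion is coupling too and a signed logarithm
is undefined; |C| is floored at 10⁻⁶ to keep weights finite, and the floor
is recorded on the graph. Consecutive-residue edges are retained by default
(a masking flag exists).

Community detection is the Girvan–Newman divisive algorithm: repeatedly
remove the edge of maximum weighted edge betweenness (shortest paths over
the d weights), tracking the connected-component partition; the partition
retained is the one maximizing Newman–Girvan modularity on the original
graph — the algorithm's classic stopping rule, chosen because the divisive
sequence itself provides no natural stopping point. Ties in the
betweenness maximum break deterministically on edge order. Communities with
fewer than 3 residues are omitted from the reported list (full membership is
still recorded), and intercommunity coupling is the summed |C| over crossing
edges. Betweenness values come from igraph's Brandes implementation; the
test suite checks them against an exhaustive path-enumeration oracle on all
small graphs, and the community stage against exhaustive modularity
maximization.

## 8. The synthetic generator: what it emulates, and what it does not

Real trajectories for this class of problem are rarely deposited, so the
generator is a first-class module, not a fixture: it produces two-chain
Cα-bead complexes whose statistical structure is *planted* and emitted
alongside the data as a ground-truth object. Every downstream stage can
therefore be scored without re-derivation.

The generator emulates, with exact or analytic truths:

- block-structured covariance (per-block collective modes with Gaussian
  amplitudes + isotropic residue noise), giving analytic pairwise
  correlations and variance fractions;
- a low-frequency interface mode: rigid displacement of one chain along the
  interface normal with a drift term (negative drift = approaching,
  positive = departing);
- residue-pair interaction schedules: typed side-chain pseudo-atoms
  (carboxylate O, amine N, hydroxyl O, apolar C) are placed at the
  interaction distance on a seeded random subset of exactly k = occupancy·F
  frames and at inward "home" positions otherwise, so every occupancy is an
  exact rational k/F (specs reject unrepresentable occupancies);
- community structure: blocks are compact 3 Å lattice blobs (dense
  intra-block contacts at the 4.5 Å cutoff), cross-chain scheduled pairs are
  aligned on matched facing-lattice sites ≥ 6 Å apart so schedules do not
  cross-talk, and a hub residue floats free of its own chain's blobs with
  planted persistent contacts across the interface.

It deliberately does **not** emulate: force-field-consistent dynamics or
kinetics (frames are exchangeable draws, not a time series), solvent, side
chains beyond the typed pseudo-atoms, secondary structure, or periodic
boxes. Consequently, passing tests demonstrate that the *analysis stages
recover known statistical structure* — they do not validate force fields or
sampling protocols on real data, where equilibration, autocorrelation and
anisotropy add failure modes the generator does not model.

The default scenario pair mirrors the qualitative contrast between a stable
wild-type-like complex and a destabilized mutant-like one. Scheduled
occupancies follow the published-table pattern of such contrasts (e.g.
77.8 % vs 3.4 % for the key salt bridge, 63.2 % vs 2.6 % for the key
hydrogen bond); percentages were rounded where necessary to values exactly
representable at F = 500 frames, since the generator insists on exact
rationals, and one secondary salt bridge of the template set was dropped so
that each residue carries at most one schedule (keeping every planted pair's
geometry free of shared-anchor interference). These are design templates for
the planted contrast, not reproduction targets: the published values derive
from microsecond all-atom trajectories that are not available.

## 9. Problem sizes and tolerances used by the test suite

The suite exercises the full pipeline at sizes chosen to keep the planted
truths statistically decidable: 54-residue complexes at 500 frames for
end-to-end runs (10 seeds), 5 000 frames for correlation/variance recovery
(planted ρ = 0.8 recovered ± 0.05; 4:1 variance ratio within 5 % using the
sampling estimator averaged over independent draws), 10⁵ samples for the
free-energy-well curvature check (within 10 % of k_BT/σ²), 2 000 frames ×
20 seeds for two-block community recovery, and 240–960 quadrature points for
SASA depending on whether the quantity feeds a trend or an analytic
comparison. Energy stages stride frames (10–100×) because the GB/SASA
evaluation dominates cost while the planted energetic contrast is large.

## 10. Known limitations

- The GB polar term is a surrogate for a finite-difference
  Poisson–Boltzmann solution; absolute polar energies differ between the
  two, which is why analytic-limit and contrast tests, not absolute-value
  tests, guard this stage.
- No mass weighting anywhere (bead fixtures are uniform); superposition and
  PCA are uniform-weight.
- Hydrogen-bond detection without hydrogens cannot check angles; the
  distance-only fallback inflates occupancies slightly for tightly packed
  polar clusters.
- π-stacking, cation–π and water-mediated bridges are not detected.
- The community stage's divisive algorithm is O(E²·V) in the worst case;
  for networks beyond a few thousand edges a faster modularity heuristic
  would be needed.
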