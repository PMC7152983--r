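---
title: "Methods: trajectory metrics, conformational clustering and dynamical networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory metrics, conformational clustering and dynamical networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajcomm)
```

## Scope and model

`trajcomm` implements the analysis layer that sits downstream of a
protein--ligand molecular dynamics simulation, of the kind used to compare
full and partial agonism across nuclear-receptor subtypes (the worked
examples ship the published chiglitazar--PPARα/β/γ energy tables). The
package deliberately does not run or re-run any force-field calculation:
its inputs are trajectories (multi-model PDB), reference structures, and
MM-GBSA term tables produced elsewhere, and its outputs are the standard
derived quantities -- RMSD/RMSF profiles, frame clusters and centroids,
correlation-weighted residue networks with communities and critical nodes,
PCA/ANM mode sets, interaction occupancy fractions, torsion histograms, and
binding-energy summaries.

## Superposition and fluctuation metrics

All deviations are computed after a Kabsch least-squares superposition
(`kabsch_fit()`), solved by SVD of the cross-covariance of the centred
point sets with the determinant correction that enforces a proper rotation.
Collinear point sets are rejected: the optimal rotation is not determined
by them.

* `rmsd_series()` fits each frame on a *fit selection* and measures on a
  *measure selection*. Ligand RMSD conventionally uses a protein fit with a
  ligand measure; both the fit and measure set are explicit arguments, so
  the ligand-fit alternative is one call away.
* `rmsf_profile()` uses the ensemble mean structure as the fitting
  reference, obtained by a two-pass procedure (fit to the first frame,
  average, refit to the mean). This is the standard essential-dynamics
  convention; fitting to frame 1 instead would bias fluctuations towards
  one arbitrary conformation. The initial part of the trajectory is
  discarded before profiling: by default the first half of the frames,
  matching the common practice of analysing only the equilibrated tail,
  and tunable in ns through `equilibration_cut`.
* `subrange_rmsd()` measures an inclusive author-numbered residue range
  (e.g. the activation helix: 448--468, 421--441 or 457--477 for the three
  PPAR subtypes) after a *global* fit, so that genuine sub-range motion is
  not fitted away, and reports a 0.5 Å histogram alongside the series.

No mass weighting is applied anywhere; all atoms in a selection count
equally.

A deliberate consequence of superposition worth knowing when validating
against synthetic data: fitting removes six rigid-body degrees of freedom,
so an isotropic ensemble of N residues loses a fraction of roughly
6/(3N) of its variance to the fit. Analytic checks against the 3-D Gaussian
moment σ√3 therefore use N = 100, where the effect is about 1%.

## Frame clustering

`pairwise_rmsd_matrix()` builds the all-pairs RMSD matrix (each pair
fitted independently), subsampling frames by a stride so at most
`max_frames` (default 2000) enter the O(n²) computation.
`average_linkage()` then performs agglomerative clustering with
average linkage -- merging stops when the smallest average inter-cluster
distance exceeds the merge cutoff, 2.5 Å by default, the conventional
pose-clustering cutoff. Clustering distances are plain RMSD, not squared
RMSD. Each cluster is represented by its *centroid frame*, the member with
the most members within the neighbour cutoff; we default that neighbour
cutoff to the merge cutoff since the two play the same structural-family
role. Ties (equal neighbour counts, equal merge heights) resolve to the
smallest frame index so results are reproducible. `report_major_clusters()`
applies the usual "> 1% of the population" reporting filter, strictly.

## The dynamical network model

Nodes are one per protein residue, positioned at the Cα atom, plus one per
ligand residue at its heavy-atom centroid (a named ligand atom may be used
instead; the centroid is the default because it needs no knowledge of the
ligand's topology). Edges come from contact occupancy: residue pairs whose
heavy atoms come within 4.5 Å in at least 75% of frames. The Methods-style
threshold of 0.75 is the default; 0.70 appears in some narratives and is a
flag away. Pairs within two positions in sequence are excluded by default
(they are trivially in contact through the backbone); set
`neighbor_exclusion = 0` to disable.

Edge weights derive from the normalised cross-correlation of Cα
displacement vectors,

$$C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j \rangle}
{(\langle |\Delta r_i|^2\rangle \langle |\Delta r_j|^2\rangle)^{1/2}},
\qquad w_{ij} = -\log |C_{ij}|,$$

so strongly correlated contacts are short, information-conducting edges.
The logarithm is natural; any other base would rescale all weights by a
constant, leaving shortest paths, betweenness ranking and communities
unchanged. |C| is floored at 1e-12 to keep weights finite, with a message
when flooring occurs.

Communities come from the Girvan--Newman procedure: repeatedly remove the
edge of highest weighted betweenness (weights act as path lengths, tied
shortest paths split equally) and keep the partition along the removal
sequence that maximises modularity. Because w is a distance, modularity is
evaluated with |C| = exp(−w) as the edge affinity -- modularity needs a
"strength", not a "length". Ties in betweenness resolve to the
lexicographically smallest edge and modularity ties to the earliest
partition, making the output deterministic. For every pair of communities
joined by at least one edge, the connecting edge of highest betweenness is
*critical* and its endpoints are the *critical nodes* -- the residues
mediating inter-community communication.

Displacements for the correlation matrix are taken after a two-pass Cα fit
to the ensemble mean (`node_trajectory(fit = TRUE)`); ensembles generated
directly in the fitted frame (as the synthetic generators do) may skip the
refit with `fit = FALSE`.

## PCA and anisotropic network model modes

`covariance_pca()` diagonalises the 3N × 3N covariance of the node
displacements (denominator n, matching the RMSF convention, so per-mode
RMSF contributions sum in quadrature to the total RMSF). The top 5 modes
are retained by default -- the usual essential-dynamics depth. Eigenvector
signs are fixed by making the largest-magnitude component positive.
`block_pca()` splits the trajectory into contiguous blocks and reports
cross-block mode overlaps as a sampling-convergence diagnostic: stationary
well-sampled motion gives overlaps near 1, unconverged noise near the
random-vector expectation 1/√(3N).

`anm_modes()` builds the standard anisotropic-network-model Hessian on a
single structure: uniform springs (γ = 1) between all pairs within 15 Å,
the common Cα-ANM default. A connected contact network is required (the
error names the components otherwise). Exactly six eigenvalues vanish for
a connected, genuinely three-dimensional structure (rigid-body invariance);
planar toy structures gain additional floppy out-of-plane zero modes,
which is why validation fixtures are helices or 3-D lattices. Internal
modes are reported ascending with the six rigid-body modes excluded. For
ANM modes the thermal amplitude scales as 1/λ, and `mode_rmsf()` uses that
scaling (PCA modes use λ directly).

## Interaction profiling

`detect_interactions()` applies geometric rules per frame between the
flagged ligand and the protein: hydrogen bonds at H···acceptor ≤ 2.5 Å with
donor angle ≥ 120° and acceptor angle ≥ 90°; hydrophobic contacts between
apolar carbons (no N/O/S neighbour within bonding distance) at ≤ 3.6 Å;
ionic contacts between oppositely charged group centroids at ≤ 3.7 Å; and
water bridges where one water is simultaneously hydrogen-bonded, under
relaxed criteria (2.8 Å, 110°), to both sides. A literal reading of
"contacts within 2 Å" sometimes seen in prose is sterically impossible for
heavy atoms; these thresholds follow the established
simulation-interaction-diagram conventions instead. Aromatic stacking is
folded into the hydrophobic class rather than separately typed. Bonds are
inferred once, by distance, on the first frame (H ≤ 1.2 Å to its nearest
heavy atom, heavy--heavy ≤ 1.7 Å); topologies without hydrogens disable
H-bond and water-bridge detection with a warning rather than failing.

`interaction_fractions()` counts, per (residue, category), the fraction of
frames with at least one event, and reports pairs at or above the 30%
threshold -- inclusive, so an interaction held for exactly 30% of the
period is reported. The threshold applies per category by default; a
`by = "residue"` flag pools categories per residue, since either reading
of "the residue interacted for ≥ 30% of the time" is defensible.

Torsions use the standard atan2 dihedral construction, signed in
(−180°, 180°], with 10° histogram bins normalised to unit mass; frames with
collinear atoms are skipped and counted.

## MM-GBSA bookkeeping

The energy layer consumes a long-format term table -- frame × entity
(complex, receptor, ligand) × term (coulomb, hbond, gb_solvation, vdw,
pi_pi, self_contact, lipophilic) -- because the native outputs of
commercial MM-GBSA pipelines are proprietary; any such output is a trivial
reshape away from this schema. Per frame,
ΔG = E_complex − (E_ligand + E_receptor), and the seven terms group into
electrostatic (coulomb + hbond + GB solvation), van der Waals
(vdw + π-π + self-contact) and lipophilic components that partition ΔG
exactly. Windowed summaries use the trailing fraction of frames (default
20%, mirroring the "last stretch of the combined trajectory" convention)
with sample (n−1) standard deviations -- the usual choice when the printed
tables do not specify. Relative energies ΔΔE subtract the most favourable
system, so exactly one system sits at 0 and the rest are ≥ 0. Favourable
contributions are negative throughout; published prose often quotes
magnitudes, so `residue_set_total()` keeps the sign and callers take
`abs()` where a magnitude is wanted. Note that one published summary is
internally inconsistent about the PPARβ mean (−135.9 vs −131.2 kcal/mol);
the shipped fixture uses the tabulated −135.9.

## Synthetic generators and what they do (not) show

All generators draw through one seeded, state-preserving RNG wrapper, so
outputs are byte-identical across runs and the caller's RNG state is never
disturbed.

* `sample_correlated_ensemble()` plants block correlations:
  Δr_i = σ_i(√ρ z_b + √(1−ρ) ε_i) per coordinate, giving intra-block
  correlation exactly ρ and RMSF σ√3. Defaults (σ = 0.5 Å, ρ = 0.6,
  5000 frames for measurement-grade runs) are chosen to sit in the range
  of equilibrated Cα fluctuations while keeping Monte-Carlo error well
  below the assertion tolerances.
* `sample_two_state()` plants discrete conformational states with *exact*
  populations (70/30 by default, 4 Å separation, 0.3 Å noise -- a cleanly
  separable two-pose scenario at the 2.5 Å cluster cutoff) and returns the
  true labels. The displaced set defaults to half the residues so that the
  static half can serve as a superposition anchor; a uniform whole-molecule
  displacement would be removed by fitting.
* `make_domain_reference()` builds compact cubic-lattice domains joined by
  single bridge contacts: at the 4.5 Å/75% contact criterion the graph is
  dense domains plus single bridges, the planted ground truth for
  community recovery.
* `make_energy_tables()` draws independent Gaussians per (entity, term)
  and returns the analytic ΔG mean and SD implied by the specification.
* `make_interaction_schedule()` is deterministic, hitting each target
  fraction exactly (floored to whole frames).

These ensembles are Gaussian, stationary and frame-independent. Real MD
trajectories are autocorrelated, anharmonic and drift; passing tests here
demonstrates that the estimators and graph algorithms are correct, not that
any particular biological system is well sampled. Published headline
numbers from microsecond simulations of undeposited trajectories are not
reproducible from this package; what is reproduced is the arithmetic on
their printed tables and the recovery of planted ground truth.

## Numerical choices and edge cases

* Kabsch: degenerate (rank < 2) point sets raise an error; the reflection
  case is handled by the determinant sign correction.
* Correlations: a zero-variance node makes C undefined; the error names
  the offending node(s). |C| is clipped into [−1, 1] against rounding.
* Betweenness: zero-weight edges (|C| = 1) are nudged to 1e-12 for the
  shortest-path solver; this changes no ranking.
* Clustering: `cutree`-style cutting at height = cutoff includes merges at
  exactly the cutoff ("merge while ≤ cutoff"); oracle comparisons in the
  tests draw cutoffs away from merge heights so both routes make identical
  stop decisions under floating point.
* Problem sizes in the validation suite (5000-frame measurement ensembles,
  300-frame clustering runs, ≤ 8-node exhaustive graph oracles, 50-seed
  recovery batches) were chosen so each check's Monte-Carlo error is well
  inside its tolerance while a full run stays desk-scale.

## Command-line use

`run_pipeline()` executes the stages in dependency order from a flat
YAML/JSON config (unknown keys are rejected; every parameter lands in the
run manifest), writing per-stage CSV/TSV outputs and a manifest JSON. A
thin wrapper script at `inst/scripts/trajcomm.R` exposes `info`, `run` and
the synthetic generators for shell use; the R functions remain the primary
interface.
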