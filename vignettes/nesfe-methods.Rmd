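---
title: "Methods: non-equilibrium switching free energies in nesfe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-equilibrium switching free energies in nesfe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nesfe)
```

# Overview

`nesfe` implements the desk-scale computational core of an automated
SMILES-to-ΔΔG relative binding free energy (RBFE) workflow built on
non-equilibrium switching (NES). In an NES protocol, one equilibrium
simulation is run at each physical end state of an alchemical
transformation, frames are extracted from the equilibrated part of those
trajectories, and many short driven transitions carry the system from one
end state to the other while the work done is recorded. The bidirectional
work samples feed a fluctuation-theorem estimator that yields the free
energy difference for the transformation; repeating this in the complex
and in water gives the relative binding free energy
ΔΔG = ΔG_complex − ΔG_water for each edge of a perturbation map, and a
graph-level analysis converts edge estimates into per-ligand binding free
energies comparable to experiment.

The docking and molecular dynamics engines themselves are out of scope:
`nesfe` consumes their file formats (SMILES/CSV ligand lists, SDF poses,
pmx-style two-column work files, dH/dλ traces) and ships synthetic
generators and mock backends that write the same formats, so every
analysis stage is exercised end to end without an engine.

# Free energy estimation from bidirectional work

## Work by thermodynamic integration

A switching trajectory records ∂H/∂λ along the driven path. The work is
the trapezoidal integral over λ in the traversal direction
(`integrate_work()`); the quadrature is exact for integrands linear in λ.
Integration is performed in λ, not time, so a non-linear λ(t) schedule
does not bias the work as long as the trace samples λ densely. A reverse
trace (λ from 1 to 0) integrates to the B→A work, which is how reverse
works are stored throughout the package (the pmx file convention); the
estimator negates them internally.

## The Crooks/Bennett maximum-likelihood estimator

The Crooks fluctuation theorem links the forward and reverse work
distributions, P_f(W) / P_r(−W) = exp(β(W − ΔG)) with β = 1/(k_B T). The
maximum-likelihood estimate of ΔG from n_f forward works W_f and n_r
reverse works W_r (stored as B→A work) is the root of the Bennett
self-consistency score

$$
\sum_{i=1}^{n_f} \frac{1}{1 + \tfrac{n_f}{n_r}\,
  e^{\beta (W_{f,i} - \Delta G)}}
\;-\;
\sum_{j=1}^{n_r} \frac{1}{1 + \tfrac{n_r}{n_f}\,
  e^{-\beta (-W_{r,j} - \Delta G)}} \;=\; 0 .
$$

The score is monotone increasing in ΔG, so `bar_estimate()` brackets the
root within `[min(W_f ∪ −W_r) − 50 k_BT, max(W_f ∪ −W_r) + 50 k_BT]` and
solves by plain bisection to 1e-10 kcal/mol — globally safe, with no
dependence on a starting guess.

Two numerical points deserve mention:

* **Overlap detection.** Mathematically the score always has a root
  (it runs from −n_r to +n_f). When the forward and reverse work
  distributions do not overlap, however, both Fermi sums underflow to a
  flat zero plateau in double precision and the bisection "root" is
  meaningless. `bar_estimate()` therefore evaluates both sums at the
  converged root and raises an `insufficient overlap` error when their
  total is negligible (< 1e-8). At a healthy root each sum is of order
  n/2.
* **Delta-function limit.** For equal-count point masses W_f ≡ a,
  W_r ≡ b the root is the CFT intersection (a − b)/2, which the tests
  pin exactly (a = 5, b = −5 gives ΔG = 5).

`jarzynski_estimate()` provides the one-directional exponential-average
estimator, computed with log-sum-exp stabilisation. It is used as an
independent validation oracle (for Gaussian works the closed form is
ΔG = μ − βσ²/2); it is biased at finite n under high dissipation and is
never used in the production path.

## Uncertainties: bootstrap and replicas

Per leg and replica, `bootstrap_se()` resamples W_f and W_r independently
with replacement (default `n_boot = 100`, seed required) and reports the
SD of the re-estimated ΔG. Replicas are combined by
`combine_replicas()` as

$$
\mathrm{se}^2 \;=\; \frac{s^2}{R} \;+\; \frac{\sum_i
\mathrm{se}_{\mathrm{boot},i}^2}{R^2},
$$

the standard error over the R replica means plus the propagated mean
bootstrap variance — both sources the replica protocol exposes. The exact
combination formula used by existing NES analysis tools is not published;
this one is declared, not claimed identical. For R = 1 the bootstrap SE
is passed through. Edge assembly (`edge_ddg()`) subtracts the water leg
from the complex leg and adds uncertainties in quadrature.

## Units and constants

Everything internal is kcal/mol and Ångström, with
k_B = 0.0019872041 kcal/(mol·K) and a default temperature of 298 K (the
simulation protocol the workflow emulates thermostats at 298 K). Work and
dH/dλ files are read in kJ/mol and converted at the boundary (÷4.184).

## Frame schedule

`frame_schedule(t_total, t_discard, n_frames)` returns
`t_discard + k·Δ` for `k = 1…n_frames` with
`Δ = (t_total − t_discard)/n_frames`: the discarded equilibration prefix
is excluded entirely and the last frame falls exactly at `t_total`. The
default protocol (6 ns production, first 2 ns discarded, 80 frames) gives
80 transition starts at exact 50 ps spacing.

# Ligand handling and pose selection

## Charges

Net formal charge is the sum of atomic formal charges of the parsed
structure — no protonation-state enumeration. Because charge-changing
edges are not supported downstream, `filter_to_single_net_charge()` keeps
the modal charge of a series and drops the rest. A tie for the modal
charge is an *error*, not an arbitrary pick: silently mixing charge
states would invalidate every edge crossing the tie, so the caller must
decide.

## Maximum common substructure

`compute_mcs()` finds the largest *connected, induced* common
substructure over heavy atoms by a McGregor-style branch-and-bound
search: the mapping grows along bonds from every compatible seed pair,
with an optimistic upper bound pruning subtrees that cannot beat the best
mapping found. Matching is element-exact; ring atoms match only ring
atoms, ring bonds only ring bonds, and aromatic systems only aromatic
systems — constraints that prevent chemically absurd aryl↔alkyl mappings.
Defaults: minimum 3 heavy atoms, 10 s search budget, up to 64
symmetry-equivalent mappings retained.

All mappings of maximal size are kept because aromatic rings admit
automorphic matches: evaluating the pose RMSD over every equivalent
mapping and taking the minimum means a benzene numbering flip cannot
inflate the deviation. Whether engine-side MCS filters consider symmetry
is generally undocumented; here the choice is explicit.

## Mapped RMSD without superposition

`mapped_rmsd()` computes the RMSD over mapped atom pairs *in the shared
receptor frame*, deliberately without superposition: docked and reference
poses live in the same crystal frame, and aligning them first would hide
exactly the binding-mode flips (reversed cores, flipped rings) the filter
exists to catch. For a rigid translation of norm d the mapped RMSD equals
d exactly — the property the synthetic pose generator exploits.
`select_best_pose()` returns the pose minimising the mapped RMSD, ties
broken by lowest pose index so engine rank order is preserved.

## Core SMARTS matching

`match_core()` verifies a manually specified core pattern and returns the
first match's atom indices. Because no installed R package exposes
atom-indexed SMARTS matches, `nesfe` ships a restricted SMARTS engine
(organic-subset and aromatic atoms, brackets with element/#n/charge/
R/H/D primitives and negation, bond symbols `- = # : ~`, branches, ring
closures) matched by subgraph isomorphism with per-atom candidate
domains. Unsupported constructs — OR (`,`), recursive SMARTS — raise an
error rather than silently mis-match. The test suite cross-checks match
presence against OpenBabel's independent SMARTS matcher.

Aromaticity is perceived with a simplified Hückel count on the kekulized
structure (rings of size 5–7 over C/N/O/S/P; in-ring double bond → 1 π
electron, heteroatom lone pair → 2, saturated carbon breaks the ring;
aromatic iff the total is 4n + 2). This covers the common heteroaromatics
(benzene, pyridine, pyrrole, furan, thiophene, imidazole and their fused
relatives) but is not a full valence model; exotic systems (azulenes,
mesoionics) may be mis-flagged.

# The perturbation map

`build_map()` scores all ligand pairs with
`mcs_similarity() = |MCS| / max(heavy_A, heavy_B)` and builds a minimum
spanning tree on distance 1 − similarity (Kruskal, ties broken by
lexicographic edge id), then greedily adds the highest-similarity
non-tree edges until every node reaches `target_degree` (default 2, so
every ligand lies on at least one cycle — cycles are what make
cycle-closure analysis possible). This transparent MST+augmentation
scheme replaces external mapping tools by design: it is deterministic,
fully testable, and guaranteed connected. A ligand with similarity 0 to
every other ligand cannot be connected and is reported by name.

Edges are stored with endpoints in lexicographic order and id
`source->target`; the direction is bookkeeping, not physics.

# From edges to absolute ΔG

## Cycle closure as weighted least squares

Noisy edge estimates do not sum to zero around cycles. The
thermodynamically consistent set closest to the measurements is the
weighted least-squares projection onto node potentials
(`solve_node_dgs()`): minimise Σ_e w_e (g_b − g_a − ΔΔG_e)² with
w_e = 1/max(se_e, 0.1)². The 0.1 kcal/mol floor keeps zero-SE edges from
acquiring infinite weight. The solution is defined up to a constant; the
gauge is fixed to mean(g) = 0 by solving (L + 11ᵀ/n) g = Bᵀ W ΔΔG, where
L is the weighted graph Laplacian. Node uncertainties come from the
diagonal of the Moore–Penrose pseudo-inverse of L. The fitted edge values
g_b − g_a close every cycle at machine precision — the same minimiser a
per-cycle redistribution scheme targets, realised in one linear solve.
`cycle_closure_errors()` reports the raw signed sums around a
spanning-tree cycle basis for diagnostics.

## Anchoring to experiment

Relative free energies fix only differences. `offset_to_experiment()`
adds one constant so that the mean calculated value over ligands with
experimental data equals the mean experimental affinity of the same
ligands — the congeneric-series convention. The offset is idempotent and
preserves all pairwise differences.

## Benchmark metrics

`compute_metrics()` reports AUE, RMSE, Pearson ρ and Kendall τ. τ is
tie-corrected (τ_b, as computed by `stats::cor`); sources rarely state
which variant they use, so the choice is made explicit here. 95%
confidence intervals come from a percentile bootstrap over (calc, exp)
pairs (`bootstrap_metric_ci()`, degenerate single-pair resamples
redrawn).

`experimental_null_band()` quantifies the performance ceiling set by
experimental noise: each draw simulates *two* independent replicate
measurements (exp + noise with SD max(σ_exp, 0.43) per ligand) and
computes each metric between them; the 2.5/97.5 percentiles over draws
form the band. Comparing two noisy replicates — rather than one replicate
against the noiseless values — is what "how well could a perfect
predictor score" means when the reference itself is noisy; it centres the
RMSE band near σ√2 (≈ 0.61 kcal/mol at the 0.43 kcal/mol best-practices
floor used when a series reports no uncertainties).

# Synthetic data: what it emulates and what it does not

`gen_cft_gaussian_works()` draws the unique equal-variance Gaussian pair
satisfying the Crooks relation for a given ΔG:
W_f ~ N(ΔG + βσ²/2, σ²) and W_r ~ N(−ΔG + βσ²/2, σ²) (at 298 K and
σ = 1 kcal/mol the forward mean is 2.8443 for ΔG = 2). The mean
dissipated work βσ²/2 plays the role of switching-speed-dependent
friction.

`gen_map_study()` emulates a mid-sized congeneric series: by default 27
ligands with true affinities uniform over a 4.3 kcal/mol span,
experimental noise at the 0.43 kcal/mol floor, edge noise 0.3 kcal/mol,
and target node degree 3 — production perturbation networks typically aim
for about 2–4 connections per ligand, and degree 3 gives every node
redundant paths without quadratic edge counts. The map is built by the
same MST+augmentation code the chemistry path uses, over a random
similarity matrix.

`perturb_poses()` produces rigid-body perturbations: rotation about the
centroid by an angle proportional to the displacement scale plus a random
translation of exactly that norm. Because the rotation is centred, RMSD²
decomposes into translation² + rotation², so the scale ordering *is* the
RMSD ordering — the property the pose-selection tests rely on — and with
rotation disabled the RMSD equals the translation norm analytically.

`mock_nes_backend()` writes pmx-style work files for both legs of an
edge, putting the full ΔΔG on the complex leg (water leg ΔG = 0). This is
a modelling convenience: the estimator only ever sees work values, never
leg labels, so the split is immaterial to what is being tested.

What the generators do **not** emulate: non-Gaussian work distributions
(bimodality from conformational trapping, heavy tails), correlated
transition starts from under-equilibrated trajectories, pose-quality
effects on work distributions, and finite-sampling artifacts of real MD.
Passing tests therefore demonstrate the correctness of the estimation
and graph machinery under its stated assumptions, not the accuracy of
any physical simulation.

# Workflow runner

`run_workflow()` executes a JSON-configured list of typed steps
(`synth_study`, `mock_nes`, `ingest_work`, `estimate_edges`,
`solve_graph`, `offset_experiment`, `metrics`, `report`, plus the ligand
and pose steps). Step outputs land in numbered subdirectories with a
`status.json` each and one structured log line per step; a failing step
halts the run with its name, retaining partial artifacts. Docking and MD
engine step types are reserved names that fail validation with a pointer
to the mock equivalents. The global seed is offset by step index so
steps draw independent streams; reruns with the same config and seed are
byte-identical. A thin command-line front end
(`inst/scripts/rbfe`: `run`, `analyse`, `synth`) wraps these functions.

# Problem sizes used in the test and acceptance suites

The routine test suite runs the workflow at 6 ligands / 20 transitions;
the acceptance suite runs the bundled fixture at full protocol size (10
ligands, 80 transitions × 3 replicas per leg and direction, dissipation
σ = 1 kcal/mol), 100-seed recovery experiments for the BAR estimator
(n = 1000 works) and the 20-node graph solve, 200-dataset coverage
experiments for the RMSE bootstrap CI (n = 40 pairs, 400 resamples), and
20-seed ranking experiments at edge noise 0.3 kcal/mol. These sizes were
chosen so each experiment's Monte-Carlo error is small relative to the
property being asserted while the whole suite stays interactive.

# Known limitations

* Aromaticity perception and the SMARTS dialect are deliberately
  restricted (see above); both error or under-match rather than silently
  mis-match, but exotic chemistry may need an external toolkit.
* The MCS is induced and connected; disconnected common substructures
  (two rings joined differently) score as their largest connected part.
* Gaussian-only synthetic works mean estimator robustness to heavy-tailed
  dissipation is untested here.
* The replica/bootstrap combination formula is declared, not matched to
  any specific external implementation.
* Map topology is built once from 2D similarity; it does not adapt to
  pose quality.
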