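---
title: "Models, numerics and design choices in DockPBSA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, numerics and design choices in DockPBSA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

DockPBSA models an antibody fragment bound to a protein antigen in four
stages — structure preparation, restricted rigid-body docking,
constraint screening, and ensemble MM-PBSA energetics — and validates all
of them against analytic oracles and planted synthetic ground truth. This
vignette records the models, the defaults and why they were chosen, the
numerical decisions, and what the validation does and does not establish.

## Structure preparation

Structures are atom tables keyed by `(chain, residue number, insertion
code)`. Antibody and antigen numbering schemes are discontinuous and use
insertion codes, so residue identity is never derived from arithmetic on
numbers: ordering always follows file order, and nothing ever renumbers.
Alternate locations keep the highest-occupancy conformer; waters and
glycans are ignored unless explicitly selected.

Protonation at neutral pH is assigned by rule: Asp/Glu side chains −1,
Lys/Arg +1, histidine neutral unless overridden. The neutral-His tautomer
(ND1-H vs NE2-H) is chosen to maximise hydrogen-bond geometry with polar
neighbours within 3.5 Å of the candidate donor nitrogen, with NE2-H as the
tie-break — a deliberately simple stand-in for a full pKa calculation,
which is out of scope. Terminal charges (+1/−1 per intact chain) cancel,
so the net formal charge equals the side-chain sum; this is the arithmetic
that fixes neutralising counterion counts. Counterions are placed greedily
at the highest-Coulomb-potential candidate grid sites subject to being
≥ 6 Å from every heavy-atom surface and ≥ 10 Å from each other.

Polar hydrogens (backbone amides, hydroxyls, amines, His ring nitrogens)
are placed at a uniform 1.0 Å bond length along idealised valence
directions. Using one bond length for N–H and O–H is a geometric
simplification: the downstream consumers (hydrogen-bond geometry,
distance-dependent-dielectric electrostatics) are insensitive to the
0.04 Å difference, and it gives the placement a single testable contract.
Cys thiols are not protonated (weak donors, not used by the analyses).

## Gas-phase energetics

Cross-part energies only: Coulomb with $k_e = 332.0636$ kcal·Å/(mol·e²)
(the CHARMM convention) and an atom-pairwise distance cutoff, and 12-6
Lennard-Jones with Lorentz–Berthelot combining under the standard cubic
switching function on 10–12 Å. Intramolecular terms and 1-4 exclusions
never arise because only inter-part interactions are computed. The shipped
amino-acid parameter table is deliberately simplified — CHARMM-like
backbone charges, unit charges localised on charged-group termini,
element-based LJ and cavity radii — and every test of the energy machinery
uses a small explicit toy table, so correctness never depends on the
shipped values.

## The Poisson–Boltzmann solver

$\Delta G_{solv}^{elec}$ comes from a finite-difference solution of the
linearized Poisson–Boltzmann equation with successive focusing:

* **Grids.** Cubic, `dime` points per side (production 321; tests and the
  toy fixtures use 33–65), focusing ladder of spacings 1.5 → 1.0 → 0.5 Å
  by default. The outermost grid takes analytic Debye–Hückel/Coulombic
  boundary values (the sum-of-monopoles condition); finer grids
  interpolate their boundaries from the coarser solution.
* **Discretisation.** Charges are spread with cubic B-splines (4-node
  support per axis, exact charge and first-moment conservation).
  Dielectrics live on cell edges; the solute/solvent transition is a
  cubic smoothstep of half-width 0.3 Å applied to the *reciprocal*
  dielectric (a harmonic blend), which preserves the series resistance
  across a radial boundary and is what makes the Born test pass at the
  half-percent level. Arithmetic blending of the dielectric itself biases
  the effective cavity inward by most of the smoothing window.
* **Iteration.** Red–black successive over-relaxation in compiled code,
  $\omega = 2/(1+\sin(\pi/n))$, relative tolerance $10^{-6}$; failure to
  converge is an error carrying the residual, never a silent result.
* **Self-energy removal.** Every solvated solve is paired with a
  homogeneous reference solve (solvent dielectric set equal to the solute
  value) on identical grids and charges; the reported energy is
  $\frac12\sum_j q_j[\phi_{solv}(r_j)-\phi_{ref}(r_j)]$ with potentials
  read back through the same B-spline weights used for spreading, so the
  grid self-energy cancels structurally.
* **Salt.** Ionic strength defaults to zero (plain Poisson). No salt
  concentration is part of the standard conditions here; the screening
  term is available as a configuration knob and adds
  $\varepsilon_{out}\bar\kappa^2 h^2$ to the diagonal on solvent nodes.

Validation: a Born ion ($q=1$ e, $R=2$ Å) is reproduced within 0.5 % at
the 0.5-Å focus, with error decreasing monotonically down the focusing
ladder; the solvation energy is invariant (≤ 1 %) under rigid motion of
the solute.

**Per-residue solvation.** The contribution of residue $i$ is
$\frac12\sum_{\text{all }q} q\,\phi_{(i)}(r)$, where $\phi_{(i)}$ is the
reaction-field potential sourced only by residue $i$'s charges on the
*same* dielectric maps. The explicit $\frac12$ is a deliberate convention:
the verbal definition of this quantity (charge times potential due to
residue $i$, summed over all charges) double-counts cross terms and would
sum to twice the total; with the $\frac12$, LPBE linearity makes the
contributions sum *exactly* to the total electrostatic solvation energy.
Residues with no charged atoms contribute identically zero and are
skipped.

## Docking

**Maps.** The receptor becomes two Gaussian occupancy maps on a 2-Å grid:
a narrow core map (σ = 1.2 Å) and a wide surface map (σ = 3 Å). The pose
score is `penalty · core − surface` summed over ligand heavy-atom
positions (trilinear interpolation, penalty weight 20). This is a
documented surrogate for surface complementarity: penetration of the core
is penalised, residence in the surface shell rewarded, and its acceptance
standard is planted-pose recovery, not agreement with any particular
published scoring function. An atom-subset argument restricts the map to,
e.g., atoms within 8 Å of the CDR loops.

**Start poses.** One pose per admissible strided grid point × starting
rotation (six deterministic orientations by default). Admissibility is a
cone test: the displacement direction from the receptor centre must lie
within the half-angle (default 60°) of the axis through the constraint
region. In `dockComplex` the axis runs from the epitope-residue backbone
centroid through the epitope side-chain centroid — the local outward
normal of the epitope face. This differs from using the whole-domain
centroid, which degenerates for elongated receptors (the two centroids
coincide and the axis direction becomes noise); for a compact globular
domain the two constructions agree.

**Grid-threading MC.** Each start runs cycles (default 50 × 20 steps) of
Metropolis moves — translations up to 0.8 Å (at most one grid cell) and
rotations up to 10° — at a low temperature (kT = 0.05 score units), each
cycle restarting from the best pose so far. The small proposals are the
point: the minimisation is *local*, so each start descends into its own
basin and the start grid, not the optimizer, is responsible for coverage.
The returned best-so-far score is non-increasing by construction and the
trajectory is bit-identical under a fixed seed.

**All-atom refinement.** Metropolis MC at 300 K on the cross interaction
energy (switched LJ plus distance-dependent-dielectric Coulomb,
$\varepsilon = r$): whole-ligand translations ≤ 0.3 Å or side-chain χ
rotations (about CA–CB, backbone frozen) of interface residues ≤ 30°,
torsions attempted twice as often as translations; interface residues are
fixed by the 5-Å heavy-atom criterion on the starting pose. A short local
minimisation follows — rigid-body pattern search, ≤ 200 evaluations on the
LJ term alone, then ≤ 300 including electrostatics — emulating a
minimiser cascade without implementing adopted-basis Newton–Raphson;
on rigid-backbone toy systems the rigid-body search captures what that
minimiser would do.

**Ranking.** Pose features are the energy components
(vdW, gas electrostatics, optional LPBE solvation, nonpolar solvation,
buried SASA). The default classifier is a linear-kernel SVM (`e1071`)
trained on generator-labelled decoys; the interface (`decision` values,
descending order, stable tie-break on input index) is the contract, so
any backend can be plugged in. The solvation feature can be disabled
(`pbConfig = NULL`) for fast triage; training and scoring must then use
the same feature definition.

## Screening

Constraints are evaluated independently and a pose is accepted iff none
is violated: required epitope contacts (5-Å heavy-atom contact list),
required residue pairs, 1:2 stoichiometry (a second ligand copy placed by
superposing the two receptor domains must produce no heavy-atom pair
within 2.5 Å of the antigen or the first copy), and a buried-area window
(default 1144–2500 Å², the observed range for antibody–antigen
complexes). "Best fits the evidence" is operationalised as: walk clusters
in rank order, and within the first cluster containing accepted poses
prefer most-constraints-satisfied, then rank. A screen with no surviving
pose returns an explicit no-model result rather than an error, because
that outcome is scientifically meaningful.

## Ensemble statistics

All interface statistics are means over frames of all runs:

* an **interface residue** has mean (over frames) *minimum* cross-part
  heavy-atom distance ≤ 5 Å — the per-frame minimum per residue pair is
  what makes the statistic residue-level;
* a **hydrogen bond** has mean H···acceptor distance ≤ 2.4 Å and mean
  D–H–A angle > 130°, with per-run occupancy reported as the fraction of
  frames passing both criteria per frame (the frame-mean criterion is the
  default; the per-frame-count reading is what the occupancy columns
  give, so both are available);
* a **van der Waals contact** holds within 4.0 Å in ≥ 50 % of frames in
  ≥ 2 independent runs — the replication requirement is across runs, not
  pooled frames.

Equilibration is checked as the backbone RMSD (interface-zone residues,
10-Å criterion) against the starting structure, with a plateau declared
when the least-squares slope over the final third is below 0.05 Å/ns.

## Clustered, population-weighted MM-PBSA

The single-trajectory approximation is used throughout: both parts are
cut from the complex frame, so there is no conformational-change term and
the cycle identity $\Delta G_{sln} = \Delta G_{gas} + \Delta G_{solv}$
holds exactly by construction on every frame. Within each run the
gas-phase electrostatic series (14-Å cutoff — used *only* for binning) is
sorted into 25 equal-width bins spanning [min, max]; "evenly distributed"
is read as equal-width rather than equal-population (the alternative is a
one-line change and the binning is isolated behind `clusterFrames`).
Representatives minimise the distance to their bin's member mean with
ties to the lowest frame index. Gas terms of the evaluated energies use a
999-Å cutoff. Weighting is by bin population within a run; across runs the
mean and sample standard deviation are reported.

The per-residue decomposition covers all residues of both parts:
(a) *half* the cross-part pairwise vdW + electrostatic energy of residue
$i$ — the halving mirrors the $\frac12$ in the solvation term and is what
makes $\sum_i \Delta G_{sln}(i)$ equal the total exactly rather than
twice it (summing full pair energies over the residues of one side only
is the other self-consistent convention; region sums over one side can be
doubled if that reading is wanted); (b) $\gamma\,[SASA_{bound}(i) -
SASA_{free}(i)]$, the bound-minus-free difference, so the nonpolar pieces
sum to $\gamma\,\Delta SASA$; (c) the bound-minus-free difference of the
residue-sourced reaction-field term. Gas terms in the decomposition use
the 999-Å cutoff of the totals, not the 14-Å binning cutoff — additivity
requires matching cutoffs. Entropy (−TΔS) is omitted throughout; the
reported ΔG_sln is an effective binding energy, comparable across
variants but not an absolute affinity.

## The synthetic-data generator

`makeToyComplex` builds a two-chain complex of simplified 4–5-atom
residues: the receptor presents a groove (floor plus two wall rows) and
the ligand lowers interaction tips into it, interdigitating between
receptor tips at ~3.6 Å with aperiodic complementary tip heights, so the
native arrangement is simultaneously the energetic optimum *and* the
shape-complementarity optimum, and no registration shift along the chain
is degenerate with it. Planted interactions realise exact geometry:
salt-bridge tips ±1 e at 2.8 Å, donor H 1.9 Å from the acceptor at ~180°,
vdW tips at 3.5 Å. `makeEnsemble` adds iid Gaussian coordinate noise
(σ = 0.15 Å default) in four runs with per-run sub-seeds; each planted
contact is held in a configurable fraction of frames (default 0.9,
attenuated noise) and broken in the rest (tip displaced 3 Å outward —
just past the contact criteria, so means remain dominated by the held
frames). `makeDecoys` labels small perturbations (< 4 Å heavy-atom RMSD)
positive and 8–20-Å displacements negative, recording the true RMSD.

What passing on these fixtures shows: the bookkeeping (cycle identity,
additivity, weights), the solver against analytic electrostatics, the
statistics against brute-force oracles, and that the search and the
decomposition recover planted ground truth. What it does not show:
behaviour on flexible loops, waters and ions, real force-field detail,
conformational strain, or the score landscape of genuinely globular
proteins — toy complexes are rigid, small and clean by design.

## Problem sizes and defaults used in validation

The shipped tests and the acceptance script run toy complexes of 4–6
residues per chain, ensembles of 4 runs × 6–40 frames (one bookkeeping
check generates 4 × 2000), PB grids of 49–65 points with focusing ladders
ending at 0.5–0.75 Å, and 25 or fewer energy bins (k = 3 on the small
ensembles, where at most three bins are occupied). These sizes were
chosen so each property is exercised at full fidelity on one CPU; all of
them scale by configuration, and the production-scale defaults (321-point
grids, 25 bins, 2000-frame runs) are the documented constructor defaults.

## Known limitations

* The shipped force-field table is simplified; quantitative agreement
  with a full additive force field is not expected and not claimed.
* The map score is a surrogate; it is validated by recovery behaviour,
  not by equivalence to any published grid-docking score.
* His protonation is rule-based; buried charged histidines require an
  explicit override.
* The LPBE solver is single-grid SOR per focus level — robust and exact
  enough at these sizes, but not a multigrid production solver for
  180,000-atom systems.
* No explicit water, no entropy, single-trajectory end states.
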