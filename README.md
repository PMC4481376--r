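# DockPBSA

Antibody–antigen complex modelling in R: restricted rigid-body docking
with Monte-Carlo refinement and classifier ranking, screening of candidate
poses against experimental epitope constraints, ensemble interface
statistics, and a clustered, population-weighted MM-PBSA binding
free-energy calculation with per-residue decomposition — built on an
internal finite-difference linearized Poisson–Boltzmann (LPBE) solver.

## Who this is for

Structural bioinformaticians who need to (i) assemble a model of an
antibody fragment bound to its antigen when no complex structure is
deposited, (ii) decide which docked model is consistent with mutagenesis,
stoichiometry and buried-surface evidence, and (iii) attribute the binding
free energy of the resulting complex to individual epitope residues using
conformational ensembles. The motivating application is anti-IgE antibody
engineering, where the receptor-blocking mechanism is read off the
per-residue energetics of the IgE-Fc/antibody interface, but every stage
is generic over two-part protein complexes.

## The methods in brief

**Docking.** The receptor is converted to Gaussian occupancy maps (2-Å
grid). Ligand start poses are enumerated at strided grid points inside a
60° cone around the axis through the epitope, with six starting rotations
each. Each start is minimised by grid-threading Monte Carlo on a
surface-complementarity map score, refined with all-atom Metropolis MC
(0.3-Å translations, ≤30° side-chain torsions of interface residues,
torsions attempted 2:1 over translations, 300 K) plus a short local
minimisation, featurised by its energy components
(ΔE_vdw, ΔE_elec, ΔG_solv^elec, ΔG_solv^nonpol, buried SASA), and ranked
by a linear support-vector classifier trained on labelled synthetic
decoys.

**Screening.** Top-ranked poses are clustered at 4-Å Cα RMSD and tested
against a `ConstraintSet`: required epitope contacts (5-Å heavy-atom
criterion), 1:2 stoichiometry feasibility via a symmetry-placed second
ligand copy (2.5-Å clash test), and a buried-surface-area window
(default 1144–2500 Å²).

**MM-PBSA.** For each of four independent ensemble runs, frames are sorted
into 25 equal-width bins of the gas-phase electrostatic interaction energy
(14-Å cutoff); each bin's representative (closest to the bin mean) is
evaluated with the thermodynamic cycle

    ΔG_sln = ΔG_gas + ΔG_solv,   ΔG_gas = ΔE_vdw + ΔE_elec (999-Å cutoff),
    ΔG_solv = ΔG_solv^elec (LPBE) + γ·ΔSASA (γ = 8 cal/mol/Å²)

and population-weighted within the run; runs are averaged with a standard
deviation. The LPBE is solved by successive-focusing finite differences
(dielectrics 1/78.54, cubic B-spline charge spreading, spline-smoothed
dielectric boundary, SOR relaxation in compiled code). Per-residue
contributions combine half the pairwise gas terms, γ·ΔSASA(i), and the
residue-sourced reaction-field term, and sum to the total by construction.

## Worked example

Everything below runs from generated data — no downloads.

```r
library(DockPBSA)

cfg <- generatorConfig(seed = 1, nResidues = 4,
                       planted = data.frame(pos = 2, type = "salt-bridge"),
                       framesPerRun = 6)
toy <- makeToyComplex(cfg)        # two-chain complex + parameter table
ens <- makeEnsemble(toy, cfg)     # 4 runs x 6 frames around it

pb <- pbConfig(dime = 49L, spacings = c(1.5, 0.75))
be <- mmpbsaBindingEnergy(ens, "A", "B", toy$params, pb, k = 3)
round(c(dG = be$mean, sd = be$sd), 2)
#>    dG    sd
#> -10.30  0.53

pr <- perResidueDecomposition(ens, "A", "B", toy$params, pb, k = 3)
head(pr[order(pr$dG), c("key", "dG", "sd")], 3)
#>        key    dG    sd
#> 6 B:2::SBN -2.74 0.227
#> 2 A:2::SBP -1.63 0.177
#> 7 B:3::NEU -1.25 0.108
```

The binding free energy of the toy complex is −10.3 ± 0.5 kcal/mol across
the four runs, and the decomposition correctly attributes the largest
favourable contribution to the planted salt-bridge residues (`SBN`/`SBP`),
with gas-phase attraction (≈ −57 kcal/mol per side) mostly cancelled by
the electrostatic desolvation penalty — the signature balance of MM-PBSA
per-residue energetics.

Docking the same toy from scratch:

```r
rec <- selectAtoms(toy$complex, "A"); lig <- selectAtoms(toy$complex, "B")
dec <- lapply(makeDecoys(toy, cfg), scoreFeatures,
              receptor = rec, ligand = lig, params = toy$params)
model <- trainRanker(do.call(rbind, lapply(dec, function(p) p@features)),
                     vapply(dec, function(p) p@provenance$label, TRUE))
top <- dockComplex(rec, lig, toy$params,
                   epitopeResidues = residueKeys(rec)[toy$truth$pos],
                   model = model, seed = 1)
rmsd(applyTransform(coords(lig)[isHeavy(lig), ], top[[1]]@transform),
     coords(lig)[isHeavy(lig), ])
#> [1] 1.818398   # rank-1 pose < 2 A from the planted native
```

## Package layout

| Area | Functions |
|---|---|
| Structure I/O & preparation | `readPDB`, `writePDB`, `selectAtoms`, `assignProtonation`, `addHydrogens`, `formalCharge`, `placeCounterions` |
| Geometry | `superpose`, `rmsd`, `rmsdCA`, `clusterByRMSD`, `shrakeRupley`, `clashAtoms`, `sasaChangeOnBinding` |
| Gas-phase energetics | `coulombEnergy`, `ljEnergy`, `gasEnergy`, `residuePairwiseEnergy`, `defaultParameterSet` |
| Poisson–Boltzmann | `solveLPBE`, `spreadCharges`, `dielectricMap`, `residueSolvation`, `nonpolarSolvation`, `pbConfig` |
| Docking | `buildMap`, `receptorMaps`, `enumerateStartPoses`, `gridThreadingMC`, `mcRefine`, `scoreFeatures`, `trainRanker`, `rankPoses`, `dockComplex` |
| Screening | `contactList`, `constraintSet`, `checkPose`, `buildSecondCopy`, `screenRanked`, `superpositionClashTest` |
| Ensemble analysis | `ensemble`, `interfaceResidues`, `hydrogenBonds`, `vdwContacts`, `equilibrationCheck` |
| MM-PBSA | `gasElecSeries`, `clusterFrames`, `frameEnergy`, `weightedBindingEnergy`, `mmpbsaBindingEnergy`, `perResidueDecomposition`, `epitopeRegionSum` |
| Synthetic data | `generatorConfig`, `makeToyComplex`, `makeEnsemble`, `makeDecoys`, `toyParameterSet` |

The methods vignette (`vignettes/methods.Rmd`) documents the models,
defaults, numerical choices and limitations in detail.
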