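# sgdml

Symmetrized gradient-domain machine-learned force fields in R.

The package builds molecular force fields from reference forces by kernel
ridge regression in the gradient domain, after automatically discovering the
permutational symmetries of the molecule from the training conformations
themselves. A trained model predicts energies and forces for new geometries
and can drive classical molecular dynamics to extract observables such as
dihedral-angle distributions, conformer occupations, and vibrational spectra
from velocity autocorrelation functions.

## What it does

1. **Data handling** — extended-XYZ reading/writing of conformational
   datasets with optional energy/force labels, plus subsampling that
   preserves the energy (Boltzmann) distribution of the source trajectory.
2. **Symmetry discovery** — for pairs of conformations, the interatomic
   distance matrix is used as a molecular-graph representation; a bipartite
   assignment between the two atom sets is found by eigenvector-overlap
   matching refined to the exact least-squares objective, with a charge
   penalty preventing matches between different elements. The pairwise
   assignments are made globally consistent by transitive closure over a
   minimum-spanning tree of the matching costs, and the recurring
   relabelings that survive a cost threshold become the symmetry set.
3. **Training** — closed-form solution of a force-only kernel ridge
   regression with a Matérn-5/2 kernel over inverse-distance descriptors.
   The symmetrized kernel sums Hessian blocks over the recovered
   permutations, so one coefficient set serves all symmetry images of each
   training point. Energies come from the same model up to an integration
   constant fitted as the mean residual. Hyper-parameters are chosen by
   grid-search cross-validation on held-out forces.
4. **Prediction and errors** — analytic energies and forces for new
   geometries (forces are exactly the negative gradient of the predicted
   energy), with MAE/RMSE reporting against labeled test sets.
5. **Molecular dynamics** — velocity-Verlet NVE and Langevin NVT in
   Angstrom/fs/amu/kcal-mol units, with dihedral histograms, basin
   occupations, and VACF power spectra.
6. **Synthetic systems** — idealized benzene, naphthalene, ethanol and
   malonaldehyde templates, plus analytic spring-network toy potentials with
   exact forces and known symmetries, so the whole pipeline can be validated
   self-contained.

## Worked example

Discover the symmetries of ethanol from 50 thermally perturbed
conformations whose methyl and hydroxyl groups rotate over the full circle:

```r
library(sgdml)

ethanol <- build_geometry("ethanol")
torsions <- list(
  list(idx = c(1, 2, 3, 4), moving = 4,   mode = "uniform"),  # hydroxyl
  list(idx = c(3, 2, 1, 7), moving = 7:9, mode = "uniform")   # methyl
)
ds <- sample_conformations(ethanol, 50, cartesian_noise = 0.03,
                           torsion_sampling = torsions, seed = 1)
syms <- extract_symmetries(ds)
length(syms)
#> [1] 6
```

The six permutations are the identity, the hydroxyl-H/methyl-H exchanges of
the three-fold methyl rotation, and their combinations with the CH2 swap —
exactly the physically realizable relabelings for this molecule (atoms 5–6
are the CH2 hydrogens, 7–9 the methyl hydrogens):

```r
syms$perms[[2]]
#> [1] 1 2 3 4 6 5 7 9 8
```

Train a model on an analytic toy (a methyl-rotor spring network with exact
forces), using cross-validation for the kernel width, and evaluate it:

```r
rotor <- make_toy_pes("rotor_molecule")
data <- sample_conformations(rotor, 120, cartesian_noise = 0.04,
                             torsion_sampling = list(list(idx = c(3, 1, 2, 4),
                                                          moving = 4:6,
                                                          mode = "uniform")),
                             seed = 7)
sp <- split_dataset(data, n_train = 60, n_valid = 20, n_test = 40, seed = 7)
rsyms <- extract_symmetries(sp$train)
model <- cross_validate(data, sigma_grid = c(1, 2, 4), n_train = 60,
                        n_valid = 20, seed = 7, syms = rsyms)
test_errors(model, sp$test)
#> $F_mae            0.362   # kcal/mol/Angstrom
#> $F_rmse           0.573
#> $F_atom_norm_mae  0.740
#> $E_mae            0.0349  # kcal/mol
#> $E_rmse           0.0486
```

Run Langevin dynamics with the trained model and measure torsion-basin
occupations:

```r
cfg <- md_config(dt = 0.2, n_steps = 2000, ensemble = "nvt",
                 temperature = 300, friction = 2, seed = 7)
traj <- run_md(model, rotor$template, cfg, z = rotor$z)
angles <- apply(traj$R, 1, function(R) dihedral_angle(R, c(3, 1, 2, 4)))
minima_occupations(angles, boundaries = c(-180, -60, 60, 180))
#> [1] 0.378 0.043 0.579
```

## Command line

A thin CLI wrapping the same functions ships in `inst/cli/sgdml.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "sgdml.R", package = "sgdml"))')" \
    make-fixtures --molecule ethanol --n 50 --seed 1 --out ethanol.xyz
Rscript .../sgdml.R discover --dataset ethanol.xyz --out perms.txt
Rscript .../sgdml.R train    --dataset labeled.xyz --symmetries perms.txt --out model.rds
Rscript .../sgdml.R test     --model model.rds --dataset test.xyz
Rscript .../sgdml.R predict  --model model.rds --xyz geom.xyz --out pred.xyz
```

## Units and conventions

* Coordinates in Angstrom, energies in kcal/mol, forces in kcal/mol/Angstrom,
  time in fs, masses in amu.
* Forces are labels, not gradients: `F = -dE/dR` throughout.
* Dihedral angles in degrees in `(-180, 180]`.
* A permutation `s` relabels a geometry as `R[s, ]`; trained models store the
  recovered symmetry set and apply it inside the kernel.

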