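---
title: "Symmetrized gradient-domain force fields: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symmetrized gradient-domain force fields: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgdml)
```

This vignette describes the methods implemented by the package: how
permutational symmetries are discovered from data, how the symmetrized
force-field kernel is trained in closed form, and how the trained model is
used for prediction and dynamics.

## 1. Descriptor and kernel

A geometry $R \in \mathbb{R}^{N\times3}$ is represented by the vector of
inverse interatomic distances
$$ D_{ij}(R) = \frac{1}{\lVert r_i - r_j \rVert}, \qquad i < j, $$
which is invariant under rigid motions and makes atom permutations act as a
simple index remap of the descriptor entries. Regression uses the Matérn
kernel with half-integer parameter $\nu = 5/2$,
$$ \kappa(D, D') = \left(1 + s\,d + \tfrac{s^2 d^2}{3}\right) e^{-s d},
   \qquad d = \lVert D - D' \rVert,\; s = \sqrt{5}/\sigma, $$
chosen because the model is trained on *derivatives*: a force-field estimate
requires a kernel that is at least twice differentiable, and $\nu = 5/2$ is
the least smooth Matérn kernel with that property, avoiding the
over-smoothing of a Gaussian kernel.

Training happens in the gradient domain. The covariance between force
components of two geometries is the Hessian of the kernel pulled back
through the descriptor Jacobian $J = \partial D/\partial x$:
$$ K_{ab}(R, R') = J(R)^{\mathsf T}\,
   \nabla_D \nabla_{D'}\, \kappa\big(D(R), D(R')\big)\, J(R'), $$
a $3N \times 3N$ block with the closed-form Matérn Hessian
$\nabla\nabla' \kappa = -(g_1 I + h\, u u^{\mathsf T})$ where
$g_1 = -\tfrac{s^2}{3}(1 + s d)e^{-sd}$, $h = \tfrac{s^4}{3} e^{-sd}$, and
$u = D - D'$. Every derivative in the package is validated against central
finite differences in the test suite.

## 2. Symmetry discovery

Physically equivalent atom relabelings (e.g. a methyl rotation) appear in
thermal conformation sets as pairs of geometries whose interatomic distance
matrices coincide up to a permutation. The discovery pipeline recovers them
in four steps.

**Pairwise matching.** For two conformations with distance (adjacency)
matrices $A_G$, $A_H$, the best relabeling minimizes
$$ L(\tau) = \lVert P(\tau) A_G P(\tau)^{\mathsf T} - A_H \rVert_F^2 . $$
An initial assignment comes from the overlap of the eigenvector matrices,
$M = |U_G|\,|U_H|^{\mathsf T}$ (absolute values resolve the eigenvector sign
ambiguity), solved as a linear assignment on the cost $-M + |\Delta z|\,
\varepsilon$, where the charge penalty $\varepsilon$ (100 times the largest
distance entry) prevents matching different elements. Because the
eigenvector overlap is unreliable when eigenvalues are nearly degenerate
(aromatic rings are the worst case), the assignment is then refined on the
exact objective: iterated linear assignments on the linearization of
$L(\tau)$, followed by a charge-preserving pairwise-swap descent, restarted
from the identity when the compositions agree. The tests verify that the
refined assignment attains the exhaustive $N!$ minimum on hundreds of random
fixtures.

**Synchronization.** Pairwise matches are individually noisy and need not be
mutually consistent. A minimum-spanning tree over the matching costs keeps
only the most reliable assignments, and transitive closure through the tree
($\tau_{ij} = \tau_{1j} \circ \tau_{i1}$) produces a globally consistent
set: after synchronization, transitivity holds exactly, by construction.

**Canonicalization and extraction.** Each raw pairwise match, expressed
between the canonicalized (synchronized) geometries, becomes a candidate
symmetry $\sigma$. Candidates are kept when their matching cost does not
exceed twice the median cost of identity pairs, which filters spurious
matches caused by thermal noise. The surviving distinct permutations, with
the identity, form the symmetry set. Because the recovered set reflects the
motions actually present in the data, symmetries that the trajectory never
realizes are deliberately *not* added: transpositions that would require
bond breaking are absent, which is the desired behavior.

```{r symmetries}
ethanol <- build_geometry("ethanol")
torsions <- list(
  list(idx = c(1, 2, 3, 4), moving = 4,   mode = "uniform"),
  list(idx = c(3, 2, 1, 7), moving = 7:9, mode = "uniform")
)
ds <- sample_conformations(ethanol, 50, cartesian_noise = 0.03,
                           torsion_sampling = torsions, seed = 1)
length(extract_symmetries(ds))
```

## 3. Symmetrized training

Given training geometries $\{R_p\}_{p=1}^M$ with force labels and a symmetry
set $\{\sigma_q\}_{q=1}^S$, the symmetrized kernel block between two
training points averages over both symmetry arguments:
$$ K^{\text{sym}}(R, R') = \frac{1}{S} \sum_{p=1}^{S} \sum_{q=1}^{S}
   P_p^{\mathsf T}\, K\big(\sigma_p R,\; \sigma_q R'\big)\, P_q , $$
so a single coefficient vector serves all $S$ symmetry images of every
training point — the effect of training on the $M\cdot S$ explicitly
permuted dataset at the cost of $M$ points. The test suite checks this
contraction identity directly: predictions from the contracted model and
from a model trained on the explicitly duplicated dataset agree to
$10^{-8}$ relative.

The coefficients solve the regularized normal equations
$(K^{\text{sym}} + \lambda I)\,\alpha = y$ with $y$ the stacked force
labels; the Cholesky solve escalates the jitter automatically if the system
is numerically rank deficient. Energies are integrals of the force model and
are recovered from the same coefficients up to a constant, fitted as the
mean residual against the training energies. The kernel width $\sigma$ (and
optionally $\lambda$) is selected by grid search against held-out validation
forces.

At prediction time the query geometry is *not* permuted; the symmetry sum
runs over the training argument only:
$$ \hat f(R) = \sum_{i=1}^{M} \sum_{q=1}^{S}
   K\big(R,\; \sigma_q R_i\big)\, P_q\, \alpha_i . $$
Predicted forces are exactly the negative gradient of the predicted energy
(one analytic functional differentiated once resp. twice), so the model is
energy conserving by construction; rigid-motion invariance is inherited from
the descriptor.

## 4. Dynamics and observables

The MD engine integrates Newton's equations with velocity Verlet (NVE) or
adds an exact Ornstein–Uhlenbeck velocity update as a Langevin thermostat
(NVT), in Angstrom/fs/amu/kcal-mol units. Observables:

* joint dihedral-angle histograms over a trajectory,
* occupations of torsional basins given basin boundaries,
* vibrational spectra as the cosine transform of the (Hann-windowed,
  unbiased) velocity autocorrelation function, reported in cm$^{-1}$.

The tests pin these against closed forms: the harmonic-dimer oscillation
period matches $2\pi\sqrt{\mu/k}$ to 0.5%, total energy shows no secular
drift over $10^4$ NVE steps, the thermostat reaches the target temperature
within 5% over $10^5$ steps, and the VACF spectrum peaks at the analytic
normal-mode frequency within one grid bin.

## 5. Validation strategy

Every layer has an independent oracle: finite differences for the
descriptor Jacobian, kernel Hessian, dihedral gradients and predicted
forces; exhaustive enumeration for the assignment solver; explicit
double-sum evaluation for the symmetrized kernel algebra; hand-computable
closed forms for the dynamics; and known symmetry counts for the synthetic
molecules (benzene 12, naphthalene 4, ethanol 6). The `tests/testthat`
directory doubles as a specification of all of these properties.
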