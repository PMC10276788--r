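---
title: "Methods: end-point binding free energies with liece"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: end-point binding free energies with liece}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liece)
```

## The model

`liece` implements the linear interaction energy with continuum
electrostatics (LIECE) approach to protein–ligand binding free energies,
an end-point method: only the bound complex and the free partners enter,
no alchemical intermediates and no sampling. Molecular-dynamics averaging
is replaced by energy minimization, and explicit solvent by a
finite-difference Poisson continuum. The predicted affinity is a linear
combination of three interaction terms,

$$\Delta G_{\mathrm{pred}} \;=\; \alpha\,\Delta E_{\mathrm{vdW}}
 \;+\; \beta\,\Delta E_{\mathrm{coul}}
 \;+\; \gamma\,\Delta G_{\mathrm{solv}} \;(+\;\delta),$$

where each $\Delta$ term is the complex − protein − ligand difference of a
component energy, and the scaling factors $\alpha,\beta,\gamma$ (and the
optional intercept $\delta$) are fitted by ordinary least squares against
experimental affinities converted with
$\Delta G_{\mathrm{exp}} = RT\,\ln K_i$ at $T = 298\,$K on the 1 M
standard state ($R = 1.9872\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$). The
central physical assumption is that, within a congeneric ligand series
binding one receptor conformation, the neglected terms (entropy, internal
strain beyond relaxation, protein reorganization) are either roughly
constant or linear in the retained terms, so they are absorbed by the
fitted coefficients.

Four model variants are supported: all three regressors or the van der
Waals term alone, each with the intercept free (`*_int`) or constrained to
zero (`*_noint`). The vdW-only variants exist because, in fitted models,
the Coulombic and desolvation contributions often nearly cancel, leaving
their coefficients small and ill-determined.

## Energy terms

**van der Waals.** Lennard-Jones sum
$\varepsilon_{ij}[(r^{min}_{ij}/r)^{12} - 2(r^{min}_{ij}/r)^{6}]$ with
Lorentz–Berthelot combination, truncated sharply at 14 Å (no switching or
shifting; the protocol specifies only a cutoff). Pairs beyond the cutoff
contribute exactly zero.

**Coulomb.** Vacuum electrostatics $k_e q_i q_j / r$ with
$k_e = 332.0636$ kcal Å mol$^{-1}$ e$^{-2}$, no cutoff and no
distance-dependent dielectric: all solvent screening lives in the
desolvation term, so double counting is avoided.

**Desolvation.** The electrostatic solvation free energy of each
component from a finite-difference Poisson solve,
$\nabla\!\cdot(\varepsilon\nabla\phi) = -4\pi k_e\rho$, with interior
dielectric 1.0 and exterior 78.5, zero ionic strength (Poisson, not
Poisson–Boltzmann). Two-level focusing is used: a coarse solve at 1.0 Å
spacing on a grid extending 10 Å beyond the solute feeds boundary
potentials to a fine solve at 0.4 Å over the solute bounding box plus
4 Å. The grid self-energy is removed by a reference solve on the
*identical* fine grid with the exterior dielectric set equal to the
interior one, using the same focusing protocol, so that boundary and
discretization artifacts cancel in the difference
$G_{\mathrm{solv}} = \tfrac12\sum_i q_i\,[\phi_{\mathrm{solv}}(x_i) -
\phi_{\mathrm{ref}}(x_i)]$.

### Numerical choices in the Poisson solver

* The dielectric boundary is the union of atom spheres at their Born
  radii — no solvent-excluded-surface construction; probe effects are
  considered folded into the radii. This keeps the boundary deterministic
  and testable against the Born closed form.
* Face dielectrics are *harmonically smoothed*: each face value is the
  harmonic mean along the grid segment it controls, with the fraction of
  the segment inside the sphere union estimated by a fixed 8-point
  deterministic sampling. A binary face-center assignment was measured at
  a 3.8% Born-ion error at 0.4 Å focusing; harmonic smoothing reduces it
  to about 0.2%, and the error decreases monotonically through 0.8, 0.6
  and 0.4 Å spacings. The test suite asserts both properties.
* Charges are spread to the eight surrounding nodes by trilinear weights
  (conserving total charge to $10^{-10}$ e); Dirichlet boundary values use
  the screened-Coulomb approximation
  $\phi = k_e \sum_i q_i/(\varepsilon_{\mathrm{ext}} r_i)$.
* The symmetric 7-point system is solved by Jacobi-preconditioned
  conjugate gradients to a relative residual of $10^{-6}$.
* A caveat on the uniform-medium limit: for a point source registered
  exactly on a grid node, the discrete Green's function of the 7-point
  stencil deviates from $k_e/r$ by up to ~4% on the nearest
  off-axis shell ($r = 3h$), a known lattice-anisotropy effect that decays
  with distance. Generic (off-node) source positions, whose charge is
  trilinearly spread, stay within 3% from three spacings outward; the
  suite checks this generic case.

## Minimization

Each component can be relaxed before the single-point evaluation with up
to 500 steepest-descent steps followed by up to 1000 Polak–Ribière
conjugate-gradient steps (Armijo backtracking line search), stopping when
the gradient RMS falls to 0.001 kcal mol$^{-1}$ Å$^{-1}$. The objective is
the nonbonded energy plus harmonic positional restraints
(k = 10 kcal mol$^{-1}$ Å$^{-2}$) to the input coordinates. The restraints
stand in for bonded force-field terms, which this package deliberately
does not implement: bonded contributions largely cancel in the
complex − protein − ligand difference, and restrained Cartesian relaxation
preserves the protocol's role (strain relief) without a full force field.
This is the principal fidelity gap relative to a full molecular-mechanics
treatment, and the reason the package's energies are validated by
closed-form and brute-force oracles rather than against any published
per-ligand energy table. By default the complex is minimized as a whole
and split at its relaxed coordinates, while the free protein and ligand
are relaxed separately from their input coordinates — mirroring a
protocol in which receptor, ligands and complexes are each minimized.

## Pose filters

Docking poses enter the energy calculation only after geometric
screening, a deterministic surrogate for visual pose inspection. A pose is
accepted iff

1. at least one ligand cationic nitrogen (partial charge ≥ +0.5 e) forms
   a salt bridge (minimum N–O distance ≤ 4.0 Å) to the carboxylate
   oxygens of the configured anchor residue — for aminergic GPCRs, the
   conserved D3.32 aspartate, addressed by its author-supplied residue
   number (no generic-numbering engine is built);
2. no buried polar ligand atom (fractional exposure < 0.1) lacks a
   hydrogen-bond or ionic partner (hydrogen bonds: donor–acceptor heavy
   distance ≤ 3.5 Å and D–H···A angle ≥ 120° where hydrogens are present;
   distance criterion alone otherwise);
3. the exposed apolar fraction — accessible surface of the ligand's
   carbons in the complex relative to the free ligand — is ≤ 0.5.

Rejections carry *every* violated constraint as a reason code. The
numeric thresholds are conventions of structural-biology practice, not
quantities fitted to any data set; they are configurable in
`filter_rules()` and cannot be validated against published cutoffs, which
are not stated for visual inspection. Exposure uses a Shrake–Rupley-style
numeric surface with a fixed, seedless 92-point spherical Fibonacci
lattice and a 1.4 Å probe, so filtering is bit-reproducible.

## Fitting and stability statistics

All fits are closed-form least squares (`stats::lm`); no iterative
optimizer and no randomness. Conventions decided where the reporting was
ambiguous:

* $R^2 = 1 - SS_{res}/SS_{tot}$ with $SS_{tot}$ about the mean of the
  observations for *every* variant, including through-origin fits. A
  single convention keeps intercept and no-intercept columns comparable;
  through-origin $R^2$ would not be.
* Leave-one-out stability: the model is refitted $n$ times leaving out
  one ligand. Coefficient spread uses the population (divide-by-$n$)
  standard deviation by default, with the sample normalization available
  by flag. The $\langle\Delta\Delta G\rangle$ statistic defaults to the
  signed mean, over folds, of (full-model − leave-one-out) predictions
  *for the left-out ligand*; an alternative convention averaging over all
  ligands in every fold is implemented behind `ddg_mode = "all"`, since
  the published footnote admits both readings. Neither is asserted to be
  the published convention.

## The synthetic-data layer

Because docking and binding assays are out of scope, the package
generates its own inputs:

* `gen_energy_table()` draws energy terms uniformly from configurable
  ranges and builds $\Delta G_{\mathrm{exp}}$ from a known linear model
  plus Gaussian noise. Defaults ($\alpha = 0.18$, $\beta = 0.018$,
  $\gamma = 0.06$, $\delta = 0$, $n = 50$, noise 0.5 kcal/mol, vdW in
  [−60, −25], Coulomb in [−20, −5], desolvation in [8, 25] kcal/mol)
  emulate the qualitative structure of fitted models on real series — a
  dominant, positive vdW coefficient roughly an order of magnitude above
  the electrostatic one, favorable (negative) vdW and Coulomb terms, a
  positive desolvation penalty, and affinities spanning a few kcal/mol
  with measurement-scale noise. They are a stylized emulation, not a
  claim about any real data distribution.
* `gen_toy_complex()` builds a rigid spherical carbon cage (radius 5 Å,
  open mouth) with an anionic carboxylate-like oxygen pair at the bottom
  and a cationic-amine ligand placed 3–4 Å from it, fully parameterized
  from an element-keyed table. Its component energies are small enough to
  brute-force, which is exactly how the tests hold the energy engine to
  account.
* `gen_decoy_pose()` produces poses guaranteed to fail a named filter
  constraint (a 180° flip breaking the anchor salt bridge — an involution,
  so flipping twice restores acceptance; burying the solvent-facing polar
  oxygen; sliding the apolar chain out of the mouth).

All generators are pure functions of their spec, seed included
(Mersenne-Twister with inversion normals, explicitly set and restored),
so identical specs give byte-identical outputs and cross-language
reimplementations can match them given the same generator.

What passing synthetic tests demonstrate — and what they do not: they
verify the statistical machinery (exact interpolation of noiseless
tables, coefficient spread matching ordinary-least-squares sampling
theory within 15%, leave-one-out bookkeeping) and the physics engine
against closed forms. They do not demonstrate predictive accuracy on real
receptor–ligand data, which depends on pose quality and force-field
fidelity outside this package's scope.

## Problem sizes

The shipped tests and the acceptance script run at deliberately desk-size
scales: Born-ion grids of roughly $21^3$–$29^3$ fine nodes, toy complexes
of ~55 atoms (six Poisson solves in a few seconds), 50-ligand synthetic
tables with 200 replicate refits. These sizes were chosen to make every
expected value recomputable from scratch at interactive speed while still
exercising each code path; the engine itself has no hard-coded size
limits.

## Known limitations

* No bonded force field; restrained Cartesian relaxation only.
* No nonpolar (cavity/SASA) solvation term, no salt, no periodic
  boundaries, no entropy estimate.
* The dielectric boundary is a union of Born spheres, not a
  solvent-excluded surface; radii must absorb probe effects.
* Published per-ligand interaction energies cannot be reproduced without
  the original receptor models and force field; the energy engine is
  therefore validated by analytic and brute-force oracles, and the model
  layer by refits of deposited energy tables when such a table is
  supplied (`read_energy_table()` + `fit_liece_models()`).
* Pose-filter thresholds are conventions; real pose triage additionally
  weighs chemical context that geometric rules cannot see.
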