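---
title: "Delta-learning potentials for molecular co-crystals: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delta-learning potentials for molecular co-crystals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

Screening co-crystals computationally means ranking thousands of trial
packings of an active ingredient with candidate co-formers by lattice
energy, and relaxing each of them. The level of theory that makes such a
ranking trustworthy is far too expensive for that many structures, while
affordable baselines (dispersion-corrected tight binding and the like)
carry systematic errors — most importantly an over-binding of
intermolecular contacts that contracts the predicted crystals.

`dgap` implements the delta-learning answer: keep a *physical baseline*
for everything long-ranged (electrostatics, dispersion, overall cohesion)
and learn only the short-ranged *difference* to the expensive target
method. The correction is split by physical length scale:

\[
E = E_{\mathrm{base}} + \sum_{t=1}^{N_{\mathrm{types}}}\sum_{i=1}^{N_t}
\Delta E^{(t)}_{\mathrm{intra}}(\mathrm{monomer}_i) +
\Delta E_{\mathrm{inter}}(\mathrm{crystal}),
\]

one intramolecular correction per component type \(t\) (trainable from
cheap gas-phase single points alone) and a single intermolecular
correction shared by all components. All three terms supply energies,
forces and virials, so the composite drives variable-cell relaxation and
constant-pressure molecular dynamics. The intermolecular label of a
training crystal is defined as the *residual* after subtracting the
already-fitted intramolecular predictions, which makes the decomposition
exact by construction at training time; the package asserts this
additivity to 1e-10 eV.

Each correction is a sparse Gaussian process over SOAP descriptors: the
neighbour density of an atom (Gaussian-smeared, width `sigma_atom`) is
expanded in `n_max` radial Gaussians times spherical harmonics to
`l_max`, contracted to the rotation-invariant power spectrum over species
pairs, and L2-normalised. The energy is a sum of per-atom kernel terms
\(k(d, u_s) = (d\cdot u_s)^\zeta\) against `m` sparse environments (zero
across centre species), plus per-species constant offsets. Forces follow
from analytic descriptor gradients by the chain rule; the virial from
\(-\sum (\partial k/\partial u)\otimes u\) over neighbour image vectors.
Fitting solves the regularised sparse-GP system by QR factorisation of
the stacked design matrix \([\Sigma^{-1/2}\Phi;\; \mathrm{chol}(K_{mm})]\).

## Descriptor configurations by role

Intramolecular and intermolecular interactions live on different length
scales, so the two corrections use different descriptors: short cutoff
(default 3.0 Å) for the intra models, longer cutoff (default 5.0 Å) for
the inter model. Package-level defaults are the conventional GAP settings
`n_max = 8`, `l_max = 4`, `sigma_atom = 0.5` Å, `zeta = 4`, with a
quintic polynomial switch over the outer 0.5 Å so every descriptor
component reaches its isolated-atom value smoothly (no discontinuity
above 1e-6 for a 1e-3 Å step across the boundary).

The inter model additionally supports an *intermolecular-only* descriptor
mode (`exclude_intramolecular = TRUE`): neighbours belonging to the same
molecule instance are removed from the environment (periodic copies of
the own molecule still count). Without it, the covalent neighbours at
1.1–2.3 Å dominate the normalised power spectrum and the weak van der
Waals signal the inter model must learn is buried in tiny descriptor
variations; with it, the inter environments describe packing only. In
the bundled toy study this mode reduced held-out force errors several
fold and it is the default for the intermolecular correction.

## Regularisation and conditioning

Per-observation noise targets are set by a weight class: the defaults are
1 meV/atom (energies), 50 meV/Å (forces), 50 meV (virials), with a
"perturbed" class carrying looser targets for far-from-minimum
structures. The toy study, whose labels are analytic and noise-free, uses
tighter targets (0.2 meV/atom, 4 meV/Å).

Two safeguards matter in practice. First, near-duplicate sparse points
(symmetry-equivalent atoms of small molecules produce many) make the
sparse Gram matrix nearly singular; its null directions are cheap for the
prior but can acquire enormous weights and wreck predictions away from
the data. `fit_gap()` therefore prunes the sparse set by pivoted
Cholesky (relative tolerance 1e-7) before solving, on top of a 1e-8
diagonal jitter. Second, intramolecular training configurations must stay
in the component's topology basin: a perturbed monomer whose perceived
bond graph differs from the reference (a broken or spurious bond) belongs
to a different molecule and its delta label is meaningless — the toy
study rejects such draws.

# The toy universe

The package validates the full workflow on an analytic universe designed
to mirror the real setting at desk scale: one "active ingredient" (a bent
N-centred triatomic) and four co-formers (N2, CO, CO2, O3-like molecules,
mutually distinguishable as element-labelled graphs), with a
baseline/target calculator pair whose difference is a smooth, short-ranged
function of local geometry — exactly what a SOAP model can learn.

The potentials use harmonic bonds and harmonic-cosine angles inside
molecules and Lennard-Jones (+ an extra attractive \(r^{-6}\) tail)
between them, smoothly switched off between 4 and 5 Å and summed over
all periodic images within the cutoff. Full image sums (rather than a
minimum-image convention with a half-cell-height restriction) are used
because variable-cell relaxation legitimately produces cells whose
half-height is below any useful interaction cutoff. The baseline
deliberately over-binds (wells ×1.4, diameters ×0.96, stronger tail) and
carries slightly wrong bond lengths (+0.03 Å), stiffnesses (×0.85) and
angles (+2°), mimicking the contraction bias of tight-binding baselines;
the target is the reference being emulated. Bonds carry a dissociation
offset (−4 eV per bond, identical in both calculators so it cancels in
every delta label) so that intact molecules are globally more stable
than van der Waals clusters of their atoms; without it an optimizer can
"react" molecules apart. Because the toy components have at most three
atoms, the evaluator additionally rejects merged aggregates — a
topology-level guard against line searches tunnelling through the
repulsive wall.

Trial crystals are generated by placing rigid reference molecules at
random positions and orientations in random cells (volumes of 380–550 Å^3
per molecule, angles 80–100°, all cell heights ≥ 8.5 Å) and rejecting
intermolecular contacts below 2.4 Å. That floor is ~0.73 of the toy LJ
diameters — the analogue of a van der Waals exclusion for molecules
without a hydrogen skin — and stays above the covalent bond-perception
cutoff of every heavy-atom pair, so a freshly generated contact can never
be mistaken for a bond. Generated structures are gas-like; cells are kept
large enough that minimum-image molecule identification is always valid.

## The benchmark study

`toy_delta_benchmark()` runs the full protocol, with sizes chosen for a
single-CPU run of a few minutes:

* four active/co-former pairs, five stoichiometries each (both
  single-component crystals, 1:1, 2:1, 1:2), 120 structures per
  stoichiometry → ~600-structure pools per pair;
* every pool structure is position-relaxed with the baseline to
  convergence (fmax 0.05 eV/Å), mirroring a screening pool of
  baseline-relaxed candidates;
* 150 training crystals per pair selected by farthest point sampling
  under the SOAP Hausdorff dissimilarity (seeded at the most stable
  structure), then 100 test crystals per pair by FPS *including the
  training set*, so the test set is maximally distant from training;
* a dense "known-crystal" augmentation: the most stable single-component
  and co-crystal entries are compacted to ~140 Å^3/molecule, fully
  relaxed (cell included) with the baseline, and added together with two
  random perturbations each — the only source of compressed-regime
  information, standing in for experimentally known structures
  (synthetic stand-ins, since the toy universe has no experiments);
* intramolecular corrections fitted per component on ~270 gas-phase
  monomers (reference geometry, topology-preserving perturbations at
  0.03/0.07/0.12 Å, and monomers extracted from the training crystals),
  80 sparse points; the single intermolecular correction fitted on the
  ~600 training crystals (energies + forces), 450 sparse points, using
  `n_max = 10`, `l_max = 2`, `sigma_atom = 0.30` Å intermolecular-only
  descriptors — the radial resolution matters most for a pairwise
  correction, angular resolution little;
* evaluation: lattice energies per molecule (gas references re-optimised
  with each method) and force components on the held-out sets, compared
  to the target.

The relaxation study (`toy_relaxation_study()`) emulates the
experimental-structure comparison: held-out co-crystals are compacted and
relaxed with the *target* to produce well-defined reference minima (the
stand-ins for experimental structures), and each reference is then
re-relaxed with the baseline and with the delta model. Density deviations
from the reference quantify the baseline's contraction and the delta
model's correction of it. Relaxations from far-from-minimum random starts
were deliberately avoided here: different methods then fall into
different packing basins and density differences measure basin choice,
not potential quality.

The NPT check relaxes a compacted co-crystal at the target level and runs
6000 steps of Langevin dynamics (1 fs, friction 0.02 fs^-1) with a
stochastic isotropic volume barostat (Metropolis volume moves every 10
steps) at 298 K and 1 bar; the block-averaged mean density (5 blocks,
first 20% discarded) lies below the 0 K density — thermal expansion with
a finite standard error.

# Numerical choices

* **Radial basis.** `n_max` Gaussians centred uniformly on `[0, cutoff)`
  with width `cutoff/n_max`; the density-projection integrals (involving
  exponentially scaled modified spherical Bessel functions, series-summed
  below x = 5 for cancellation safety) are tabulated on a 600-point grid
  and interpolated by natural cubic splines, whose analytic derivative
  keeps forces exactly consistent with energies.
* **Kernel.** Polynomial SOAP kernel, zero across centre species; Gram
  matrices of the normalised descriptors are PSD to −1e-8 by
  construction.
* **Optimizer.** Variable-cell relaxation works on fractional coordinates
  plus six symmetric strain components (scaled by V^(1/3)), minimised
  with L-BFGS-B restarts under a per-round trust box (~0.8 Å per
  coordinate, 5% strain) — an unbounded line search can tunnel through a
  repulsive wall into a spuriously re-perceived topology. Convergence
  requires every force component below `fmax` and, for cells, every
  virial component below `fmax · V^(1/3)`. Failed evaluations restart the
  quasi-Newton state from the last good point; non-convergence raises a
  structured error carrying the last structure.
* **Dynamics.** BAOAB Langevin integration; Monte-Carlo volume moves with
  the atomic-scaling NPT acceptance rule; masses from a pinned standard
  table; all randomness flows from one explicit seed.
* **Ties and degeneracies.** FPS breaks ties at the lowest pool index and
  records each selection distance (exactly recomputable); exact duplicate
  structures are selected last.

# What passing the toy study does and does not show

The toy universe has molecules of 2–3 atoms, three elements, no
hydrogens, no electrostatics by default, rigid generation and an
analytically smooth baseline–target difference confined within the SOAP
cutoffs. Success on it demonstrates that the machinery — descriptors,
gradients, sparse regression, selection, bookkeeping, relaxation,
dynamics — is correct and that the delta-learning design can recover a
learnable correction essentially to its noise floor. It does not
demonstrate chemical accuracy for real co-crystals: real corrections are
not exactly short-ranged (many-body dispersion reaches beyond any local
cutoff), real monomers are flexible and H-bonded, and real reference data
are far scarcer and noisier than analytic labels.

Known limitations: bond perception is distance-based (no bond orders);
minimum-image molecule identification requires molecular diameters below
half the smallest cell height (violations raise errors); the barostat is
isotropic, so cell shapes never relax during NPT; RMSD15 molecule
correspondence is greedy (seeded on central molecules, one refinement
pass, no inversions) rather than an exhaustive packing-similarity search;
and `l_max` is capped at 4 by the generated spherical-harmonics code.
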