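---
title: "Methods: GaMD boost mathematics, reweighting, and contact-map deep learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GaMD boost mathematics, reweighting, and contact-map deep learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gamdl)
```

This vignette documents the models, numerical choices, and design
decisions behind `gamdl`, and states precisely what the synthetic data
do and do not show about real simulations.

## The scientific setting

Kinase conformational regulation is a problem of rare transitions: the
glycine-rich loop (G-loop), the activation loop (T-loop), and the
regulatory alphaC helix rearrange between open, semi-open, and closed
binding-pocket states on timescales that conventional molecular
dynamics struggles to sample. Gaussian accelerated molecular dynamics
(GaMD) flattens barriers with a harmonic boost whose statistics permit
exact energetic reweighting; a convolutional network trained on residue
contact maps then identifies, via saliency, which residue contacts
discriminate the sampled states; and free energy landscapes over the
contact-derived reaction coordinates expose the state structure. This
package implements that workflow as reusable, tested components, and
drives it with synthetic ensembles so every stage can be validated
without multi-microsecond trajectories.

## GaMD boost potential

When the total potential `V` is below a reference energy `E`, it is
raised by `dV = 1/2 k (E - V)^2`; above `E` nothing is added. Two
requirements fix the admissible `E`: boosting must preserve the energy
ordering of any two configurations and must compress their gap, which
together confine `E` to `[Vmax, Vmin + 1/k]`. Writing
`k = k0 / (Vmax - Vmin)` makes `k0` a dimensionless knob in `[0, 1]`.
In the lower-bound mode (`E = Vmax`, the package default and the common
choice in practice)

```
k0 = min(1, (sigma0 / sigmaV) * (Vmax - Vmin) / (Vmax - Vavg))
```

where `sigma0` caps the boost-potential standard deviation
(`sigma_dV = k (E - Vavg) sigmaV` to first order) so that reweighting
stays well conditioned. The upper-bound mode (`E = Vmin + 1/k`,
`k0 = (1 - sigma0/sigmaV)(Vmax - Vmin)/(Vavg - Vmin)`, clamped to
(0, 1]) requires `sigma0 < sigmaV` and falls back to the lower bound,
with a warning, when that fails. Defaults: `sigma0 = 6` kcal/mol,
`T = 300` K, `kB = 0.0019872` kcal/mol/K.

Design choices worth stating:

* the boost applies to the **total** potential only — the model system
  has no dihedral/total split, and this is the simplest faithful
  reading of the boost equations;
* potential statistics are collected over an unbiased equilibration
  segment and then **frozen** — no adaptive updating during production,
  which keeps the reweighting theory exact;
* statistics use the population (divide-by-N) standard deviation.

The integrator is BAOAB-split Langevin in AKMA-like units (kcal/mol,
Å, amu; time unit ≈ 48.9 fs). With zero collision frequency it reduces
to velocity Verlet; the suite verifies energy drift below 1e-4 kcal/mol
over 10,000 steps on a harmonic well, equipartition
(`var(x) = kBT/ks`), and that boosting multiplies barrier crossings on
a 6 kT double well (3.6 kcal/mol at 300 K, the default toy landscape,
with minima ±1.5 Å). The stability heuristic is `dt <= 0.1 / omega` for
the stiffest well frequency `omega = sqrt(ks/m)`; the default
`dt = 0.02` satisfies it for every packaged potential.

## Cumulant-expansion reweighting

The boosted ensemble yields a modified free energy
`F*(A) = -kBT ln p*(A)` over a reaction coordinate `A`. The canonical
profile follows from per-bin exponential reweighting,
`F(A) = F*(A) - kBT ln <exp(beta dV)>_A`, whose cumulant expansion to
second order is

```
F(A) = F*(A) - ( C1 + beta/2 * C2 ),  C1 = mean(dV), C2 = var(dV)
```

per bin, with `beta = 1/(kBT)`. Order 2 is the default (order 1 is kept
for diagnostics; the two agree exactly when the per-bin boost variance
vanishes, which the suite asserts). Cumulants are accumulated **per
bin**, not globally — the per-bin form is what makes the expansion
accurate, because the boost distribution within a bin is much closer to
Gaussian than the marginal over all bins. Implementation notes:

* bins with fewer than `min_frames = 10` samples are flagged unreliable
  and excluded from anchoring; empty bins are `NA`, never a finite cap
  (any plotting ceiling is presentation-layer only);
* profiles are anchored to 0 over reliable bins before and after
  reweighting, so a constant boost shifts nothing;
* dihedral axes span exactly (−180°, 180°] and values are wrapped, so a
  360° rotation of the input leaves the landscape bit-identical;
* default binning: 50 bins per distance axis, 6° bins (60 per axis) for
  dihedral grids — recorded in the output metadata since the choice is
  a convention, not a derived quantity;
* multiple trajectories are concatenated with equal frame weight before
  binning.

The recovery test treats a 10x longer unbiased simulation as the
oracle: on every bin holding at least 500 boosted samples the
reweighted profile agrees within 0.5 kcal/mol, and the barrier estimate
lands within 10% of the analytic height.

## Synthetic conformational ensembles

The generator emulates, at contact-pattern level, a four-system study
(an inhibitor bound to a kinase with and without a partner protein,
for two inhibitors): classes differ in which inter-domain block pairs
are in contact. Residues are single C-alpha points; each named domain
block (e.g. G-loop, T-loop, alphaC analogs) lies on its own chain
segment with 3.8 Å spacing, segments separated by 20 Å. For a rule
`(block_a, block_b, p)`, each matched residue pair draws its contact
state independently per frame with probability `p`; an "on" residue
docks 3.4 Å from its partner (inside the 4.5 Å cutoff), an "off"
residue stays on its distant segment. Gaussian noise (sd 0.3 Å per
coordinate) is applied last, so realized distances fluctuate by ~0.42 Å
and contacts near the cutoff flip stochastically.

Two properties motivate the per-residue-pair (rather than per-block)
draw. First, fidelity: the realized contact frequency of a block pair
tracks `p` within binomial error (the 3.4 Å docking distance keeps
noise-induced flips below ~0.5%, inside that error at the tested sample
sizes). Second, separability: a whole-block draw would let two classes
emit literally identical contact maps whenever their rule states
coincide — with 0.9 vs 0.1 rules the best possible per-frame accuracy
is then only ~0.81, no matter the classifier. With per-pair draws the
inter-block band is a binomial pixel pattern whose density separates a
0.9-class from a 0.1-class with error below 1e-4 per rule, so
near-perfect validation accuracy is attainable *and* the task remains
nontrivial (every frame's pattern is distinct, and pixels flip near the
cutoff). Class streams are split deterministically from the master seed
as `seed + 7919 * class_index`, so classes can be generated in any
order or in parallel, reproducibly.

What the synthetic data do **not** emulate: force-field energetics,
solvent, realistic secondary structure, chain connectivity across
docking events, or the 295-residue scale of a real kinase/cyclin map.
Passing tests demonstrate that the pipeline's mathematics and learning
machinery behave correctly on ensembles with known ground truth — not
that a particular biological system has been reproduced.

The hydrogen-bond series generator places a donor/hydrogen/acceptor
triple exactly at a stated bound geometry (default 2.9 Å, 155°) with
probability `target_occupancy` and at an unbound geometry otherwise;
positional jitter defaults to zero so the stated geometries are exact.

## Contact-map featurization

Contacts are C-alpha pairs at distance `<= 4.5` Å — boundary inclusive,
per the usual printed convention "≤4.5 Å". The diagonal is 1 (zero
distance satisfies any cutoff); it is class-constant and therefore
carries no signal. No sequence-separation exclusion is applied ("any"
C-alpha pairs), so chain neighbours at 3.8 Å are always in contact, as
in a real protein. Maps render losslessly to 8-bit grayscale (1 → 255),
and the inverse transform restores them exactly. Residue indices are
1-based in every file written. Trajectories read and write as
multi-model PDB (via bio3d; 0.001 Å coordinate precision) or long
coordinate CSV, and the suite checks both encodings produce identical
maps.

## The classifier

The network is the standard compact architecture for this task: four
3x3 "same" convolutions with 32/32/64/64 filters, each followed by ReLU
and 2x2 max pooling, then dense 512 and 128 with ReLU and dropout 0.5,
then a linear softmax layer. Images must be multiples of 16 on each
side (four poolings); the synthetic system uses 64x64. Training
minimizes cross-entropy with Adam; the optimizer, learning rate
(default 1e-4), and batch size (default 32) are configuration knobs
recorded with every model, since such choices are conventions. An 80/20
stratified split (seeded) separates training from validation; training
can stop early once validation accuracy reaches a target (default 1.0).
All randomness — initialisation, shuffling, dropout — flows from one
seed, making training bit-reproducible; the suite asserts that
scrambling the validation images leaves the learned weights untouched.

The kernels are hand-written in C++ (RcppArmadillo, single precision,
im2col + GEMM) so training a 3,200-image 64x64 problem takes seconds
per epoch on one CPU core. Backpropagation is verified against finite
differences; because the network is piecewise linear, kinks can sit
exactly at an evaluation point (tied ReLU/pool states), where the
analytic gradient legitimately matches a one-sided difference — the
gradient test accepts either side.

**Saliency** backpropagates the *pre-softmax* class score to the input
pixels — using the probability instead would null gradients at
saturated outputs — then takes absolute values, symmetrises
(`(M + t(M))/2`), and min–max normalises to [0, 1]. Key contacts are
the pairs with gradient strictly greater than 0.7 ("higher than 0.7");
the stricter 0.9 cut used for reaction-coordinate selection is the same
operation at a higher threshold, so the 0.9 set is a subset of the 0.7
set by construction.

**Most populated structure.** The representative map for saliency is
defined here as the medoid of the largest complete-linkage cluster
under Hamming distance, cut at a radius of 10% of the map entries. This
is a documented stand-in for the looser notion of a "most populated"
structure (which could equally be read as a free-energy-minimum
representative); the medoid choice is deterministic, cheap, and reduces
to the modal map when one map dominates. Stacks beyond 1,000 maps are
subsampled evenly, since the distance matrix is quadratic.

## Structural analysis

Superposition is the Kabsch algorithm (SVD of the cross-covariance,
determinant-corrected to exclude reflections). RMSF uses the time-mean
structure as reference with a single re-fit pass (fit to frame 1,
average, re-fit to the mean) — the CPPTRAJ-like convention; iterating
to convergence changes results negligibly for the ensembles tested.
PCA diagonalises the full 3N x 3N population covariance of the
superposed coordinates; a guard (default 1,000 atoms) keeps the dense
eigendecomposition tractable. Dihedrals follow the convention of the
standard MD toolchains (cis = 0°, trans = 180°, sign from
`(b1 x b2) . b3`), reported in (−180°, 180°]. Hydrogen bonds use
donor–acceptor distance < 3.5 Å AND donor–H–acceptor angle > 120°,
both strict — boundary values are not bound, since the printed criteria
are strict inequalities; reported mean distance and angle average over
the bound frames, as hydrogen-bond tables are customarily tabulated.

## Energetic bookkeeping

The module composes supplied components; it evaluates no force field,
generalized-Born, semi-empirical QM, or normal-mode entropy — those
require external engines, and the checkable content is the composition:
`dH` as the sum of five enthalpy components, `dGbind = dH + (-T dS)`
(the entropy penalty is stored as printed, a positive `-T dS` value),
the nonpolar term `dGsurf = 0.0072 * dSASA + 0`, and the decomposition
identities `T = S + B` per interaction type at a 0.02 kcal/mol rounding
tolerance (two-decimal tables drift up to ~0.03 in the enthalpy sums,
hence the separate 0.05 tolerance there). `dGexp = RT ln(IC50/1M)` —
negative for sub-molar IC50, the binding-free-energy reading of the
`-RT ln(1/IC50)` relation. Published experimental values derived from
IC50s are not always mutually consistent with a single temperature;
the function implements the formula and leaves interpretation to the
caller.

## Pipeline and problem sizes

`run_pipeline()` executes simulate → featurize → train → saliency →
reaction coordinates → free energy landscapes → structural and
energetic reports from one configuration (R list or YAML), writing a
JSON manifest with parameters, seeds, and MD5 hashes of every product,
so reruns are verifiable hash-for-hash. The packaged default emulates
the four-system setting with two rules per class (G-loop/T-loop and
alphaC/T-loop analog pairs at probability 0.9 or 0.1), 64 residues.

Problem sizes used by the tests and the acceptance script — chosen as
the smallest sizes at which every statistical assertion has comfortable
margin: 800 frames/class (3,200 images, 640 held out) for the
classification benchmark; 200,000 boosted steps against a 2,000,000-step
unbiased oracle for reweighting recovery; 2,000 frames for hydrogen-bond
occupancy (binomial 99% interval ±2.8% at a 0.6 target); unit-scale
fixtures elsewhere.

## Known limitations

* The CNN trains on CPU in single precision; there is no GPU path, no
  data augmentation, and no class-imbalance handling beyond stratified
  splitting.
* The Langevin engine integrates the packaged analytic potentials only;
  it is a testbed for the boost mathematics, not a general MD engine.
* Reweighting offers cumulant orders 1 and 2 only; anharmonicity beyond
  order 2 surfaces as residual error, not as an automated gate.
* `most_populated_map()` implements one defensible reading of a loosely
  defined concept; alternatives (free-energy-minimum representatives)
  would require the landscape stage upstream of the saliency stage.
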