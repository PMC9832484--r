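---
title: "Classifying ELP phase behavior from short MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying ELP phase behavior from short MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elptools)
```

Elastin-like polypeptides (ELPs) are repetitive designer proteins built
from VPGXG-type pentapeptides. Below a transition temperature they are
soluble; above it they coacervate (LCST phase behavior). Whether that
transition lies below 37 °C determines whether a design is useful as a
thermoresponsive biomaterial, and this package implements a pipeline
that predicts it from comparatively short (150 ns) all-atom MD
trajectories, without long simulations or enhanced sampling. This
vignette explains the models, the tunable parameters and the design
choices, and is the reference for what the package's tests do and do
not demonstrate.

## From trajectories to descriptors

A trajectory (topology plus frames in Å, times in ns) is reduced to one
observation row per sampled time point. Sampling takes frames after an
equilibration window (`start_ns`, default 100 ns) at a fixed stride
(`stride_ns`, default 0.2 ns); a 100–150 ns window at 0.2 ns thus gives
exactly 250 rows per replica. The 27 properties in
`descriptor_registry()` are:

* **Size and shape** — mass-weighted radius of gyration; backbone RMSD
  after optimal (Kabsch, proper-rotation) superposition onto the first
  sampled frame; end-to-end CA distance; gyration-tensor asphericity;
  maximum CA–CA extent.
* **Surface** — Shrake–Rupley SASA with a 1.4 Å water probe, computed
  on a deterministic golden-spiral point lattice (default 240 points
  per atom; the per-frame featurizer uses 120 to halve cost, which
  changes totals by well under 1 %, consistent with the convergence
  test). The hydrophobic/hydrophilic split assigns each atom by the
  sign of its residue's Kyte–Doolittle value; backbone/side-chain
  splits are also reported. Classes always sum exactly to the total.
* **Hydrogen bonding** — geometric criterion: donor–acceptor distance
  ≤ 3.5 Å and deviation of the D–H–A angle from linearity ≤ 30°. This
  is the convention in which the cutoff bounds the *deviation at the
  hydrogen*, which we document explicitly because "D–H–A angle cutoff"
  is ambiguous between the angle and its complement. Counted
  intra-peptide (with backbone/side-chain splits), peptide–water and
  peptide–hydration-layer.
* **Hydration** — number of water molecules whose oxygen lies within
  3.15 Å of any backbone atom, each water counted once.
* **Secondary structure** — helix/sheet/turn/coil fractions from the
  assigner described below.
* **Energies** — pairwise Coulomb (332.0636·q_iq_j/r kcal·Å/mol) and
  Lennard-Jones (CHARMM ε, r_min combination rules) sums with an
  energy-switching function between 10 and 12 Å, matching common
  simulation settings. Intra-group sums exclude pairs within the same
  or adjacent residues as an analysis-level stand-in for bonded 1-2/1-3
  exclusions (the package never evaluates bonded terms).

The registry is data: each row carries the extractor applied to a
shared per-frame context, so a user with a different property list can
swap their own registry into `sample_descriptors()` without touching
the sampling code.

Two deliberate numerical choices: pairwise operations use direct
vectorized distance matrices rather than cell lists — at the system
sizes this package targets (up to a few thousand atoms) the simple
implementation is faster to verify and fast enough, and its correctness
is pinned by exact brute-force-oracle tests; and when periodic box
lengths are present, the minimum-image convention is applied per
dimension, otherwise boundaries are open.

### Secondary structure without external binaries

Established assigners (STRIDE, DSSP) are external compiled programs.
The package ships a self-contained approximation that combines backbone
dihedrals with backbone N–H···O=C hydrogen-bond patterns: residues
spanned by i→i+4 bonds with helical φ/ψ are helix; long-range
(|i−j| ≥ 3, excluding i→i+3/i+4) bonded bridges with extended φ/ψ on
both sides are sheet; i→i+3/i+4 bonds without a helical run are turn;
everything else (including residues with missing backbone atoms, which
are flagged) is coil. Amide hydrogens are reconstructed 1.02 Å from N,
anti to the preceding carbonyl, when the topology lacks them. The
assigner will not reproduce STRIDE's exact boundaries — ends of helices
and single-residue bridges are where they differ most — and it is
pluggable: any function producing per-residue classes can replace it in
a custom registry.

## The classifier

Descriptor columns are autoscaled (centred, unit variance with the
population-sd convention; constant columns are dropped and recorded).
Autoscaling before PCA/PLS is the chemometrics default; it is refit
inside every training fold so no scaling information crosses folds.

PCA (`fit_pca()`) decomposes the scaled matrix as X = T P′ + E by
singular value decomposition, with orthonormal loadings and components
ordered by explained variance; the reconstruction identity is tested to
1e-8.

PLS-DA (`fit_plsda()`) is the package's own NIPALS implementation for a
single binary response: each weight vector is the normalized covariance
direction w = X′y/‖X′y‖, scores are t = X w, and X and y are deflated
before the next component, giving X = T P′ + E and y = T b + F with F
orthogonal to the scores. Phase behavior is coded 1 (LCST transition
below 37 °C) / 0 (absent), and a prediction above 0.5 — the midpoint of
the coding — is classified as 1; a value exactly at 0.5 goes to class 0
(documented tie-break). Per-ELP predictions are the arithmetic mean of
all row predictions (every replica and time point) of that ELP.

### Double cross-validation

Per-row predictions are far from independent (they share an ELP and are
temporally autocorrelated), so model selection and accuracy estimation
use a nested leave-one-ELP-out scheme in which all rows of an ELP
always travel together:

1. hold one ELP out as the **test** set;
2. of the remaining ELPs, hold one out as **validation**;
3. fit PLS-DA on the rest;
4. choose the smallest component count (up to `k_max`, default 10,
   capped by rank) that classifies the validation ELP correctly — if
   none does, fall back to the count whose validation prediction lies
   furthest toward the correct side, flagged in the fold table;
5. predict the test ELP with that model.

Repeating step 2 over every inner ELP gives 7 predictions per test ELP
for an 8-ELP library (8 × 7 = 56 fits), combined into a mean and a 99 %
Student-t interval (df = 6). An ELP is confidently classified when the
interval lies entirely on one side of 0.5. Folds whose training labels
collapse to a single class are skipped with a warning; the returned
fold table records the chosen k, the fallback flag, and the training
membership of every fit, which the test suite audits for leakage.

### What the null looks like (a caveat)

Leave-one-group-out schemes with balanced designs have a known
pathology worth stating plainly. With 4 + 4 ELPs, whenever a class-1
ELP is held out the training mean of y is 3/7; with no signal, the
held-out prediction collapses to that intercept, which sits on the
*wrong* side of 0.5 — and symmetrically for class 0. The
no-signal/permuted-label null therefore does not hover near 50 %
accuracy: it is driven *below* chance (exactly 0 % for pure noise, and
a permutation-overlap-dependent mixture of 0/75/100 % when the data
contain real clusters). The package's tests characterize this honestly:
the null shows no predictive skill, and across 20 permutation seeds the
mean accuracy is statistically indistinguishable from 50 % only because
its dispersion is large. A positive classification result should
therefore always be read alongside the interval criterion, not the raw
accuracy alone.

## The synthetic data generators

The generators produce data with the statistical structure the analysis
assumes, at the study's shape, and they are the fixtures for every
pipeline test. They are seed-deterministic (a seed is mandatory) and
parameter-faithful (sample moments converge to the specified ones).

* `gen_descriptor_dataset()` — defaults: 8 pseudo-ELPs (4 per class),
  3 replicas × 250 time points, 27 descriptors of which 6 carry a
  between-class mean shift of 4 within-class standard deviations. Rows
  within a replica follow an AR(1) process with ρ = 0.5 scaled to unit
  marginal variance, reflecting that MD time points are autocorrelated
  rather than independent; ρ = 0.5 at a 0.2 ns stride is a moderate
  choice for slowly varying structural descriptors. What it does *not*
  emulate: cross-descriptor correlation structure, heavy tails, drift,
  or replica-to-replica offsets — so a passing classifier test shows
  the procedure works on clean clustered data, not that real
  trajectories separate.
* `gen_chain_trajectory()` — a pseudo-peptide (backbone N/H/CA/C/O plus
  one side-chain bead, idealized local geometry, alternating
  hydrophobic/hydrophilic residue names) built as a correlated random
  walk whose step persistence scales with 1 − compactness, with a
  centripetal bias and a 4 Å excluded-volume rejection for collapsed
  chains; waters are placed uniformly in the periodic box outside a
  2.5 Å exclusion zone and carry TIP3P-like parameters. Extended chains
  (c = 0) have larger radii of gyration than collapsed ones (c = 1) in
  every seed tested. This is a geometry generator, not physics: frames
  are independent samples, energetics are not Boltzmann-weighted, and
  its purpose is to exercise every featurization precondition.
* `gen_frap_trace()` / `gen_ftir_spectrum()` — direct simulations of
  the fitted models (single-exponential recovery; five Gaussians on a
  650–4000 cm⁻¹ grid at 2 cm⁻¹ spacing) plus Gaussian noise.

## Hydrogel calculations

* **Mesh size.** ξ = (k_B T / G′)^{1/3} from rubber elasticity, valid
  for gels and physically cross-linked networks of flexible chains.
  Monotone decreasing in G′; ξ³G′ = k_B T holds to numerical precision.
* **Temperatures.** Converted exactly (37 °C = 310.15 K). This matters
  at the margins: the 40 kDa dextran free diffusivity rounds to
  73.0 μm²/s at 310.15 K but 72.9 at a truncated 310 K.
* **FRAP.** Full-scale normalization divides the bleach-ROI trace by
  the whole-field trace (correcting laser fluctuation, acquisition
  bleaching and fluorescence loss), then rescales so the pre-bleach
  mean is 1 and the first post-bleach point is 0, which also defines
  t = 0 for the fit. The recovery is fit by Levenberg–Marquardt
  (`minpack.lm`) to I(t) = A(1 − e^{−k t}) with unweighted residuals;
  starting values come from the late-time plateau and the half-recovery
  time, and non-convergence is flagged rather than silently returned.
  Parameter recovery at the study's noise (σ = 0.01, 200 points over
  100 s) is within 5 % with bias below 2 % across 50 seeds.
* **In-gel diffusivity.** With a fixed bleach geometry, D ~ k_FRAP L²,
  so D_gel = D₀·k_gel/k_solution — scale-free in the rates. A hindered
  probe bounds the mesh from above by its diameter.
* **Amide-I deconvolution.** The 1595–1705 cm⁻¹ window is normalized to
  unit maximum and fit with five Gaussians whose centres are
  box-constrained to ±4 cm⁻¹ of 1620 (β-sheet), 1645/1660/1670 (random
  coil/helix) and 1700 (β-turn) cm⁻¹. Widths are parameterized as
  standard deviations, started at window-width/20 and bounded positive;
  areas follow analytically as amplitude·width·√(2π). The
  **ordered-structure fraction** is defined here as the pooled β-sheet
  plus β-turn area fraction (the coil/helix bands are pooled by the
  canonical assignment); this definition is configurable in the result
  object since reasonable analysts differ on including helix.
  *Identifiability caveat:* the three overlapping coil/helix sub-bands
  cannot be individually resolved at realistic noise — their areas
  trade off against each other — so recovery guarantees (within 5
  points at 1 % noise, bias < 2 points) are stated for the pooled class
  fractions and the ordered fraction, which are the quantities a
  secondary-structure analysis reports.

## Problem sizes used by the tests

The suite runs in about a minute on one core: oracle comparisons use
≤ 200-atom systems where O(N²) double loops are exact and fast;
classifier tests use the full 8 × 3 × 250 × 27 shape where the result
matters (the separable-cluster and permutation-null checks) and 10–50
time points where only bookkeeping is under test; recovery suites use
10–50 seeds. These sizes are the package's own choice of
statistically sufficient fixtures, stated here so users scaling up know
what has actually been exercised.

## Known limitations

* The classifier is validated on synthetic clusters; applying it to
  real trajectories requires the user's own MD data and labels.
* The secondary-structure assigner approximates, but is not, STRIDE.
* XTC trajectories are not read; use DCD, PDB frames or the tidy CSV
  fallback.
* Interaction energies are analysis-level (switched, truncated,
  adjacency-excluded) and not comparable to simulation-engine totals.
* The double-CV null pathology described above is a property of the
  validation design, not of the implementation; it is inherent to
  leave-one-group-out with midpoint thresholding.
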