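---
title: "Dissecting macrocycle binding affinity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting macrocycle binding affinity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macrodissect)
```

## The two-term affinity model

macrodissect treats the apparent binding affinity of a flexible
macrocyclic ligand as the product of two separable effects.

**Conformational pre-equilibrium.** Assume the ligand binds its target
only from a "bioactive" conformational state which it occupies with
fraction $p$ in free solution. If the bound complex is unaffected by
what the free ligand does, the observable dissociation constant is
inflated by the time spent outside the bioactive state:

$$K_d^{app} = K_d / p \qquad\Longleftrightarrow\qquad
  \mathrm{p}K_d^{app} = \mathrm{p}K_d + \log_{10} p .$$

`apparentPkd()` implements this, and `conformationalDpkd()` its
difference form for a ligand pair,
$\Delta \mathrm{p}K_d^{conf} = \log_{10}(p_A/p_B)$. Two assumptions
matter: (i) the bioactive/non-bioactive exchange is fast relative to the
binding experiment (a true pre-equilibrium), and (ii) the intrinsic
$K_d$ from the bioactive state is what a *conformationally restrained*
relative-FEP calculation estimates. Under (ii), adding the FEP-derived
direct term and the population-derived conformational term
(`dissectAffinity()`) is a consistent decomposition and not double
counting. Neither assumption is checked by the package; they are the
modelling commitments of the workflow.

**Direct term from a FEP network.** Relative FEP gives per-edge binding
free energy differences $\Delta\Delta G = \Delta\Delta G_{complex} -
\Delta\Delta G_{solvent}$ (`combineLegs()`). Node values are obtained by
ordinary least squares over all edges with the reference ligand pinned
at zero (`relativeDpkd()`); on a tree this is an exact path sum, on a
redundant network it is the Gauss–Markov best linear estimate, which the
test suite verifies has lower variance than any single path. Conversion
to pKd units uses $\Delta \mathrm{p}K_d = -\Delta\Delta G /
(\ln 10 \, R T)$ with $R = 1.98720425864083 \times 10^{-3}$
kcal mol$^{-1}$ K$^{-1}$ and $T = 298.15$ K by default (configurable;
the temperature of the underlying simulations is the right choice).

Convergence diagnostics are deliberately simple: per-edge hysteresis is
the *signed sum* of forward and backward estimates (0 for converged
edges; an `"absdiff"` convention is available since the field is not
uniform on the sign), and cycle-closure errors are signed sums around a
cycle basis built from a BFS spanning tree, reported per cycle with a
network RMS. Restraint force constants (e.g. soft 0.1, medium 1, hard
10 kcal mol$^{-1}$ Å$^{-2}$) are treated purely as metadata labels:
`restraintSensitivity()` reports the per-ligand spread across levels,
but no attempt is made to debias the restraint free energy — that would
require the reversible work of switching the restraints on, which is
upstream of this package.

## Population analysis

The RMSD series of an ensemble against the bound-state reference
(`rmsdSeries()`) superposes each frame on a fit selection and measures
RMSD over a measure selection. Both default to the `"backbone"` mask —
for the bundled toy system the ring N/Cα/C/O atoms — because free-ligand
simulations contain no protein to fit on; both are fully configurable
since the appropriate atom set depends on the system (in particular,
whether crosslink atoms are included).

The classifier (`classifyPopulations()`) is intentionally minimal:
population 1 is all frames with RMSD $\le$ the threshold, default
2.6 Å, chosen as the interior minimum of the bimodal RMSD histograms
(0.1 Å bins) this workflow targets. Frames exactly at the threshold
count as population 1 (the "$\le$" convention). A helper
(`findHistogramMinimum()`) locates the histogram minimum inside a
user-given window, but an automatic threshold is never silently applied
— a silent data-driven threshold would make occupancies incomparable
across ligands.

Statistical uncertainty is the sample standard deviation (ddof = 1,
since the block mean is itself estimated) of per-block occupancies over
5 contiguous blocks, mirroring the standard block-averaging treatment of
a 2.5 µs trajectory split into 0.5 µs blocks. With fewer than 2 blocks
the uncertainty is reported as missing, never as zero.
`blockConvergence()` quantifies sampling consistency as pairwise L1
distances between per-block RMSD densities; 0 means identical blocks, 2
disjoint support.

## Surface areas and lipophilicity

`shrakeRupley()` samples each atom's expanded sphere (vdW radius +
probe, probe 1.4 Å water by default) with a deterministic golden-spiral
lattice; a point is accessible iff it lies outside every other expanded
sphere. The lattice is seed-free, so SASA values are bit-reproducible at
fixed `nPoints` — an intentional trade against the variance-reduction of
random rotations. The buried test uses a strict inequality with a
$10^{-9}$ Å$^2$ margin so that points exactly on a shared surface
(coincident atoms of equal radius) remain accessible for both atoms:
degenerate input degrades gracefully instead of annihilating both
spheres. Accuracy against the two-sphere spherical-cap closed form is
about 2% at 960 points and 0.5% at 10,000; the defaults (960) favour
ensemble throughput.

Polarity follows a simple rule (`assignAtomClasses()`): N, O, S and any
hydrogen bonded to them are polar; C, P and hydrogens on carbon are
nonpolar. The rule is configurable because "polar surface area" has no
single field-wide definition (O/N-only and Ertl-style topological PSA
are common alternatives); radii default to the Bondi set and can be
overridden per element. All atoms, including hydrogens, enter the
partition by default — heavy-atom-only PSA can be had by classifying on
a reduced atom set. Per-frame PSA/NPSA always sum to the frame total,
and `ensembleSurface()` averages them over frames (optionally over
blocks, or over a frame subset such as population-1 members only — an
exploratory option, not part of the core model).

`fitLogdModel()` is ordinary least squares of measured logD on NPSA and
PSA. The package imposes **no hidden descriptor scaling**: coefficients
are on whatever scale the caller supplies, and that scale is recorded in
the model object. The synthetic generator (`makeLipoDataset()`)
documents its descriptors as areas/100 (units of 100 Å², NPSA ~
U(6, 9), PSA ~ U(3.5, 5)), which places generated logD values with the
default coefficients (0.27, −0.82, 2.22) in the 0.5–1.5 range typical of
measured macrocycle logD.

For competition assays, `kiFromIC50()` defaults to the classical
Cheng–Prusoff correction $K_i = IC_{50}/(1 + [L]/K_d^{tracer})$; an
`"fp"` mode adds the free-protein term used in fluorescence-polarization
variants. Both are exposed because published FP workflows differ and the
package does not guess which one produced a given table.

## The synthetic-data generator

The generator stands in for enhanced-sampling MD output; its defaults
*are* the study conditions of the workflow it emulates:

- `makeToyMacrocycle()` builds a closed ring of pseudo-residues
  (N/Cα/C/O, 3.8 Å Cα spacing) with a two-carbon crosslink chord —
  enough geometry to carry masks, bonds and realistic RMSD behaviour,
  with no pretence of chemistry.
- `makeBimodalEnsemble()` draws each frame as native (reference +
  isotropic Gaussian jitter, 0.25 Å per coordinate, RMSD mode ≈ 0.4 Å)
  with probability `pBioactive`, else as a decoy in which the
  crosslink-bearing half of the ring is rotated 120° about the hinge
  axis and displaced 2 Å (RMSD mode ≈ 3.5 Å). Decoys are built as a
  coherent segment motion — mimicking the crosslink swinging out of its
  bound-state arrangement — rather than unstructured noise, so the RMSD
  histogram is genuinely bimodal with an interior minimum near the
  2.6 Å threshold. The generator warns when the two modes are closer
  than 4 pooled standard deviations. Ground-truth labels are returned
  so recovery can be tested without the classifier.
- `makeStudy()` fixes the occupancy series at 6%, 16%, 30%, 40% — the
  measured bioactive populations of the H/H, Me/H, Me/Me, Et/Me
  substitution series — with 5000 frames per ligand by default.
- `makeFepNetwork()` produces two-leg edge tables from additive node
  free energies plus independent Gaussian noise per leg and direction,
  so hysteresis is exactly 0 at σ = 0 and has standard deviation σ√2
  otherwise, and cycle closures vanish exactly in the noise-free case.

What passing tests on this data do **not** show: real REST-MD ensembles
have correlated frames (the generator's are i.i.d., so its binomial
error bars are a best case), multimodal decoy structure, and
force-field-dependent populations; real FEP noise is neither Gaussian
nor independent across edges sharing a ligand. The generator validates
the *analysis machinery*, not the simulations feeding it.

## Numerical choices

- Kabsch superposition uses SVD with the determinant sign correction so
  reflections are never returned; degenerate (collinear, < 3 atom)
  selections are errors, not warnings. Rigid-motion invariance holds to
  1e-8 Å in the test suite.
- Torsions use the standard atan2 triple-product form, degrees in
  (−180, 180], positive per the IUPAC convention; the angle is invariant
  under atom-order reversal and antisymmetric under mirror reflection.
  Coincident or collinear defining points are errors.
- Histograms are left-closed right-open from 0.0, so a frame at a bin
  boundary belongs to the upper bin, and densities integrate to 1.
- Contiguous block partitions give earlier blocks the extra frame when
  sizes do not divide evenly (sizes differ by at most 1).
- Least-squares network solves use the QR path of `lsfit`; the solution
  is unique once the reference is pinned, hence invariant to edge
  orientation and path enumeration.
- All coordinates are Å; atom indices are 1-based throughout the R API
  and in PDB serials.

## Problem sizes

Tests and the acceptance checks run at deliberately modest sizes chosen
as the package's own validation conditions: 5000-frame ensembles for
occupancy recovery (binomial σ ≈ 0.007 at p = 0.3, block σ over 5 blocks
of 1000), 100 seeded replicates for FEP noise statistics, 960/10,000
SASA lattice points, and a 400-frame four-ligand study for the
end-to-end determinism check. Ensemble SASA subsamples frames
(`surfaceStride`, default 20) since surface averages converge much
faster than population fractions.

## Known limitations

- The dissection assumes additivity of the direct and conformational
  terms; cooperative effects (binding-induced shifts of the free-ligand
  landscape) are outside the model.
- The 2.6 Å default threshold is appropriate for ligands of this size;
  the bimodal structure itself is not guaranteed for other scaffolds
  and should be checked via `rmsdHistogram()` before the two-population
  reading is trusted.
- PDB precision truncates coordinates at 3 decimals; round-trips are
  exact only to that precision (XYZ output keeps 6).
- No binary trajectory formats (DCD/XTC): convert externally to
  multi-model PDB or XYZ.
- Restraint bias in the direct term is consumed as given; debiasing by
  computing the restraint work is out of scope.
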