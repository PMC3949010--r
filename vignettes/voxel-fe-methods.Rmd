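---
title: "Image-based voxel finite-element modelling of fractured and augmented vertebrae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based voxel finite-element modelling of fractured and augmented vertebrae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertefem)
```

## The problem

Traumatic (burst) fractures of the vertebral body are sometimes treated by
vertebroplasty: bone cement — non-resorbable PMMA or an osteoconductive
calcium-phosphate (CaP) formulation — is injected through the pedicles into
the fracture voids. Whether the mechanical outcome is driven more by the
cement's elastic modulus or by how much of the fracture void the injection
actually fills is hard to separate experimentally, because no two fractured
specimens are alike. Specimen-specific finite-element (FE) models built from
micro-CT images solve that problem: the same specimen geometry can be
re-solved with different cement properties, and the model's axial stiffness
can be validated against the specimen's own compression test.

`vertefem` implements this methodology end to end and, because the original
specimens' scans are not available, exercises it on synthetic voxel
phantoms that reproduce the structure the pipeline assumes: a vertebral-
body surrogate potted between two PMMA end caps, internal fracture voids,
partial cement fill, a radiopaque locating marker, and noisy "experimental"
axial stiffness measurements.

## The model

Every stage works in mm / N / MPa.

**Meshing.** Images are down-sampled to the working resolution by exact
fractional-overlap box averaging (each coarse voxel is the volume-weighted
mean of the fine voxels it covers — a partial-volume scheme, so a voxel
half-filled by bone gets half the bone grayscale). Each voxel of a
segmented component then becomes one cubic 8-node trilinear hexahedral
element (2×2×2 Gauss quadrature). A working voxel of about 1 mm is the
scale at which voxel-to-element conversion is known to be converged for
whole-vertebra stiffness while staying above the trabecular length scale;
the package's tests and scripts run the same pipeline at 2 mm on smaller
grids to keep a full multi-study run in the minutes range on one CPU, a
pure problem-size choice that exercises identical code paths.

**Materials.** All materials are linear-elastic and isotropic with
Poisson's ratio 0.3:

| Component | Modulus | Why |
|---|---|---|
| bone | `E = max(alpha * g, floor)` | linear grayscale-to-modulus map |
| fracture gap | 1e-9 GPa | near-zero filler (below) |
| end caps | 2.45 GPa | PMMA potting cement |
| injected PMMA | 1.035 GPa | experimental compression value |
| injected CaP | 0.585 GPa | experimental compression value |
| loading plate | 210 GPa | steel |

The conversion factor `alpha` (MPa per grayscale unit) is the one free
parameter; it is calibrated, not assumed. The tiny positive floor
(default 1e-3 MPa) guards against non-positive grayscale values.

**The fracture gap as a material.** Explicit contact between the many
fragment surfaces of a burst fracture would demand unverifiable contact
assumptions and invite convergence trouble. Instead gap voxels are meshed
with a near-zero modulus (1e-9 GPa), letting fragments move relative to
one another without interpenetration constraints. `gapSensitivity()`
reproduces the supporting argument: stiffness is solved over a descending
sequence of gap moduli until the change becomes undetectable (relative
tolerance 1e-3 by default), and the working value is placed three orders
of magnitude below that plateau so that more severely fractured specimens
stay on it too. The acceptance suite confirms the margin is inert: between
1e-6 and 1e-9 GPa the reference phantom's stiffness changes by less than
1e-4 relative.

**Loading.** The base of the lower cap is fully fixed (whether the
physical rig also prevented transverse slip at the base is not knowable
from the experiment; full fixation is the default and the solver exposes
the rotation/translation constraints for sensitivity work). A steel plate
layer (default 3 voxels) is synthesised on the upper cap's footprint, and
the plate's top-surface nodes are tied to a rigid reference at the pivot —
the radiopaque marker centroid projected onto the plate plane — with
small-rotation kinematics `uz = Uz + Rx (y - yp) - Ry (x - xp)` and
in-plane displacements fixed. That reproduces the ball joint of the
physical test: the loading point cannot translate horizontally but the
plate is free to tilt. A 4.5 kN compressive load acts on `Uz`; the
reported stiffness is load over `|Uz|` in N/mm. A true contact model with
an analytic disk is unnecessary in this linear small-displacement setting;
the 3-DOF tie is its exact linearisation.

**Solver.** The global sparse symmetric system is reduced through the tie
constraints, Jacobi-scaled, factorised by supernodal sparse Cholesky
(CHOLMOD via Matrix), and polished by iterative refinement to a relative
residual of 1e-8 — the residual tolerance, not the method, is the
contract, and the extreme modulus contrast (1e-9 GPa gaps to 210 GPa
steel) is what makes the scaling and refinement worthwhile. Elements not
path-connected to both the base and the plate cannot carry load and are
removed with a warning; a model with no base-to-plate path is an error.

## Segmentation

A threshold window captures bone only, leaving gaps, caps, cement and
marker unsegmented; separate windows capture those components. The
fracture mask is `close(bone, cube kernel) - bone`, restricted to a body
region of interest, with connected components below a minimum size
removed. Two conventions matter:

* A cubic structuring element of side `k` closes gaps at most `k - 1`
  voxels thick — a side-2 kernel (the working default at 1 mm voxels)
  recovers one-voxel cracks exactly, and thicker un-closable cores are
  reported in a message rather than silently dropped.
* Erosion pads the array border with foreground and dilation with
  background (the scikit-image convention), so closing does not gnaw at
  structures cut by the field of view.

The original workflow removed spurious fracture components by hand;
reproducibility demands a rule, so the package substitutes
connected-component size filtering inside a dilated, hole-filled body
region — small and exterior components are exactly what an operator would
delete. The marker is localised (`locateMarker()`, physical centroid) and
then removed from the model, since no load passes through it.

**Fracture severity scoring.** On transverse slices evenly spanning the
bone height, the in-plane bounding box of the bone is divided into a grid
(default 4×4 cells, 5 slices) and each cell scored 0 / 1 / 2 by its
fracture-area fraction (defaults: below 0.02 scores 0, below 0.15 scores
1, else 2). The normalised score is the cell sum over twice the number of
cells, and a specimen is "included" above a threshold (default 0.1). The
source methodology used human 0–2 judgements and does not report the grid
size, slice count or mapping; these thresholds are an automated surrogate
— configurable, and not claimed equivalent to human scoring.

## Calibration of the conversion factor

`calibrateAlpha()` adjusts `alpha` until the mean error between measured
and predicted stiffness over a development set (default six fractured
models) is minimised. "Mean error" is ambiguous; the package's default
objective is the mean absolute percentage error (matching how validation
errors are reported), minimised by golden-section search, with the mean
*signed* percentage-error root as an alternative mode solved by bisection
— predicted stiffness is strictly increasing in `alpha` (caps, cement and
plate moduli are fixed), so that root exists and is unique, which also
makes the signed mode the fast, deterministic choice for Monte-Carlo
recovery studies. The full search trace is retained. Because the system
matrix is assembled as `K = K_fixed + alpha * K_bone`, re-solving at a new
`alpha` reuses the assembly and the symbolic factorisation.

`validateAlpha()` applies the fitted factor to held-out specimens and
reports per-specimen percentage errors, their mean absolute value, Lin's
concordance with the measurements and the Bland–Altman agreement
(experimental minus FE, by convention).

## The virtual augmentation study

`virtualAugmentation()` assigns every augmented specimen's cement region
the PMMA modulus, then the CaP modulus, and re-solves; the fractured
baseline reassigns the cement region to the gap modulus, isolating the
cement's contribution on identical geometry (the alternative baseline —
the specimen's experimental pre-augmentation stiffness — would confound
the comparison with measurement noise). Stiffness gains are correlated
with percent fracture fill (Pearson, two-tailed). Per specimen the PMMA-
modulus stiffness can never fall below the CaP-modulus stiffness; that
monotonicity is asserted by the result class itself.

## The synthetic cohort

`phantomSpec()` / `generatePhantom()` build a circular-cylinder body
between two rectangular cap slabs — deliberately simplified geometry that
keeps analytic oracles (block and series stiffness) available. Defaults:
40 × 40 × 56 voxels at 1 mm, body radius 16 mm and height 32 mm, 8 mm
caps. The bone grayscale is a smoothed Gaussian random field (mean 250,
SD 60 a.u., 3 mm correlation length, clipped to [25, 600]) so that with
`alpha` near 0.5 MPa/a.u. bone moduli land in the low-hundreds-of-MPa
range typical of vertebral trabecular bone and whole-specimen stiffness
falls in the 1–4 kN/mm range of real potted specimens. Caps, cement and
marker get distinct grayscale plateaus, making threshold windows exact on
phantoms — real scans blur boundaries, so passing segmentation tests here
validates the logic, not grayscale robustness.

Fracture voids are planar slabs (optionally radius-bounded) and
ellipsoids intersected with the body. Nothing quantitative is known about
real fracture-void morphology from the source study; partial transverse
cracks that leave an annular bone bridge are a modelling choice with two
desirable properties: the fragments stay load-bearing (a full-section
near-zero-modulus gap would collapse the stiffness and destroy the
calibration's sensitivity to `alpha`), and sub-voxel apertures snapped to
voxel-centre layers are exactly recoverable by the side-2 closing kernel,
so segmentation errors do not confound downstream checks. Cement fills
void voxels nearest two pedicle-like entry axes first, emulating the
spatially coherent spread of a bi-pedicular injection, until the target
fill fraction is met (within one voxel's quantisation).

`generateCohort()` randomises severity (one or two cracks, axially
separated; radius 0.45–0.8 body radii; aperture 0.5–0.95 voxels) and
draws fill fractions around the study's arm means — 0.53 (SD 0.055) for
PMMA, 0.36 (SD 0.125) for CaP, clamped to [0.05, 0.95]. Augmented
records carry a cement-free pre-augmentation twin with the identical
grayscale field and a pre-augmentation measurement, mirroring a
test–inject–retest protocol. `simulateMeasurement()` runs the forward FE
model at a generating factor `alphaTrue` (default 0.5) and perturbs it
with multiplicative Gaussian noise (default SD 5%); the optional
load-displacement curve has a quadratic toe (slope-continuous at its
end, default 0.3 mm) followed by a linear segment of at least 0.8 mm, so
the 0.6 mm windowed-gradient extractor (`stiffnessFromCurve()`) is
exercised on realistic curve shapes and must recover the generating
slope.

All randomness flows through explicit integer seeds (`withSeed()`
restores the session RNG), so identical seeds give byte-identical
phantoms, cohorts and pipeline JSON.

## Statistics

The group and agreement statistics mirror the study design: one-way
ANOVA and Tukey–Kramer (valid for unequal group sizes, studentized-range
quantiles from R's `ptukey`/`qtukey`, which evaluate the same numerical
integral as published tables — verified against q(3, 10, 0.05) = 3.877),
the pooled-variance unpaired t test, Pearson's correlation with its
t-based two-tailed test, Lin's concordance correlation coefficient, and
Bland–Altman limits of agreement (mean ± 1.96 sample SD). ANOVA, the t
test and Pearson are computed from the textbook sums-of-squares formulas
— which lets degenerate inputs (zero within-group variance with unequal
means) be flagged explicitly as infinite statistics rather than errors —
and are cross-checked in the test suite against `aov()`, `t.test()`,
`TukeyHSD()` and `cor.test()` as independent oracles. Lin's coefficient
uses 1/n (biased) moment estimators per the original definition;
implementations based on n−1 variances differ slightly at small n. The
attenuation property |CCC| ≤ |r| is asserted over a thousand random
vectors.

## What passing tests do and do not show

The phantoms share the pipeline's structural assumptions: plateau
grayscales, sub-voxel planar cracks, cubic voxels, noise that is
multiplicative and unbiased. Green tests therefore demonstrate that the
implementation is faithful — analytic stiffness oracles to 1e-8,
parameter recovery within 0.5% noiselessly and 5% under 5% noise in ≥90%
of seeded cohorts, exact mask recovery, byte-identical reruns — not that
the method would achieve any particular accuracy on real micro-CT data,
with its beam hardening, blurred interfaces, trabecular texture and
operator-dependent segmentation. The original study's headline values
(mean fills 53%/36%, concordance 0.69, validation errors 12–21%) depend
on its physical specimens and are emulation targets for the generator,
not reproducible quantities.

## Numerical choices

* Solver: supernodal Cholesky, Jacobi scaling, iterative refinement to
  1e-8 relative residual; singular systems and failed refinement are
  errors, never silent.
* Calibration: golden-section (MAPE) or bisection (signed) to a relative
  tolerance of 1e-3 on `alpha`; the bracket must straddle the signed-error
  root, otherwise the error message says to widen it.
* Down-sampling weights are exact interval overlaps; a trailing partial
  output voxel is normalised by its actual coverage.
* Cement placement breaks distance ties by voxel index, keeping fills
  deterministic.
* Percent fill above 100% (possible with independently segmented cement
  and void) is clamped to 100 with a warning.
* Problem sizes in the shipped tests and acceptance script: 14×14×22 and
  12×12×18 grids at 2 mm (roughly 1300–2100 elements, 4000–7300 DOFs),
  five slices and 4×4 cells for scoring, 20–50 Monte-Carlo replicates.

## Known limitations

* Pure voxel-hexahedral meshes have stair-stepped surfaces; the
  grayscale-based surface smoothing of the original commercial toolchain
  is out of scope, as are mixed tet/hex meshes.
* Linear elasticity only: no failure load, post-yield behaviour, contact
  or fatigue.
* The phantom is not anatomical — no posterior elements, no trabecular
  microarchitecture, no cortical shell — and fracture-void shapes are a
  modelling choice, not reconstructions.
* Image registration between pre- and post-augmentation scans is not
  implemented; the synthetic twins are voxel-aligned by construction.
* The fracture score's cell thresholds cannot claim equivalence to human
  severity judgements.
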