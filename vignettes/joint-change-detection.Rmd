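---
title: "Joint deformable registration and focal change detection: methods"
author: "jointchange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint deformable registration and focal change detection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(jointchange)
```

## The problem

Monitoring focal disease activity — most prominently multiple sclerosis
(MS) lesions — from two MRI scans of the same brain taken months or years
apart requires separating two entangled kinds of change.  Focal intensity
changes (new, growing, shrinking lesions) are the signal of interest.
Smooth geometric change (ventricular enlargement, cortical thinning —
brain atrophy) is a confound: if it is not compensated, intensity
subtraction lights up around the ventricles and cortex; if it is
compensated with an unconstrained deformable registration, the optimizer
also deforms tissue to "explain away" the appearing lesions, erasing the
very signal to be detected (lesion over-compensation).

`jointchange` treats registration and detection as one problem.  With
$I_1, I_2 : \Omega \to \mathbb{R}$ the baseline and follow-up scans, a
dense displacement field $w : \Omega \to \mathbb{R}^3$ and a binary
change map $c : \Omega \to \{0, 1\}$ are estimated together by
minimizing a single energy

$$
E(w, c) \;=\; \sum_{x \in \Omega}
  \Big[(1 - c(x))\, \rho(I_1, I_2, w, x) + \lambda_2\, c(x)\Big]
  \;+\; \lambda_1 \Psi(w) \;+\; \lambda_3 \Phi(c),
$$

with

* data term $\rho(x) = \frac{1}{\sigma^2}\,\lVert I_2(x - w(x)) -
  I_1(x)\rVert^2$ — backward warping with trilinear interpolation;
  $\sigma$ is the median absolute deviation (MAD) of the in-mask
  intensity differences, so $\rho$ is a squared robust z-score;
* field regularizer $\Psi(w) = \sum_x \lVert \nabla w(x) \rVert^2$
  (first-order Tikhonov, forward differences);
* change-map regularizer $\Phi(c)$, a binary Potts boundary penalty over
  the 6-neighborhood, written as the ordered-pair (double-counted) sum —
  every unordered differing neighbor pair costs $2\lambda_3$.

The coupling is the $(1 - c)$ factor: where a change is detected the data
term is cancelled, so the field there is driven by regularization alone
and cannot contract tissue to erase the lesion.  Conversely a good field
removes atrophy-induced residuals so the detector does not flag them.

## Optimization

The energy is nonconvex; it is minimized by alternation (at most 5 outer
iterations, stopping when the relative RMS field change and the fraction
of flipped labels both drop below $10^{-3}$).

**Field subproblem.**  The residual is linearized at the current field
$w_0$: writing $\tilde I_2 = I_2(\cdot - w_0)$ and $g = -\nabla \tilde
I_2$, the residual of the *total* field is $g^\top w + I_t$ with $I_t =
\tilde I_2 - I_1 - g^\top w_0$.  (The minus sign on the gradient comes
from the backward-warp convention $I_2(x - w(x))$; with it, the residual
is exact to first order and reduces to $I_2 - I_1 - \nabla I_2^\top w$
at $w_0 = 0$.)  The linearized problem — masked weighted least squares
plus Tikhonov — is convex and is solved in scaled-form ADMM with a
splitting variable $z$ for the regularizer:

* the $w$-update is a voxelwise proximal step with a rank-one Hessian,
  solved in closed form by the Sherman–Morrison identity; voxels with
  $c = 1$ or with warp samples outside the grid pass through unchanged;
* the $z$-update solves $(I + (2\lambda_1/\mu) L)\, z = v$ per component,
  where $L$ is the 6-neighbor Laplacian with Neumann boundary; this is
  diagonalized exactly by the 3D DCT-II, computed here through
  single-length (Makhoul) FFTs with all three components batched per
  call;
* the scaled dual update is $\alpha \leftarrow \alpha + \mu (w - z)$.

ADMM stops at a relative RMS change of $2 \times 10^{-3}$ or 300
iterations, and the *regularized* iterate $z$ is returned so smoothness
holds exactly at finite iteration counts.  Because the linearization is
valid only for small displacements, the solve is embedded in a
coarse-to-fine Gaussian pyramid (3 levels, factor 2, anti-aliasing sigma
$0.8 \times$ factor; 2 linearize-and-solve passes per level).  The
Tikhonov term penalizes the *total* field, not per-level increments, so
the prolonged field enters both the linearization and the regularizer.

**Change-map subproblem.**  With $w$ fixed, minimizing over $c$ is a
binary Potts labeling with unary costs $\rho(x)$ (label 0) and
$\lambda_2$ (label 1).  This submodular energy is minimized *exactly* by
max-flow/min-cut on the 6-connected voxel graph: source/sink t-links
carry $\rho$ and $\lambda_2$; each ordered neighbor relation contributes
an n-link of weight $2\lambda_3$, implementing the double-counted Potts
sum literally so printed $\lambda_3$ values keep their meaning.  With
$\lambda_3 = 0$ the solution reduces to the threshold rule
$c(x) = 1 \iff \rho(x) > \lambda_2$, with ties resolved to "no change".

**Order and initialization.**  Each outer iteration updates $w$ first
(detection needs a current field), starting from $c \equiv 0$ and
$w \equiv 0$.  The first iteration runs the full coarse-to-fine
schedule — making the *sequential* baseline exactly the first outer
iteration, a nesting verified bitwise in the tests — while later
iterations refine at full resolution only, initialized from the previous
field: restricting an already-converged field to the coarsest grid and
re-running the pyramid discards detail the alternation has earned, and
was observed to push the coupled energy back up.  A descent safeguard
completes the scheme: a field update that would increase the recorded
energy (possible, since the field step minimizes a linearized surrogate)
is rejected and the alternation stops at the previous iterate.  Change
maps are downsampled *conservatively* onto coarse pyramid grids (any
overlap masks the coarse voxel): with majority downsampling a
small lesion's mask vanishes at coarse levels and the data term erases
the lesion there anyway.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `lambda1` | 70 | Tikhonov weight; the published value, tuned on longitudinal atrophy data |
| `lambda2` | 16 (preset `lesjakdb`), 25 (`msseg2`) | detection threshold on the squared robust z-score |
| `lambda3` | 5 (`lesjakdb`), 3 (`msseg2`) | Potts boundary weight |
| `mu` | 1 | ADMM penalty (unpublished; see below) |
| pyramid | 3 levels, factor 2, 2 warps/level | coarse-to-fine schedule (unpublished; conventional for few-voxel displacements) |
| ADMM stop | tol 2e-3, cap 300 | published stopping rule |
| outer stop | tol 1e-3, cap 5 | published stopping rule |

Design choices where the published description is silent or ambiguous:

* **ADMM penalty `mu = 1`.**  With the data term normalized by
  $1/\sigma^2$, a unit penalty is a balanced default.  Larger values
  (10–30) reach a lower *linearized* objective in fewer iterations, but
  the early-stopped iterate at `mu = 1` is smoother and recovers known
  smooth deformations more accurately in our experiments, so the default
  favors field quality over inner-loop speed.  The exactness tests
  instead run ADMM to a tight tolerance, where the solver matches a
  direct sparse solve of the same quadratic.
* **Scaled-form prox.**  The update equations are implemented in
  standard scaled form (both proximal steps carry $1/\mu$), which is the
  form with convergence guarantees.
* **$\sigma$ estimation.**  When $\sigma$ is estimated — before or after
  registration — is not pinned down by the published description.  Here
  it is re-estimated from the currently warped pair inside the brain
  mask throughout the *first* alternation (so the scale is calibrated on
  registered residuals, not raw misalignment) and then **frozen** for
  all subsequent outer iterations.  Freezing matters: if $\sigma$ keeps
  changing, the recorded energy is not a single objective (the data
  term is rescaled between iterations) and the alternation can appear
  to — and effectively does — ascend it; with $\sigma$ fixed, the
  graph-cut step is an exact minimizer of the recorded energy and the
  alternation is genuine block-coordinate descent.
* **Stopping norms.**  "Relative change" is the RMS over all field
  components with an $\varepsilon = 10^{-12}$ guard; for the binary
  map the outer criterion uses the fraction of flipped labels, since a
  relative norm is undefined for labels.
* **Tie-breaking** at $\rho = \lambda_2$ resolves to no-change,
  matching the thresholding rule's $\le$ branch.
* **Returned iterate** is $z$ (regularized), not $w$.

## Preprocessing and post-processing

The detection framework assumes a harmonized pair: intensities scaled so
the in-mask median is 100, grids resampled to 1 mm isotropic, and the
*differential* bias field removed by dividing the follow-up by
$\exp(M)$, where $M$ is a cubic median filter (default $21^3$) of
$\log(I_2/I_1)$ computed inside the brain mask — a robust smooth estimate
of the multiplicative inter-scan intensity discrepancy.  Out-of-mask
voxels receive no correction.  Absolute bias correction (e.g. N4) and
tissue segmentation are upstream preconditions: the pipeline accepts
already-corrected inputs and mask files.  A simple multiresolution
Nelder-Mead affine pre-alignment over negative normalized
cross-correlation is included as plumbing for inputs that are not yet
aligned; it makes no parity claim with dedicated registration tools.

Detected maps are cleaned by discarding connected components smaller
than 3 mm³ (26-connectivity; the convention is configurable since the
published description does not state it) and removing detections outside
the brain parenchyma (gray + white matter), and can be split into
positive- and negative-change maps by the sign of the warped difference.

Evaluation reports voxel-wise DSC, PPV and TPR; *local* DSC restricted
to the dilation of the ground truth by a 4-voxel-radius Euclidean ball;
and lesion-wise L-TPR / L-PPV over 18-connected components with a 10%
minimum overlap fraction for a detection to count.  The overlap
threshold approximates the anima/Commowick convention, whose exact
hyperparameters are not reprinted in the source description, and is
configurable.  For truly change-free pairs the component count and total
detected volume (cm³) are reported instead.

## The synthetic generator

Real longitudinal MS data cannot ship with a package, so the test
surface is a seeded generator (`scenarioSpec()`, `makePair()`)
emulating a simulated-phantom study design:

* **Phantom** (`makePhantom`): nested ellipsoids — a thin gray-matter
  shell, white-matter interior, two CSF ventricles — with T2-like
  intensity ordering CSF (250) > GM (120) > WM (90), a 0.5-voxel
  point-spread blur standing in for partial volume, and ~2% smooth
  intra-tissue texture.  A geometric stand-in, not an atlas.
* **Lesions** (`addLesions`): spheres sampled in eroded white matter,
  with +150 contrast (nearly CSF-bright, the typical T2 appearance of
  demyelinating lesions).  *Appearance* adds them only at follow-up;
  *growth* enlarges baseline lesions by a radius increment.  The ground
  truth is the discrete lesion extent in baseline coordinates, where the
  residual of a perfectly registered pair is evaluated.
* **Atrophy** (`makeAtrophyField`): a smooth seeded radial field
  expanding the ventricles and contracting the cortex, normalized to a
  peak displacement that scales with the grid (default
  $0.028 \times \min(\text{shape})$ voxels — the anatomy-relative
  equivalent of a ~5-voxel peak on a full-size 181-voxel scan) and
  verified diffeomorphic (positive Jacobian determinant of
  $x - w(x)$).  The original study used a patient-derived field that is
  not publicly available; this stand-in reproduces its *mechanism*
  (smooth ventricle-centered deformation), so ground-truth recovery and
  the joint-vs-sequential-vs-affine *ordering*, not the study's exact
  metric values, are the meaningful test surface for atrophy scenarios.
* **Corruption** (`corrupt`): a low-order polynomial multiplicative
  bias field spanning $[0.8, 1.2]$ (20% amplitude) and additive Gaussian
  noise with sd equal to 5% of the mean intensity of the brightest
  tissue (CSF), drawn independently per timepoint.  Rician noise is not
  modeled.

What the generator does *not* emulate: real anatomy and its fine
structure, multi-tissue partial-volume mixtures, acquisition artifacts
(motion, ghosting), Rician noise statistics, or patient-specific atrophy
patterns.  Passing tests therefore demonstrate the mechanics and the
relative behavior of the three pipelines under controlled conditions,
not clinical-grade accuracy on real scans.

## Problem sizes used by the tests and the acceptance script

The full-size study (181×217×181) reported ~24 CPU-minutes for a single
joint run.  The package's own experiments use scaled-down phantoms so
the complete three-method, five-seed comparison remains a desk-scale
computation: 40³ grids for the multi-seed method-ordering experiment and
the masked-data-term checks, 48–64³ for single registration-recovery
cases.  The atrophy amplitude scales with the grid (see above) so these
scaled-down runs represent the same relative deformation as a full-size
study.

## Known limitations

* The alternation minimizes a nonconvex energy: descent of the recorded
  (nonlinearized) energy is expected and monitored, not guaranteed; the
  tests require it on at least 90% of seeded runs.
* No symmetric / inverse-consistent registration: detection of
  *disappearing* lesions behaves differently from appearing ones under
  the backward-warp convention, as the asymmetry discussion in the
  source work notes.
* No diffeomorphic parameterization of the field; plausibility is
  monitored through the Jacobian determinant, not enforced.
* The affine pre-alignment is plumbing (NCC + Nelder-Mead), not a
  substitute for a production affine registration.
* Detection is intensity-difference-based; modality pairs needing
  mutual information are out of scope.
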