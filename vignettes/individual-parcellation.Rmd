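---
title: "Individual-space atlas parcellation of rodent brain MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual-space atlas parcellation of rodent brain MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memriparc)
```

## The problem

Region-of-interest (ROI) analysis of rodent MRI — and of manganese-enhanced
MRI (MEMRI) in particular — conventionally normalises every subject into a
stereotaxic standard space and reads ROI signal off a fixed atlas.
Normalisation resamples the subject's voxels, and interpolation mixes the
signal of enhanced voxels with that of their unenhanced neighbours: the
mean signal of a small active region is systematically diluted, and
case-control contrasts lose sensitivity. Manual tracing in native space
avoids the dilution but is slow, subjective and irreproducible.

`memriparc` automates the alternative: bring the atlas to the subject.
The subject's anatomy is registered *into* standard space once, the
transformation is inverted, and every atlas region is carried back onto
the native grid as an independently warped binary mask. The subject's
voxel intensities are never resampled.

## The pipeline

For an individual volume $I$ (for 4D MEMRI series: after rigid realignment
of the repetitions to the first volume and voxel-wise averaging):

1. **Registration** (`register_affine`, `register_nonlinear`,
   `register_diffeomorphic`). Template path: a 12-parameter affine
   (translation, rotation, log-scale, shear about the volume centre) is
   estimated by Nelder–Mead ascent of normalised cross-correlation (or
   32-bin mutual information across modalities) over a 3-level Gaussian
   pyramid, then refined by a cubic B-spline free-form deformation (FFD)
   minimising sum-of-squares intensity mismatch with a bending-energy
   penalty on the control lattice, optimised by L-BFGS-B with an analytic
   gradient, coarse to fine. TPM path: a stationary velocity field is
   estimated on tissue probability maps by greedy multi-channel
   gradient iterations with fluid-like Gaussian regularisation and
   exponentiated by scaling and squaring, which guarantees a positive
   Jacobian. All transforms follow the pull-back convention (a transform
   maps target-space world coordinates to source-space world
   coordinates), so registering the individual to the template directly
   yields the standard-to-individual map used for normalisation.
2. **Inversion** (`invert_affine`, `invert_deformation`). Affines invert
   exactly. Dense fields invert by damped fixed-point iteration
   $v \leftarrow -u(x + v)$ evaluated on the individual grid (the grid on
   which masks will be resampled), with the achieved composition residual
   recorded; the iteration contracts whenever the forward field's
   voxel-unit displacement gradients stay below one.
3. **Atlas splitting** (`split_atlas`). Every atlas region is resaved as
   an independent binary mask so that neighbouring labels cannot bleed
   into each other during interpolation — interpolating the integer label
   image directly would either stairstep (nearest neighbour) or invent
   intermediate labels (higher orders).
4. **Mask warping** (`warp_mask`). Each mask is resampled onto the
   individual grid through the inverse transform with 4th-degree B-spline
   interpolation. The spline coefficients are computed by recursive
   prefiltering (mirror boundaries) so that the kernel interpolates
   rather than smooths; values may legitimately over- and undershoot 0/1
   (spline ringing) and are kept unclipped as continuous memberships.
5. **Binarisation and refinement** (`binarize`, `refine_boundary`).
   Memberships at or above 0.5 become region voxels; each region is then
   opened (eroded and dilated) with a one-voxel-radius disc. The disc is
   applied slice-wise in-plane by default because thick-slice rodent
   acquisitions (here 0.14 mm in-plane vs 1.2 mm through-plane) make 3D
   opening destructive on structures one slice thick; a 6-connected 3D
   ball is available by flag.
6. **Recombination** (`combine_rois`). Refined regions are reassembled
   into one label image. A voxel claimed by several regions goes to the
   highest membership, ties to the smaller region, remaining ties to the
   lower index — deterministic and order-independent. Gaps opened by the
   refinement stay unlabelled and are reported, not in-filled: in-filling
   would fabricate boundary voxels the data do not support. Regions that
   vanish entirely are reported with a zero count rather than erroring,
   since small regions can legitimately disappear at coarse through-plane
   resolution.

`parcellate_individual()` chains the stages; `run_parcellate()` /
`run_evaluate()` and the script in `inst/cli/` expose the same pipeline on
NIfTI files.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| interpolation `degree` | 4 | – | "4th-degree" B-spline, the convention of SPM-style pipelines; degree is configurable (0/1/3/4) so cubic can be compared |
| binarisation `threshold` | 0.5 | membership | majority coverage; the natural boundary under spline ringing |
| refinement `radius`, `element` | 1, `disc2D` | voxels | one-voxel disc opening; slice-wise by default on anisotropic grids |
| FFD `grid_spacing` | 4 | fixed-grid voxels | resolves deformations a few voxels in wavelength while keeping the lattice small |
| FFD `reg_weight` | 0.005 | – | bending penalty weight; larger values always give smoother fields (lower roughness) — note that the *global mean* displacement can grow with the weight, because a smooth field extrapolates in-brain displacement into the background instead of decaying |
| inversion `tol` | 0.01 affine / 0.05 field | voxels | convergence and acceptance thresholds for the fixed-point inverse; failure above 10x tol is a hard error naming the worst voxel |
| normalisation `out_voxel` | (1, 1, 1.5) | mm | reslice size used when comparing against conventional normalisation |

Interpolation degree deserves one note: "4th B-spline" in the source
tooling's menus means polynomial degree 4, and that is the reading adopted
here; degree 3 remains available for sensitivity checks. FFD coefficients
are internally kept in voxel units so that the optimiser is equally
conditioned along 0.14 mm and 1.2 mm axes.

## The synthetic phantom

No rodent images are shipped; every test and the acceptance run generate
their own ground truth with `make_phantom()`:

* **Template and atlas** — an ellipsoidal "brain" (64 x 64 x 24 voxels at
  0.14 x 0.14 x 1.2 mm, echoing the anisotropy of thick-slice MEMRI) with
  66 regions formed by a centroidal Voronoi partition (4 Lloyd
  iterations) of seeded interior points. The partition uses the voxel
  metric so that regions span several slices even on anisotropic grids,
  and each region boundary is smoothed by the same disc opening used in
  the pipeline — hand-drawn anatomical ROIs are smooth, and a staircase
  partition would charge the refinement stage for raggedness the data
  never had. The few unlabelled interstitial voxels this leaves mirror
  real functional atlases, which do not tile the whole brain. Template
  texture is a per-region intensity offset (±25% of the base intensity
  100), smoothed; TPMs are a smoothed tissue indicator and its
  complement.
* **Ground-truth deformation** — a separable sinusoid, by default 2
  voxels amplitude and 20 voxels wavelength, with component dependencies
  $u_x(y), u_y(x), u_z(z)$ and displacements scaled per-axis by voxel
  size. Every voxel-unit displacement gradient is then bounded by
  $2\pi A/\lambda$ regardless of grid anisotropy, so the stated bound
  $2\pi A/\lambda < 1$ simultaneously guarantees a diffeomorphism and a
  contractive fixed-point inversion. (Coupling a 2.4 mm through-plane
  displacement to a 2.8 mm in-plane wavelength, as a naive axis pairing
  would, produces mm-space shears above 5 — no anatomy deforms that way.)
  The analytic direction is the individual-to-standard map used to
  synthesise the individual image; the opposite direction is computed
  numerically and accepted only if the composition residual is below
  0.01 voxel.
* **Ground-truth individual parcellation** — each voxel takes the label
  whose exact-warped fractional coverage (trilinear membership) is
  largest and at least 0.5, followed by the same disc opening. This
  majority-coverage rule shares no kernel with the pipeline's quartic
  path. Cohort simulations use plain nearest-neighbour label carry
  instead, which is cheaper and sufficient for placing and extracting
  the enhanced-region signal.
* **MEMRI series** — within the brain support the base intensity is
  uniform (100); enhanced regions carry
  $\textrm{base} \cdot \textrm{contrast} \cdot (1-\textrm{decay})^k$ in
  repetition $k$ (defaults: contrast 5, decay 0.1, six repetitions,
  emulating manganese uptake in active regions and its measured
  downtrend), plus Gaussian noise of SD 5. The base is deliberately flat
  so that the enhancement arithmetic is exact; anatomical texture lives
  in the structural volume used for registration.
* **Cohorts** (`make_cohort`) — one shared template (the common standard
  space); per-subject deformation phases, noise and series derive from
  the master seed. Model subjects have their contrast multiplied by
  $(1-\textrm{effect})$, emulating reduced activity; five healthy versus
  ten model subjects reproduce the case-control design the evaluation
  statistics are aimed at.

What the phantom does *not* emulate: Rician MRI noise (additive Gaussian
only), intensity bias fields, partial-volume mixtures at the brain edge,
susceptibility distortion, or manganese pharmacokinetics. Passing tests
therefore demonstrate the correctness of the geometry, interpolation,
morphology and statistics machinery under realistic resolutions and
deformation scales — not robustness to every artefact of real
acquisitions.

## Numerical choices and degenerate inputs

* Out-of-domain resampling pads with zero (brains and masks are zero
  outside the head); the interpolation domain is the convex hull of voxel
  centres. Spline prefiltering and kernel taps use mirror boundaries.
* Field evaluation outside a deformation field's grid returns flagged
  `NA`s for point mapping, but the iterative machinery (inversion,
  exponentials) extrapolates by edge clamping, which is exact for fields
  whose components do not vary along the clamped axis and benign
  otherwise.
* The fixed-point inverter damps its step (halving down to 0.25) when the
  update oscillates; the registered-field inversion tolerance (0.05
  voxel) is looser than the analytic-field tolerance because estimated
  FFDs are rougher than the smooth truth.
* Zero-variance t-test inputs: equal means give $t = 0, p = 1$ by
  convention; unequal means give $p = 0$.
* Ties in `combine_rois` resolve membership > volume > index, making the
  result independent of mask order.
* Self-registration of identical images is exact up to optimiser
  termination (translations below 0.1 voxel, rotations below 0.2 degrees
  in tests).

## Problem sizes

The bundled analyses run at the phantom's native 64 x 64 x 24 grid for
everything pipeline-shaped (registration, inversion, 66-region warping),
and at 32 x 32 x 12 with 12 regions for the repeated statistical
simulations (100 phantoms for the interpolation-dilution check; 100
cohorts of 15 subjects each for power and size of the two-sample t-test).
Group statistics do not depend on grid size, so the smaller grid is used
there to keep the simulations plentiful.

## Known limitations

* The diffeomorphic path operates on whatever TPMs are supplied; with
  only two classes (tissue/background) the data constrain mainly
  boundary-normal motion, and interior deformation is recovered weakly.
  Its contracts (identity on self-registration, positive Jacobian,
  integrator agreement) hold regardless. Richer tissue classes would be
  needed for accuracy parity with the template path.
* The template path's FFD recovers the study deformation to roughly one
  voxel inside the brain; whole-brain overlap after the full pipeline is
  around 93–96%, comfortably above the 80% agreement bar, but individual
  region boundaries inherit registration error.
* Creating TPMs from raw images (unified segmentation), group-wise
  template construction, and slice-timing correction are out of scope;
  TPMs are accepted as input.
* The package assumes NIfTI-1 with a trustworthy affine; DICOM and
  scanner raw formats are not read.
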