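# memriparc

Automatic individual-space atlas parcellation of rodent brain MRI and
manganese-enhanced MRI (MEMRI), for imaging groups doing ROI-based
analyses of small-animal studies.

Conventional ROI analysis normalises every subject into a stereotaxic
standard (Paxinos-style) space and reads signal off a fixed atlas — but
resampling mixes enhanced voxels with unenhanced neighbours, diluting
exactly the signal MEMRI is meant to measure. `memriparc` inverts the
workflow: the subject is registered *into* standard space once, the
transformation is inverted, and every atlas region is carried back onto
the subject's native grid as an independently warped binary mask. Native
voxel intensities are never resampled.

## The method

Given an individual volume (or a 4D MEMRI series, which is rigidly
realigned and averaged first):

1. estimate the individual-to-standard transformation — either affine +
   B-spline free-form deformation against an intensity template, or a
   stationary-velocity diffeomorphism (exponentiated by scaling and
   squaring) on tissue probability maps;
2. invert it exactly (affine) or by damped fixed-point iteration (dense
   field), with the composition residual verified in voxels;
3. split the atlas: each region becomes an independent binary mask
   (inside = 1, outside = 0), so neighbouring labels cannot bleed into
   each other during interpolation;
4. warp each mask onto the individual grid through the inverse transform
   with 4th-degree B-spline interpolation (prefiltered, true
   interpolation);
5. threshold memberships at 0.5 and refine each region by morphological
   opening with a one-voxel disc (slice-wise in-plane by default, suited
   to thick-slice acquisitions);
6. recombine the refined regions into one label image, resolving
   contested voxels by membership, then region size, then index.

Evaluation tools include the Dice similarity coefficient
`2|A∩B| / (|A|+|B|)` between masks, Otsu-based whole-brain masking, ROI
time-course extraction in individual versus normalised space, and pooled
or Welch two-sample t-tests for case-control designs. A synthetic
phantom generator supplies a labelled ellipsoidal brain, ground-truth
diffeomorphic warps, MEMRI-like decaying series, and case-control
cohorts, so the entire pipeline is testable without any data download.

## Worked example

```r
library(memriparc)

# a synthetic subject with known ground truth
bundle <- make_phantom(phantom_spec(seed = 42))

# full pipeline: template path (affine + nonlinear), inversion, per-region
# warping, refinement, recombination
parc <- parcellate_individual(bundle$individual, bundle$template,
                              bundle$atlas, path = "template")
parc
#> <parcellation> 66/66 regions, 29791 labelled voxels

# whole-brain agreement between the subject's brain mask and the
# parcellation union
dice(brain_mask(bundle$individual), parcellation_union(parc))
#> Dice_MePa = 0.9336  (|A| = 32172, |B| = 29791, |AnB| = 28924)

# native-space ROI time course of an enhanced region vs the same region
# read after conventional normalisation: interpolation dilutes the
# normalised signal at every repetition
cs <- compare_spaces(bundle$series,
                     structure(list(labels = bundle$truth_labels$labels),
                               class = "parcellation"),
                     bundle$truth_std_to_ind, bundle$atlas, roi_index = 1)
round(rbind(individual = cs$individual$means,
            standard   = cs$standard$means), 1)
#>            [,1]  [,2]  [,3]  [,4]  [,5]  [,6]
#> individual 500.4 450.2 405.6 364.6 327.9 295.2
#> standard   413.1 373.1 337.3 304.2 274.9 248.6
```

The Dice value of 0.9336 says the parcellation union recovers 93% of the
subject's brain after a 2-voxel synthetic deformation with 5% noise
(0.80 is the conventional excellent-agreement bar). The time-course rows
show the enhancement signal (5x contrast decaying 10% per repetition)
read in native space versus after normalisation — the normalised means
sit below the native ones at every repetition, which is the dilution the
method exists to avoid.

File-based workflows (`run_parcellate`, `run_evaluate`, `run_phantom`)
and a thin command-line wrapper (`inst/cli/memriparc.R` with `phantom`,
`parcellate`, `evaluate` subcommands) expose the same pipeline on NIfTI
inputs. See the vignette in `vignettes/` for the model, parameter and
design discussion.

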