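---
title: "Methods: task-induced deactivation and DMN connectivity classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: task-induced deactivation and DMN connectivity classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmnclass)
```

## What this package computes

The default mode network (DMN) — medial prefrontal cortex (MPFC),
posterior cingulate/precuneus (PCC/PrC), angular gyrus (AG) and related
midline/parietal regions — deactivates during goal-directed tasks and
fluctuates coherently at rest.  Two families of statistics quantify it
from blocked-design fMRI:

1. **Task-induced deactivation.**  A per-subject GLM regresses each
   voxel/ROI time series on HRF-convolved condition boxcars; the
   rest-minus-task contrast is positive where the region deactivates
   during task.  Group inference is a random-effects t test on
   subject-level contrasts, thresholded voxelwise and by cluster extent.

2. **Pseudo-resting-state connectivity.**  Rest (fixation) blocks are
   excised and concatenated into a pseudo-resting-state series, nuisance
   signals are regressed out, and connectivity is computed as Pearson
   correlation — seed-to-voxel maps (Fisher z transformed and averaged
   over three canonical seeds into one DMN map per subject) and an
   ROI-by-ROI z matrix over a 116-label parcellation reduced to 102
   usable ROIs.  A leave-one-out logistic regression classifies subjects
   into groups from these features; accuracy is tested against an exact
   binomial null B(n, p).

Because no public scan data accompany the design this package emulates,
a synthetic cohort generator produces a 13 + 14 two-group cohort with
planted group differences, so the full chain is testable end to end.

## The pseudo-resting-state extraction

Each of the three built-in runs (sentence comprehension; word/self-other
judgment; intentional-causality cartoons) interleaves task blocks with
fixation blocks — 5 x 24 s, 7 x 15 s and 5 x 24 s respectively, 17 rest
blocks and 345 s of rest in total at TR = 1 s.  `excise_rest_blocks()`:

* drops the first `lag = 6` s of every rest block (hemodynamic return to
  baseline);
* when all of a run's rest blocks are shorter than `append_threshold =
  20` s (the 15-s study), appends the first 6 s of the following task
  block to each segment (the hemodynamic delay means those volumes still
  carry rest-like signal);
* converts seconds to volumes conservatively (`ceiling(lag / tr)`
  volumes dropped; half-open 0-based windows), which is exact at TR = 1.

This yields 90 + 105 + 90 = 285 retained volumes per subject.  Segment
provenance is kept so detrending stays within session.

## Nuisance model

`build_nuisance()` assembles: the six rigid-body motion parameters; one
mean-motion column (per-volume RMS of the six, centred — the upstream
description of a single "mean head motion" regressor is ambiguous, and
this choice is recorded in the output labels); the mean signal of gray
matter, white matter, CSF and whole brain from template-style masks (in
roi mode, a single global column — the mean across ROIs); and one
intercept plus one linear trend per session.  No band-pass filter is
applied by default because the emulated procedure states none.

Two numerical caveats are deliberate and tested:

* The synthetic tissue masks do not tile the brain exactly, so the
  whole-brain mean is not an exact linear combination of the tissue
  means; a rank-deficient nuisance matrix is still handled (pivoted QR
  pseudo-inverse) with a warning.
* In roi mode the "global" stand-in is the mean of only 10 node time
  courses, so it shares variance with the DMN nodes and shrinks absolute
  z values (a planted r = 0.6 cleans to roughly z = 0.3).  Both groups
  shrink alike, so group contrasts and classification are unaffected;
  voxel mode computes the global over the whole brain where the
  contamination is negligible.

## Deactivation GLM and cluster inference

The HRF is the canonical double gamma (response gamma shape 6, scale
1 s; undershoot shape 16, ratio 1/6), normalised to unit area so a
sustained block plateaus at the boxcar height and planted amplitudes
keep their BOLD-unit meaning.  In the built-in designs the blocks tile
the run, so modelling rest explicitly alongside task and an intercept is
collinear; the default treats rest as the implicit baseline and reads
deactivation from negated task coefficients.  `fit_glm()` drops
collinear columns with a warning and refuses contrasts on dropped
columns.

Cluster-extent correction follows the Monte-Carlo convention: simulate
Gaussian noise in the mask, smooth to the stated FWHM (then restandardise
in-mask), threshold two-sided at the voxelwise p, and take the smallest
extent k whose exceedance probability is at most alpha.  The default
connectivity rule is 18 neighbours, configurable to 6 or 26.  Two-sided
thresholding was chosen because the emulated procedure quotes z = 3.53
with p < 0.001, a pairing that matches neither a one- nor a two-tailed
convention exactly; both the z and p thresholds are exposed in
configuration and the inconsistency is not asserted anywhere.

## Connectivity and classification

Seeds default to MPFC (-1, 47, -4), PCC/PrC (-5, -49, 40) and left AG
(-45, -67, 36) with a 6-mm radius (a common convention for 3-mm grids;
the radius is configurable, and coarse test grids use larger radii so
spheres contain at least one voxel centre).  Correlations are Fisher
transformed first and averaged afterwards (transform-then-average; the
alternative order is configurable in principle but not the default).
`atanh` inputs are clamped at |r| = 1 - 1e-7, and zero-variance series
yield z = 0 with a flag rather than NaN.  Seed-sphere voxels are removed
from ROIs for seed-based feature vectors only; the full ROI-by-ROI
matrix uses intact ROIs.

The classifier is L2-regularised logistic regression (glmnet ridge path,
coefficient read at the requested penalty; default strength 1.0).  Plain
unregularised logistic regression — features of 5151 connections against
26 training subjects — has no defined optimum, so some penalty is a
necessity, not a tuning choice; the strength is exposed in configuration.
Features are standardised with training-fold statistics only, predicted
probabilities of exactly 0.5 fall back to the training-fold majority
class, and the per-fold weight vectors are averaged for the
informative-connection report (`ceiling(fraction x d)` connections per
class, signed-weight ranking, ties broken by feature order and flagged).
Chance probability defaults to 0.5, with the class-prior alternative
available.

## The synthetic cohort: what it emulates, and what it does not

`make_dmn_cohort_spec()` states the world once:

* 13 clinical-like ("a") and 14 control-like ("b") subjects, three runs
  each on the canonical designs.
* Control correlation targets: MPFC-PCC 0.6, PCC-AG 0.6, other
  within-DMN pairs 0.5, background 0.1.  Group a reduces the MPFC's
  couplings to the other DMN nodes by `effect_size` (default 0.3) and is
  re-projected to the nearest positive semi-definite correlation matrix
  (eigenvalue clipping, diagonal renormalisation).
* Deactivation amplitudes: -1 BOLD unit in DMN nodes for controls,
  attenuated to -0.4 in group a.
* Nuisance components: white noise (sd 0.5), linear drift (0.005 per
  volume), a global fluctuation (amplitude 0.5), a motion-coupled
  component (0.3, tied to the first of six random-walk motion
  parameters).  These amplitudes were chosen once for realistic
  signal-to-noise at 285 rest volumes and are exposed in the spec, not
  tuned against any test.
* A 30 x 36 x 30 grid of 6-mm voxels spanning an MNI-like bounding box,
  with an ellipsoidal brain mask and a 116-label synthetic atlas (node
  spheres plus slab-shaped pseudo-ROIs; the 14 lowest slabs form the
  default exclusion list, emulating the vermis/cerebellum exclusions of
  a real parcellation by count only).

It does **not** emulate: physiological noise spectra, scanner artefacts,
spatial autocorrelation of real BOLD, anatomically shaped parcels, or
empirical effect sizes (none are published for this design).  A green
recovery test therefore establishes that the pipeline's statistics
recover the effects the generator plants at desk scale — not that the
published group results would reproduce.

## Numerical and design choices worth knowing

* Seconds-to-volumes conversions are conservative (`ceiling`), exact at
  TR = 1 s.
* Smoothing uses symmetric-reflection boundaries; interior impulses
  preserve mass to 0.1% and match the analytic 3D Gaussian peak to 1%.
* The LOOCV permutation null is intentionally asserted to sit at or a
  few points *below* 50%: under label permutation the held-out subject's
  class is always under-represented in its training fold, a known
  negative bias of leave-one-out accuracy.  Tests assert that corrected
  property rather than a naive "mean = chance" band.
* The detection-rate test for a 2-sd univariate group difference checks
  the empirical rate against the exact noncentral-t power of the
  Bonferroni-corrected test (0.879 at n = 13 + 14) rather than a round
  90% figure.
* Whether the 6-s task appendage should also apply to 24-s-rest runs is
  not documented upstream; the default applies it only when all rest
  blocks are shorter than 20 s, and the threshold is configurable.

## Limitations

Volumes live in memory as R arrays with explicit affines; no NIfTI
reader/writer is bundled (none is available in the supported dependency
set), so interchange with scanner data requires converting to the
package's array + affine representation.  The cluster simulation
assumes Gaussian noise; group t maps are thresholded at t quantiles but
the extent null is simulated from z, a standard approximation.  The
classifier deliberately omits nested hyper-parameter tuning.
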