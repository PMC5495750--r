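---
title: "Searchlight RSA of preparatory target templates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searchlight RSA of preparatory target templates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(templight)
```

## The scientific problem

Before a visual search begins, the brain holds a *target template*: a
working-memory representation of what is being looked for.  When the target
is defined by one feature dimension of a cue (its spatial frequency, say,
rather than its orientation), attention can be weighted toward that
dimension.  `templight` implements an analysis pipeline that asks *where*
such dimension weighting is represented: subjects view one of nine Gabor
cues (3 orientations x 3 spatial frequencies) under one of two task
instructions (search for the cue's SF, or for its orientation), hold the
template over a jittered delay, and then search a six-item display.
Representational similarity analysis (RSA) of the cue-period and
delay-period BOLD responses compares the observed pattern geometry of the
18 conditions (9 cues x 2 tasks) against two model hypotheses:

* a **dimension-weighted model**: conditions sharing a task-relevant
  dimension are represented maximally similarly (representational distance
  RD = 0) and conditions of different tasks maximally differently (RD = 2);
* an **HMAX C1 model**: a purely sensory account, where the dissimilarity
  of two conditions is the correlation distance between simulated
  complex-cell (C1) responses to their cue images, regardless of task.

The raw study data are not public, so the package ships a forward model:
a synthetic multi-subject BOLD generator that plants either
representational geometry into chosen ROIs at a controlled
signal-to-noise ratio.  Every downstream stage — GLM, searchlight,
group inference — is then validated by parameter recovery.

## Representational distances

All dissimilarities are correlation distances, `RD = 1 - Pearson r`,
ranging over `[0, 2]` with 0 = identical, 1 = uncorrelated,
2 = sign-flipped patterns.  Model-to-data agreement is the Pearson
correlation between the vectorized upper triangles (153 condition pairs)
of the neural and model RDMs, reported after the variance-stabilizing
Fisher z transform `atanh(r)`.  Correlations at `|r| >= 1` are clipped to
`1 - 1e-7` with a warning.  Condition order is fixed (SF-task conditions
1-9, then ORIENTATION-task conditions 1-9, cue id ascending) and the
row-major upper-triangle vectorization is part of the package contract.

The cross-task distance of the dimension-weighted model is set to 2 (the
scale maximum).  Pearson correlations are invariant to a positive
rescaling of the model, so this choice is cosmetic.  In the expanded
stimulus model the same cue under the two tasks is assigned RD 0: the
sensory model is blind to the task.

## Experimental design generation

A block holds 27 trials: the three task instructions ordered by a
randomized order-3 De Bruijn sequence over the 3-letter instruction
alphabet (each instruction 9 times, every instruction 3-gram exactly once
cyclically), with each of the 9 cues appearing once per instruction.  Cue
durations take 9 values log-uniformly spaced on [1, 2.5] s and delay
durations 9 values on [2.5, 6.5] s, each value three times per block; the
two assignments are shuffled independently, which makes cue and delay
durations uncorrelated across trials (|mean r| < 0.05 over seeds) and is
what lets one GLM separate cue-period from delay-period responses.  The
exact jitter values are not published; log-uniform spacing inclusive of
the endpoints is this package's deterministic reading of a "logarithmic
distribution of 9 values".  The unpublished inter-trial interval defaults
to 1 s, which reproduces the reported ~5 min 22 s block duration almost
exactly (we compute ~5 min 21 s); it is a convenience, not a claim.  The
EXACT-image task occupies a third of each block but is never analyzed;
the package schedules it and refuses to build its search displays.

Gabors are rendered with an even-symmetric cosine carrier under a
Gaussian envelope with sigma = diameter/6 (a conventional psychophysics
default; the study does not state its envelope), on a mid-gray
background.  Search displays place six Gabors at 60-degree steps on a
circle of radius 8.37 degrees, rotated so no item sits on the vertical
meridian and every item has a defined side.

## HMAX front end

Only the S1 (simple cell) and C1 (complex cell) stages are implemented,
because only C1 feeds the stimulus model.  S1 kernels are zero-mean,
unit-norm Gabor filters at 4 orientations and (by default) 8 sizes
(7-21 px) with the standard size-to-sigma/wavelength mapping and aspect
ratio 0.3; responses are absolute normalized cross-correlations, bounded
in [0, 1].  C1 takes the max over paired adjacent scales and over spatial
windows (8-14 px, stride half a window).  The exact HMAX parameterization
behind the study's citation is unknown, so all parameters are
constructor arguments and the package asserts *properties* (translation
tolerance of C1 relative to S1, orientation tuning, RDM validity) rather
than numeric matches to the published color map.  The 9 x 9 C1 RDM shows
the expected structure: cues sharing an orientation are far closer than
cues differing in both dimensions.

## Forward model

The simulator is the package's ground truth.  For a target RDM `D` the
condition-correlation matrix `C = 1 - D` is factorized by
eigendecomposition (eigenvalues below -1e-10 are rejected as non-PSD,
small negatives truncated), and `18 x V` voxel patterns are drawn as
`E sqrt(L) Z` with i.i.d. normal `Z`, so the empirical pattern RDM
converges to the target as the ROI grows.  The voxel time series is the
sum over conditions of `amplitude x pattern x regressor`, where the
regressor is the condition's phase boxcar (exact onsets/offsets) convolved
with a unit-peak double-gamma HRF (peak 6 s, undershoot 16 s, dispersions
1 s, peak:undershoot 6 — canonical values; the study names only the HRF
family), plus white Gaussian noise (optional AR(1)).  Amplitude is
expressed in units of the noise sd.  The defaults emulate the study's
structure (TR 2 s, 18 conditions, 11-subject cohorts supported) on a
24^3-voxel 3 mm grid, a desk-scale stand-in for the 80 x 80 x 36
acquisition.  What the generator does *not* emulate: physiological noise,
motion, registration error, spatial autocorrelation of noise, and
between-region heterogeneity — so passing recovery tests demonstrate the
pipeline's correctness, not robustness to every property of real data.

## GLM

Beta estimation is mass-univariate OLS on a design with one HRF-convolved
regressor per condition for the period of interest, per-condition
regressors for the *other* period, shared nuisance regressors for search,
instruction and EXACT-task events, and a polynomial drift basis (order 2).
Modeling the other period condition-wise is deliberate: with a single
pooled nuisance regressor, condition-specific delay signal leaks into
cue-period betas at more than the planted amplitude (we measure ~1.3x),
whereas condition-wise modeling reduces leakage to numerical zero; the
jittered design is what keeps the two periods' regressors identifiable
(mean worst-case same-condition cue/delay regressor correlation ~0.69
across 8-block sessions).  A `"shared"` option reproduces the pooled
variant.  Prewhitening is omitted — the synthetic noise is white by
default and the AR(1) option is documented as a limitation.  Condition
images are voxelwise z-scored (mean 0, sd 1 across the 18 conditions)
before group analysis; zero-variance voxels are zeroed and flagged.

## Searchlight

For each in-mask voxel, the neural RDM over all in-mask voxels within the
searchlight radius (default 9 mm; spheres at mask edges are kept when
they hold at least 10 voxels) is correlated with the model and the Fisher
z written at the center.  The study never reports its radius, so it is a
configuration value echoed into every output.  Degenerate spheres
(constant condition patterns) yield NA and are flagged, never silently
imputed.

## Group inference

Group inference follows the bootstrapped permutation scheme: per subject,
`K` searchlight maps under freshly permuted model condition labels
(default 150); `B` null group maps, each averaging one uniformly drawn
permutation map per subject (default 10,000); a per-voxel cluster-forming
threshold at the `1 - p_voxel` empirical quantile of the null; connected
components (26-connectivity by default) of the thresholded group map;
and a cluster-size familywise error correction against the per-map
maximum null cluster size, with plus-one p-values `(1 + #{null >= size})
/ (B + 1)`.  The pooled-cluster null is available behind a flag.  When
nothing survives at alpha = 0.01 the analysis can be rerun at 0.05, the
same fallback the study used for its sensory model.

Two methodological details matter for validity and are on by default:

* **Map centering.**  The GLM noise covariance between condition betas is
  the same `(X'X)^{-1}` block at every voxel, so each (permuted) model
  induces a *map-wide* offset in a subject's correlation map.  Offsets
  vary across permutations but are fixed for the observed model, which
  over-disperses the null relative to the observation: in calibration
  runs the procedure then rejects essentially never.  Centering every
  subject map (observed and permutation alike) at its spatial mean
  removes the shared offset and makes cluster inference target spatially
  specific structure.
* **Identity permutation in the bootstrap pool.**  With small `K` an
  atoms-only empirical null is anti-conservative (measured false-positive
  rate ~0.11 at `K = 30`, alpha = 0.05).  Including each subject's
  observed map in its pool — the standard guarantee that the observed
  statistic is a member of its own permutation distribution — restores
  calibration (measured rate 0.065 over 200 pure-noise cohorts); at the
  study's `K = 150` the inclusion is negligible.

## Numerical choices

Event regressors are built on a 0.1 s grid (onsets rounded to it) and
convolved via zero-padded FFTs at 2-3-5-smooth lengths; the simulator and
the GLM share this code path, which is why noiseless recovery is exact to
machine precision.  Quantiles are type-7.  Cluster connectivity accepts
6, 18 or 26.  Per-stage seeds derive from one master seed through an LCG
hash, so every run is reproducible from a single integer and nested
stages never collide.  Coordinates are reported both as 0-based voxel
indices and in mm through a centered 3 mm MNI-like affine.

## Validation study sizes

The packaged validation studies are sized for a desktop: parameter
recovery uses 6 subjects, 2-block sessions, a 24^3 grid, planted ROI
balls of radius 6 voxels at opposite grid corners, amplitude 0.5 (noise
sd 1), a 6 mm searchlight on unsmoothed data, `K = 50`, `B = 1000`,
alpha = 0.01; familywise-error calibration uses 200 pure-noise cohorts of
4 subjects on a 16^3 grid with `K = 30`, `B = 500`, p_voxel = alpha =
0.05.  The 6 mm / unsmoothed choice for these studies is geometric: any
recovered cluster is the planted ROI dilated by roughly the searchlight
radius (plus smoothing reach), and with a 9 mm light plus 4 mm kernel no
pair of disjoint ROIs fitting a 24^3 grid could reach a Dice overlap of
0.5 even under perfect detection.  Analyses of realistically sized grids
should keep the package defaults (9 mm radius, 4 mm FWHM smoothing).
`B x p_voxel >= 10` is enforced so the per-voxel tail quantile is
estimable; at `B = 500` this forbids p_voxel = 0.01, hence the
calibration study's 0.05.

## Known limitations

No prewhitening or autocorrelation-aware GLM inference; no surface-based
searchlight; no cross-validated distance estimators (the study uses plain
correlation distance); no univariate group contrasts or template-space
registration (out of scope); the HMAX stage stops at C1.  The behavioral
module computes the inverse efficiency score IES = RT/accuracy from
supplied summaries; note that a cohort-level IES computed from mean RT
and mean accuracy is not the mean of per-subject IES values.

## A worked miniature

```{r mini, eval = FALSE}
cfg <- templight_config(seed = 1, n_subjects = 4, grid = c(16, 16, 16),
                        n_blocks = 1, K = 20, B = 200, p_voxel = 0.05,
                        alpha = 0.05, roi_radius = 4, models = "dimension")
run <- templight_run(cfg)
print(run)
summary(run$fits$dimension)   # cluster table
plot(run$fits$dimension)      # axial montage of the group z map
```
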