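---
title: "ROI construction and GTM partial volume correction for tau PET: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ROI construction and GTM partial volume correction for tau PET: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taupvc)
```

## The problem

Tau PET tracers of the AV-1451 family bind off target: in the basal
ganglia and thalamus, in the superior cerebellar gray, in the posterior
choroid plexus, and in skull, meninges and soft tissue ("extra-cortical
hotspots", ECH). Because PET resolution is coarse (4–8 mm FWHM), these
nuisance sources spill into exactly the structures tau studies care
about — hippocampus, temporal cortex, and the cerebellar reference
region. Region-based partial volume correction with the Rousset
geometric transfer matrix (GTM) can undo that mixing, but only for
signal that is *inside* some modeled ROI: activity in unmodeled space is
implicitly assumed to be zero, and a hotspot left out of the model
corrupts every neighboring estimate. This package therefore does two
things:

1. builds an edited label volume in which every source of signal —
   anatomical ROIs *and* off-target structures — carries its own integer
   code, and
2. solves the GTM on that label volume and quantifies how well the ROI
   configuration explains the observed image.

## The GTM model

Let \(c_j\) be the true (piecewise-constant) activity of ROI \(j\) and
let \(h\) be the scanner point spread function, modeled as a 3D Gaussian
of given FWHM (\(\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})\)). The
observed mean over ROI \(i\) is

\[ t_i \;=\; \sum_j \omega_{ij}\, c_j, \qquad
   \omega_{ij} \;=\; \frac{1}{|R_i|}\sum_{v \in R_i} (h * \mathbf{1}_{R_j})(v), \]

so \(\omega_{ij}\) is the mean over ROI \(i\)'s voxels of the smoothed
indicator of ROI \(j\). Solving \(\omega c = t\) gives the corrected
means. Voxels with label 0 contribute no column: they are assumed
signal-free, which is the precise reason the off-target ROIs must exist.
`solve_gtm()` uses a direct solve and falls back to the SVD
pseudo-inverse when the 2-norm condition number exceeds `1e8` (tiny ROIs
adjacent to large ones can make \(\omega\) near-singular); the solver
used is recorded in the model.

The same smoothing routine implements the forward model, the mask
adjudications and the calculated pre-PVC image, so the fit diagnostic
can never be polluted by a kernel mismatch. Smoothing uses zero-padded
boundaries (out-of-field activity is assumed zero, consistent with the
GTM convention), a unit-normalized kernel truncated at 4 sigma, and
degenerates to the identity on an axis whose FWHM is below half a voxel.

## The fit diagnostic (PVCnstd)

Assigning each ROI's corrected mean to its voxels gives the PVC image;
re-smoothing it by the PSF gives the *calculated pre-PVC* image. If the
ROI configuration and PSF explained the data perfectly, this would equal
the observed SUVR. The residual (calculated pre-PVC minus observed) has
near-zero mean within each ROI, so the mean is uninformative; its
*standard deviation*, normalized by the ROI's mean observed SUVR, is the
per-ROI fit score (PVCnstd), and the global score is the unweighted mean
over the anatomical labels 1–77. Two conventions were open: population
vs sample standard deviation (population is the default, configurable)
and unweighted vs voxel-weighted global averaging (unweighted is used;
the per-ROI table is returned so any reweighting can be applied).

## Pipeline stages and their parameters

`run_subject()` executes, in order:

1. **Remap** (`remap_labels()`): FreeSurfer aparc+aseg codes map onto
   edited indices 1–76 (`default_remap_table()`), ventricles to 0
   (assumed zero activity), cerebellar gray (codes 8/47) to a reserved
   internal code. Unrecognized codes go to 0 rather than erroring, since
   real segmentations contain codes outside the scheme. A custom TSV
   table can be supplied for other FreeSurfer dialects. Note the edited
   index space and the FreeSurfer code space overlap (e.g. FreeSurfer 17
   maps to edited 3, while 17 is itself a valid edited index), so the
   remap is a one-shot transformation of raw segmentations, not an
   idempotent cleanup pass.
2. **Cerebellar split + SUVR** (`split_cerebellum()`,
   `normalize_suvr()`): SUIT lobule codes 6, 8–28, 33, 34 define the
   inferior cerebellar gray (the reference region) and 1–5, 7 the
   superior part, which gets edited index 77. Binary SUIT masks are
   smoothed (8 mm FWHM, `mask_smooth_fwhm_mm`) and every cerebellar-gray
   voxel goes to the side with the larger smoothed value, so gray voxels
   outside the atlas's coverage are still assigned. Ties (including
   both-zero) go to the superior side — the conservative choice for a
   reference denominator. The inferior reference is carried as edited
   index 78, the one unused slot below the published choroid codes. The
   PET is divided by the mean over the inferior mask; the divisor is
   recorded.
3. **Choroid split** (`split_choroid()`): seed components are choroid
   voxels at SUVR ≤ 1 (low) or > 1 (high) in clusters of ≥ 100 voxels;
   remaining choroid voxels follow whichever smoothed seed mask is
   larger. High = 79, low = 80; ties go to high (overestimating
   off-target choroid signal protects the hippocampal estimate).
   If neither side has a seed, direct thresholding is used with a
   warning. The choroid's FreeSurfer source codes default to the
   standard aseg convention {31, 63} and are configurable.
4. **Extra-cortical hotspots** (`build_searchable_roi()`,
   `detect_ech()`): the searchable region is CSF-probability voxels
   (c3 > 0.5) nearer bone than brain (smoothed-bone > smoothed-brain at
   scanner resolution) plus any voxel with c4+c5 > 0.3. Hotspots are
   connected clusters (26-connectivity) of searchable voxels with
   SUVR > 1.6 and strictly more than 500 voxels, labeled 85 upward in
   a deterministic order (descending size, then smallest bounding-box
   corner). In the pipeline the searchable region is additionally
   restricted to still-unassigned voxels so hotspot labels can never
   overwrite anatomical ROIs.
5. **CSF / bone+meninges classes** (`classify_csf_bone()`,
   `assign_stray_gray()`): remaining unassigned voxels with real signal
   become CSF low/high (81/82) or bone+meninges low/high (83/84)
   according to probability dominance (c3 vs c4+c5), a 0.3 probability
   cut, a 0.1 SUVR floor and the SUVR 1 split (strict < 1 for low,
   ≥ 1 for high, no upper bound). Stray gray voxels (c1 > 0.3, exactly
   zero c3/c4/c5, SUVR > 0.1, still unassigned) take the modal nonzero
   label of their 26-neighborhood; ties go to the smallest label. A
   single sweep can strand interior strays, so the sweep iterates to
   convergence (at most `stray_max_passes`, default 10); set
   `max_passes = 1` for a strict single application.
6. **Reference hotspot scan** (`scan_reference_hotspots()`): last, the
   inferior cerebellar gray is searched for clusters of SUVR > 1.6 with
   strictly more than 500 voxels. Each is removed from the reference and
   labeled counting up after the highest hotspot label, and the SUVR is
   renormalized to the cleaned reference mean. The scan runs after all
   threshold-based stages and does not retroactively re-evaluate them —
   the stages are sequential by design, which mirrors how contaminated
   references actually propagate: an inflated denominator deflates every
   earlier SUVR threshold decision, and only the final renormalization
   repairs the scale.

The ten `roi_config()` presets toggle stages 3–6 (whole vs split
choroid; hotspots at threshold 1.6, 1.3 or 1.9; tissue classes merged or
split; reference scan on/off). Configuration 1's whole-choroid ROI uses
an internal label (200) outside the published range so that all ten
configurations share one label space. Configurations 9 and 10 inherit
the reference scan from configuration 8.

## The phantom

`generate_phantom()` builds a fully synthetic subject with known ground
truth: nested ellipsoids for cortical gray (four bilateral regions) and
white matter, hippocampi beside a two-slab choroid plexus (ventral slab
high-binding, dorsal low, separated by two voxel layers so smoothing
cannot carry one mode into the other's seed), ventricles, a brainstem
bridge, a spherical cerebellum whose gray shell carries SUIT-style
superior/inferior lobule codes (the atlas is deliberately eroded so a
ring of gray falls outside it and must be adjudicated), a CSF gap and
skull shell with superior/inferior activity contrast, a ~1400-voxel
hotspot sphere against the parieto-occipital skull, a small
stray-gray pocket, and optionally a 1200-voxel hotspot inside the
reference region (off by default — such lesions are rare). The PET
volume is exactly the PSF-smoothed piecewise-constant truth plus
optional seeded Gaussian noise.

Default conditions: 64^3 grid at 2 mm, 6 mm PSF FWHM, noiseless. The
feature activities (cortex 1.2–1.6, hippocampus 1.3, white matter 0.9,
superior cerebellar gray 1.3, choroid 1.8/0.7, CSF 0.4, skull 1.3/0.5,
hotspot 2.2, all in reference units) sit well clear of the decision
thresholds so that the designed partitions are recoverable, while the
hotspot and reference-lesion sizes are chosen so their supra-threshold
cores *after* smoothing still clear the 500-voxel cluster cut — a
smaller or cooler lesion is genuinely undetectable under the published
criteria, which is a property of the criteria, not of this
implementation.

What the phantom does not emulate: anatomical shape detail, Poisson-like
PET noise (the noise is additive Gaussian on the smoothed image),
scanner effects (attenuation, scatter, motion), segmentation error
beyond the designed stray pocket, and registration error. Passing tests
therefore demonstrate correctness of the algorithms under their own
forward model, not robustness to real-data nuisances.

`recovery_experiment()` fixes the ROI model from a noiseless run, then
repeats the noise `n_reps` times, renormalizing and re-solving each
time. Estimates are compared in activity units (corrected mean times the
recorded reference mean) — in those units the estimator is linear in the
noise, hence exactly unbiased — against the noiseless-run estimand. The
geometric truth is also reported where a label corresponds to a single
truth region; it is NA for the classification-derived tissue ROIs, whose
estimand legitimately differs from any single geometric compartment.

## Numerical choices and degenerate inputs

- Connectivity is 26 (the usual 3D default) everywhere, configurable to
  6 or 18; one shared constant covers hotspots, choroid seeds and the
  reference scan.
- Cluster cuts follow the published wording exactly: strictly **>** 500
  voxels for hotspots and reference lesions, **≥** 100 for choroid
  seeds.
- Probability cuts are strict (>) uniformly; "zero probability" in the
  stray-gray rule means below 1e-9, to tolerate float-stored maps.
- Affine agreement between inputs is required to 1e-4 per element; no
  resampling is attempted.
- Label volumes are written as int16 (int32 above 32767); a write/read
  round trip is bit-exact for labels.
- An empty reference after hotspot removal, an empty choroid mask, a
  non-positive reference mean, and a GTM with no modelable labels are
  errors; requested-but-absent ROI labels (e.g. no hotspot in a subject)
  are dropped with a warning.

## Problem sizes used in the tests

The suite validates against brute-force oracles (dense convolution,
breadth-first flood fill, SVD least squares) on grids up to 32^3 and
systems up to 10x10, runs the full pipeline and the ten-configuration
sweep on the 64^3 phantom, and the Monte-Carlo recovery on 100 seeded
noise repetitions — sizes at which every property is exercised while the
whole suite stays in the minutes range on one CPU.

## Known limitations

- World-space resampling, registration and segmentation are upstream:
  all inputs must already share one voxel grid.
- Voxel-wise PVC methods (Müller-Gärtner, iterative Yang, RBV) are out
  of scope; so is PSF estimation from data and noise-propagation
  covariance of the GTM estimates.
- The Braak composite mean is voxel-count-weighted by default (a
  composite is a union of voxels); an unweighted mean of ROI means is
  available since the convention is not universal.
- Whether the "Other" ROI (edited 76) should be excluded from reporting
  is a matter of taste; it participates in the GTM here, and the QC
  label set is an argument.
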