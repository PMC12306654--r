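---
title: "CT-like bone MRI: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CT-like bone MRI: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bonemri)
```

`bonemri` studies a simple question quantitatively: when a multi-echo MRI
acquisition of spinal bone is post-processed into a CT-like image — echoes
averaged, intensities inverted — how much do the acquisition sequence and the
processing choice matter for bone conspicuity, and how reliably can a
fracture gap be measured on the result? Because clinical multi-echo spine
data are rarely shareable, the package pairs the analysis with a digital
phantom so that every number it produces is recomputable from code.

## Signal model

Each tissue is described by a relative proton density $\rho \ge 0$ and an
effective transverse relaxation time $T_2^*$ (ms). The noise-free magnitude
signal at echo time $TE$ is mono-exponential,

$$ SI(TE) = \rho \, e^{-TE/T_2^*}. $$

Repetition time and flip angle are deliberately outside the model: they are
carried as sequence metadata only, because none of the downstream
measurements use them. Acquisition noise is complex Gaussian with
per-channel standard deviation $\sigma$, applied before the magnitude
operation, so voxel intensities are Rician distributed and pure-noise (air)
regions are Rayleigh with mean $\sigma\sqrt{\pi/2}$ and SD
$\sigma\sqrt{2-\pi/2}$ — the standard magnitude-MRI noise model, and the one
that makes "noise SD measured in air" a well-defined quantity. A
Gaussian-only mode exists for analytic diagnostics; it can produce negative
intensities and is never used by the pipeline.

Default tissue values are literature-typical 3-T numbers chosen to produce
the qualitative contrast that motivates bone-oriented imaging — cortical
bone ($\rho = 0.25$, $T_2^* = 0.4$ ms) is faintly visible at $TE = 0.1$ ms
and a void by $TE = 4$ ms, while muscle ($1.0$, $28$ ms) and marrow ($1.1$,
$45$ ms) decay slowly. The default sequences are 3-echo UTE-like
($TE = 0.1, 2.7, 5.3$ ms) and FE-like ($TE = 4, 8.6, 13.2$ ms) protocols at
1 mm slices.

## The phantom

The geometry is a deliberately minimal slab-and-plate model: a muscle slab
surrounded by air, a cortical-bone plate running along the slice axis (the
pars-like structure), and a marrow box alongside. The analysis consumes
intensities and masks, not anatomy, so the phantom's job is to provide every
structure the measurements need — bone with a measurable cross-section,
adjacent muscle, background air, and an optional fracture gap — at a size
where a full study simulates in seconds. The default grid is
$64 \times 64 \times 32$ voxels at 1 mm isotropic; geometry scales
proportionally for other grids and construction is purely deterministic.

A pars defect is emulated by relabelling bone as muscle over a contiguous
run of voxel columns along the plate. The run covers the
$\mathrm{round}(w / \mathrm{voxel})$ columns nearest the requested centre
(start index $\lceil c - n/2 \rceil$), so the realized gap is the requested
width rounded to whole voxels and the rounding convention is explicit: a
2.5 mm gap on a 1 mm grid is 2 columns. This nearest-columns rule, rather
than a "within $w/2$ of the centre" test, keeps the realized width equal to
the rounded width at every centre parity.

What the phantom does *not* emulate: anatomical vertebrae, multiple levels,
bone-marrow edema, partial-volume anatomy at oblique interfaces, the radial
k-space readout of a real UTE sequence, $B_0/B_1$ inhomogeneity, fat–water
chemical shift, motion, or coil-sensitivity structure. Subject-to-subject
variability is a ±5% uniform multiplicative jitter on tissue proton
densities plus independent noise realizations — enough to give the factorial
analysis a realistic between-subject variance, with no claim of biological
realism. Passing tests therefore demonstrate correctness of the
*measurement machinery* under a controlled signal model, not performance on
clinical images.

## CT-like processing

Two processing routes produce a CT-like image from an echo series:

- **first-echo**: invert the earliest-TE volume, $1 / SI_1$;
- **multi-echo**: average all echoes voxelwise with equal weights, then
  invert, $n / \sum_i SI_i$.

The reciprocal is taken as $1/\max(SI, \varepsilon)$ with
$\varepsilon = 10^{-3}$ times the series' 99th-percentile intensity, so the
cap on signal voids ($1/\varepsilon$) is scale-covariant. Whether a scanner
console rescales or clips before inverting is generally unknowable from the
outside; the literal reciprocal with a clamp is this package's reading, and
a linear inversion ($\max SI - SI$), common in the bone-MRI literature, is
provided behind `inversion = "linear"` to expose the ambiguity rather than
hide it. Averaging uses extended-precision accumulation, which has a
convenient testable consequence: a series whose echoes are identical
processes bit-identically through both routes.

The mechanism that makes multi-echo processing pay off is in the noise, not
the signal: averaging $n$ echoes shrinks the air-noise SD roughly by
$\sqrt{n}$ *before* the reciprocal amplifies near-zero voxels, and it
drastically thins the near-zero tail of the air distribution that the
reciprocal blows up. Both effects lower the denominator of SNR/CNR on the
processed image, which is exactly what the 20-phantom benefit check in the
acceptance suite measures.

## Measurement conventions

Several conventions had to be fixed where common practice varies; they are
all encoded in one place each and tested:

- **ROIs** are the tissue labels on a chosen slice eroded by one voxel
  (3×3 box, via EBImage), so partial-volume boundary voxels never enter the
  statistics; each mask must keep ≥ 25 voxels so means and SDs are stable.
  Mask placement depends on geometry only, never on tissue parameters.
- **SD** is the sample SD with $n-1$ denominator throughout. A single-voxel
  ROI reports SD 0 with a warning instead of failing.
- **SNR/CNR** are computed on the processed CT-like image with the noise ROI
  drawn on that same image, mirroring how such measurements are made in
  practice. Because the air ROI of a reciprocal-inverted image sits near the
  $1/\varepsilon$ cap and inherits the heavy $1/x$ tail, processed-image
  SNRs live on an O(1) scale here; clinical reports of SNR in the tens
  reflect console-specific rescaling that this package deliberately does not
  model. On the *source* magnitude images the default
  $\sigma = 0.03$ puts muscle SNR near 50 — the familiar regime. For the
  sequence-contrast question (is bone better seen on UTE than FE under
  matched noise?) the package's convention is to compare bone SNR on the
  first-echo source images, where the effect genuinely lives in this model:
  any order-reversing inversion would rank the deeper FE bone void *above*
  the partially visible UTE bone on the processed images, so a
  processed-image comparison under matched noise answers a different
  question (void depth, not bone visibility).
- **CNR** is reported signed, bone minus muscle, and equals
  $SNR_{bone} - SNR_{muscle}$ identically because the denominators are
  shared. SNR and CNR are invariant under global positive scaling of the
  image and *not* invariant under additive offsets; both properties are
  tested.
- **Slice CoV** is $100 \times$ SD/mean of the per-slice bone-ROI means over
  $k \ge 2$ consecutive slices; the default pipeline uses the 5 slices at
  the start of the plate, clear of a centred defect.
- **FWHM**: profiles are sampled by trilinear interpolation at evenly spaced
  points in physical mm (voxel centre of the first voxel at 0 on each axis).
  The baseline is the mean of the outer 10% of samples at each end, the
  half-height is baseline + (extremum − baseline)/2, and crossings are
  linearly interpolated between samples. Both bright-feature ("peak") and
  dark-feature ("dip") orientations are supported; on reciprocal-inverted
  images a defect is a dip in the bright bone plate, which is the pipeline
  default. An extremum at a profile end or a missing crossing yields
  `fwhm = NA`, never an error, so batch runs degrade gracefully.

## The factorial analysis

The study design is sequence (UTE vs FE) × processing (first vs multi-echo)
with each simulated subject contributing all four cells. `two_way_anova()`
implements the balanced fixed-effects decomposition directly from cell,
marginal and grand means — under balance the Type I/II/III distinction
vanishes, so the implementation refuses unbalanced tables rather than
silently picking a convention. F tail probabilities come from `stats::pf`.
Subjects are treated as independent replicates per cell, mirroring how such
small feasibility analyses are usually run; the repeated-measures structure
that treatment ignores is a known simplification, not an oversight. The
test suite checks the decomposition against an independent least-squares
cell-means fit (`stats::lm`/`stats::anova`) to $10^{-8}$ relative on random
tables, and its empirical type-I error at $r = 4$ over 10,000 null
simulations.

When every subject is identical (zero within-cell variance) the summary
table is still produced but the F tests are reported as `NA` with a
warning — the report structure should not collapse because a degenerate
fixture was fed in.

## Problem sizes and runtime

The defaults were chosen so a complete study is interactive: a 4-subject,
2-sequence, 2-processing run on the $64^3$-scale phantom takes about two
seconds, the full test suite under a minute, and the acceptance script about
half a minute, including the 20-phantom benefit checks and the
10,000-replicate ANOVA calibration. Monte-Carlo tolerances follow from these
sizes (e.g. Rayleigh moments to 2% at $\ge 10^4$ air voxels; type-I error
within 3 binomial SDs of 0.05 at $10^4$ replicates).

## Known limitations

- The phantom's geometric simplicity means partial-volume effects exist only
  at axis-aligned interfaces; FWHM behaviour on oblique or curved fracture
  planes is untested.
- The reciprocal inversion's air behaviour makes processed-image SNR
  sensitive to the epsilon convention; comparisons should always hold the
  inversion settings fixed, as `run_pipeline()` does.
- Between-subject variability is a modelling convenience (density jitter),
  so the ANOVA's between-subject variance is not calibrated to any
  population.
- DICOM input, sagittal reformatting of axial acquisitions, and any
  learning-based pseudo-CT synthesis are out of scope; NIfTI (one file per
  echo, JSON sidecar for echo times) is the interchange format.
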