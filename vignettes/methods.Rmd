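---
title: "Quantifying early-endosome dynamics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying early-endosome dynamics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoquant)
```

## The problem

During receptor-mediated endocytosis of EGF/EGFR, internalized cargo
vesicles meet a pre-existing population of EEA1-positive early endosomes.
Confocal imaging of fixed cells stained for EEA1 (green) and EGFR (red)
turns this biology into a counting problem: how many EEA1 vesicles does a
cell carry, how bright are they, and what fraction of cargo vesicles touch
EEA1 structures at each time after stimulation? `endoquant` implements that
quantification pipeline — segmentation, per-vesicle measurement,
object-based colocalization, and the nonparametric statistics around them —
together with a synthetic scene generator that provides geometric ground
truth, so every stage can be validated end to end without microscope data.

## Segmentation model

Vesicles are compact, bright, roughly disk-shaped objects over a smooth
background. The pipeline per channel is:

1. **Median-filter subtraction.** The image is median-filtered with a disk
   footprint (radius 6 px for the green channel, 10 px for the red channel
   by default — the radii used in the original protocol, overridable per
   channel) and the filtered image is subtracted from the original. The
   local median tracks background and the interior of structures larger
   than the window, so the difference image sharpens the intensity step at
   vesicle edges. The practical payoff is resistance to blur-induced area
   inflation: when the PSF smears a disk into a halo, direct thresholding
   of the raw image includes the halo in the footprint, whereas
   thresholding the subtracted image does not (quantified in
   `analysis/05_subtraction_rationale.R` and the acceptance suite).
   Negative differences are clamped to 0 by default, matching 8-bit image
   arithmetic. Edges are handled by reflection.

2. **Threshold selection.** The published procedure chooses "the threshold
   providing maximal correspondence between the original and binarized
   image" without defining correspondence numerically; whether it was
   scored by eye or by a statistic is unknowable from the text. We
   operationalize it deterministically: every integer threshold between
   the enhanced image's minimum and maximum is scanned, and the one
   maximizing the Pearson correlation between the resulting binary mask
   and the original image's intensities is chosen, ties broken toward the
   smaller threshold. This is parameter-free, reproduces the separable
   (two-valued) case exactly, and is verified in the tests against a
   literal exhaustive-scan oracle. Otsu and fixed thresholds are available
   as alternative modes, and the threshold actually used is recorded in
   every result object. A flat image has no separating threshold; the
   pipeline maps that degenerate case to an empty mask (zero vesicles).

3. **Binarization and particle filtering.** Binarization is strict
   (`pixel > threshold`). Foreground components are labelled with
   8-connectivity — the contiguity rule of ImageJ's Analyze Particles —
   and a component is retained only when its calibrated area
   `pixel_count * pixel_size_nm^2` is *strictly greater than* 20 000 nm².
   At the default 100 nm/px calibration this discards 2-pixel components
   (exactly 20 000 nm²) and keeps 3-pixel ones, so the boundary semantics
   are pinned down by tests. Both the connectivity and the strictness are
   deliberate readings of "particles larger than 20 000 nm²".

4. **Measurement on the original image.** Object footprints are defined on
   the enhanced image but all intensity measurements (integral density =
   sum of pixel values over the footprint) are made on the original,
   unenhanced image, as in the published workflow. Centroids and areas are
   reported in nm.

Pixel calibration is a required input: the area cutoff lives in physical
units, and the source micrographs' pixel size is not recoverable from the
protocol (only the objective and frame size are stated). Synthetic work
uses 100 nm/px.

## Projections, slices and colocalization

Counting and density measurements use the 8-bit maximum-intensity
projection of the z-stack (z-step 500 nm by default). The conversion mode
to 8 bits is itself ambiguous in typical protocols, so both options exist:
`rescale_minmax` (the default; affine map of the observed range onto
0–255, matching common confocal export) and `clip`; the mode is recorded in
each image's provenance.

Object-based colocalization is evaluated on a *single optical slice*
representing the base plane of the cell. As a reproducible proxy for "the
plane where the majority of endosomes are located", the slice with the
greatest summed intensity across the analysis channels is selected
(override with an explicit z). A source object colocalizes when at least
one of its pixels falls on the target channel's binarized mask — partial
overlap counts, with no minimum-fraction requirement. The percentage is
reported under an explicit normalization, because the two plausible
readings of "percentage of overlapping objects from the total number of
objects" differ: `by_source` divides by the source-channel object count,
`by_target` by the target-channel count. Both are computed for both
directions; consumers must choose explicitly, and the tables record the
choice.

## Statistics

* **Mann–Whitney U** (`mann_whitney_u()`): exact null distribution when
  the combined sample size is ≤ 12 and there are no ties, tie-corrected
  normal approximation otherwise, with the branch recorded. Timecourse
  comparisons of per-cell quantities (15–20 cells per condition) land in
  the approximate branch, as is standard at those sizes. The exact branch
  is verified against full rank-assignment enumeration for every split of
  up to 4+4 values.
* **One-sample sign test** (`sign_test()`): exact two-sided binomial test
  on the signs relative to the null value; exact ties are dropped (classic
  convention) and counted. With n = 3 replicates the smallest attainable
  p is 0.25 — worth keeping in mind when reading small-replicate
  densitometry: three timepoints under Holm can never fall below 0.75, so
  non-significance there is structural, not merely observed.
* **Bonferroni–Holm** (`holm_adjust()`): the standard step-down
  adjustment, verified against a literal implementation of the formula.
* **Densitometry fold changes** (`densitometry_foldchange()`): band
  density normalized by the loading-control (Ponceau) density per lane,
  then divided by the same replicate's control lane, so each biological
  replicate is its own reference.

Significance is marked at alpha = 0.05 (configurable) after Holm
adjustment within each family of timepoint comparisons.

## The synthetic-scene generator

`generate_scene()` renders what the pipeline is meant to measure, with
known truth:

* a 256 × 256 px field at 100 nm/px (a 25.6 µm crop holding one cell) with
  5 optical slices;
* 150 green vesicles by default — the baseline EEA1 population of a
  serum-starved cell — as disks with radii uniform in 200–500 nm, placed
  juxtanuclearly (isotropic Gaussian, spread 8 µm, around a nucleus-edge
  point) or scattered, as after microtubule disruption;
* red cargo vesicles, free or attached to green structures as **hybrid
  endosomes**: two offset disks, one per channel, whose centres sit at
  0.8 × (r₁ + r₂), so the domains always overlap partially but never
  coincide — the two-domain organization seen on real hybrid structures;
* Gaussian PSF (sigma 100 nm by default), additive background (10),
  Poisson shot noise and Gaussian read noise (sd 2), giving a
  signal-to-noise ratio in the 10–15 range at the default amplitudes
  (120–200);
* placement by rejection sampling (1000 retries) keeping an edge-to-edge
  clearance of 600 nm between distinct structures, so ground-truth counts
  and overlaps are exact functions of the layout.

All vesicles sit in the middle ("base-plane") slice by default, matching
the single-slice colocalization protocol; a uniform-z mode exists. Per-
object amplitudes are free parameters, not claims about real staining:
the source protocol reports no per-cell intensity statistics, so intensity
checks are internal-consistency checks only. Ground-truth overlap
fractions are audited in the tests by brute-force rasterization at 25 nm
resolution.

Timecourses (`timecourse_scenario()` / `generate_timecourse()`) fix the
total number of red objects and make `round(target × n_red)` of them
hybrid-attached per timepoint, so the geometric truth hits each target up
to integer rounding; a per-timepoint red amplitude multiplier emulates
progressive cargo concentration. The default validation scenario uses
targets 10/50/70/40/10% — low baseline contact, a mid-course maximum near
the ~70% plateau characteristic of peak fusion, then segregation.

What the generator does **not** emulate: realistic 3-D PSFs, spectral
bleed-through, photobleaching, vesicle motion, cell-to-cell size
variation, or autofluorescence texture. Passing the recovery tests
therefore shows the *pipeline's* correctness on disk-like objects under
shot noise and modest blur; it does not certify performance on any
particular microscope's data.

## Problem sizes and numerical choices

The validation analyses use 15 cells for count recovery, one cell per
timepoint for the 5-point colocalization course, and 20 scenes for the
blur-rationale comparison; these sizes put Monte Carlo noise comfortably
below the decision margins being tested (the rationale comparison, for
instance, has a per-scene win rate near 95%, so 20 scenes make a sub-80%
reading very unlikely). All randomness flows from one root seed; scene
seeds are derived deterministically from it and recorded in simulation
manifests, and library code saves and restores the caller's RNG state.
Quartiles use linear interpolation between order statistics
(`quantile()` type 7), recorded so that boxplot figures regenerate
identically. One stack is treated as one cell: cells are assumed
hand-selected at acquisition, and no cell-boundary detection is attempted.

## Known limitations

* Touching vesicles are not split (no watershed); the generator avoids
  same-channel contact, so merging appears in real data before it appears
  in these tests. Very large vesicles (diameter approaching the median
  window) can occasionally fragment after subtraction — with the default
  radii this affects roughly 2% of simulated cells' counts by one object.
* Segmentation is 2-D (projection or single slice); there is no 3-D
  linking across z.
* The correspondence threshold is a declared stand-in for an ambiguous
  published criterion; Otsu and fixed modes exist precisely so the choice
  is visible and revisable.
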