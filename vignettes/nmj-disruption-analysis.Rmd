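---
title: "Quantifying neuromuscular junction disruption: models and methods"
author: "nmjcoloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neuromuscular junction disruption: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmjcoloc)
```

## The measurement problem

Neuromuscular junctions (NMJs) are organized so that the postsynaptic
acetylcholine receptor (AChR), the basal-lamina components
acetylcholinesterase (AChE) and laminin β2, and the presynaptic vesicle
marker SV2 are tightly apposed. Disease and immaturity loosen this
apposition. This package quantifies that loosening from triple-stained
fluorescence micrographs: each NMJ field is imaged in one grayscale
channel per stain (a 12-bit monochrome camera is the reference setup),
each channel is thresholded objectively, and non-colocalization is scored
on the resulting binary masks.

## Objective thresholding

For each channel, the gray-level histogram (one bin per integer level, no
smoothing) is split at the level `t` minimizing a split-variance
objective, scanning every level present. Background pixels fall at or
below `t`; positive pixels lie strictly above it.

Two objectives are provided behind `computeThreshold(method = )`:

* `"weighted"` (default) — the within-class variance weighted by class
  pixel counts, i.e. the Otsu criterion. This is the default because the
  standard thresholding algorithms shipped with commercial microscopy
  packages are Otsu-family methods.
* `"unweighted"` — the plain sum of the two class variances, the literal
  reading of "the summed variance of the distributions on each side of
  the split".

Ties in the objective break toward the lower level, and a constant image
is an error ("no split exists") rather than an arbitrary answer.
Thresholds are computed per channel per NMJ crop, not per slide, matching
a per-NMJ imaging workflow; channels are assumed registered, and no
flat-field correction or deconvolution is attempted.

## Directional non-colocalization scores

For an ordered stain pair (A, B) with positive-pixel sets from the two
masks, the appositional score is

> score(A, B) = |A \\ B| / |A|,

the proportion of pattern A lying outside pattern B: 0 is complete
overlap, 1 is no overlap. Codes follow the field's three-letter
convention — first letter the measured stain, `O` for "outside of", last
letter the reference (R = AChR, E = AChE, L = laminin β2, V = SV2), so
`EOL` is AChE-outside-laminin-β2. Each triple-stained NMJ yields six
directional scores (both directions of its three pairs). An NMJ whose
numerator mask is empty is excluded for that code — the ratio is
undefined — rather than scored 0 or 1. Pixels positive in neither mask
never enter any count, so the score is independent of crop padding, and
it is invariant under joint translation of both masks.

## Nested cohort statistics

The data are hierarchical: two diagnosis groups (spastic cerebral palsy,
CP, and idiopathic scoliosis, IS, as scoliotic controls), many patients
per group, many NMJs per patient. Three comparisons respect that nesting:

1. **Pooled** (`pooledComparison`): all NMJ-level scores per group,
   compared per code by two-sided Mann-Whitney test.
2. **Per-patient** (`perPatientComparison`): each eligible patient
   contributes one median score per code; group medians are compared by
   Mann-Whitney. Eligibility requires at least 15 distinct NMJs per code
   (`minNmjs`, default 15); ineligible patients keep their NMJs in
   comparison 1 but drop out of comparisons 2–3.
3. **Patient-versus-pool** (`patientVsPool`): each eligible CP patient's
   NMJ scores are tested against the pooled eligible-control scores.
   Bonferroni control divides the family α by the number of CP patients
   tested — 0.05/25 = 0.002 — *not* by patients × codes; that is the
   published design, which treats each code's 25 patient tests as the
   family. Flag direction (`higher`/`lower`) comes from the sign of the
   median difference, not from one-sided tests.

`mannWhitney` wraps `stats::wilcox.test` with a fixed policy: exact
enumeration whenever `n_x · n_y ≤ 400` and the pooled sample is tie-free,
otherwise the tie-corrected normal approximation with continuity
correction. The 400 cutoff keeps exact enumeration for all per-patient
comparisons while the pooled thousands-of-NMJs comparisons use the
approximation, where it is accurate.

`logisticPredictor` fits, per code, a univariate logistic regression of
diagnosis (CP = 1) on eligible-patient median scores and reports the
Wald p. A univariate design was chosen as the minimal model answering
"which measures are predictive"; with ~25 patients per group a
ten-predictor multivariable fit would be poorly determined. Complete
separation is reported as non-converged (detected by IRLS warnings or a
near-zero deviance) instead of returning a meaningless huge coefficient.

## TEM morphometry

Digitized traces of nerve-muscle contact regions (five per NMJ, each
defined by a distinct synaptic gutter) yield three measures:

* **Fold length** — cumulative arc length of each traced fold path from
  its cleft-attached origin to its tip. Arc length (not straight-line
  penetration depth) is used because it is the only definition consistent
  with tortuous folds.
* **Inter-fold spacing** — arc-length distance along the cleft polyline
  between successive fold-opening points.
* **Mitochondrial area fraction** — summed shoelace area of mitochondrion
  polygons clipped to the nerve-terminal polygon, divided by the terminal
  area. Clipping (Sutherland–Hodgman) is exact for convex terminal
  outlines; non-convex outlines fall back to a fine-grid rasterization
  estimate (400² cells over the polygon's bounding box, accurate to well
  under 1% for realistic shapes).

All measures are invariant to rigid motion of the trace coordinates;
scaling coordinates by k scales lengths by k and leaves the area fraction
unchanged. Coordinates are stored in micrometres so outputs compare
directly with published group values. `interraterReliability` computes
the two-way single-measure absolute-agreement intraclass correlation
(ICC(A,1), via the ANOVA decomposition) together with Pearson's r;
absolute agreement is used because a systematic offset between raters
should reduce reliability.

## qPCR relative quantification

`pfafflRatio` implements efficiency-corrected relative quantification:
`E_target^ΔCq_target / E_ref^ΔCq_ref`, with ΔCq = Cq(calibrator) −
Cq(sample). `tsRatio` averages replicate wells arithmetically on the Cq
scale (the convention of the telomere qPCR literature) before forming
ratios; with the telomere amplicon over a single-copy gene this is the
T/S ratio, and the same operation with a housekeeping reference (GUSB)
and a fetal calibrator gives expression fold differences. Efficiencies
default to 2.0 (perfect doubling) when a plate does not supply them,
since no instrument-specific calibration is assumed; the valid range is
(1, 2.2]. The calibrator's own ratio is exactly 1 by construction. The
pure efficiency-corrected form is implemented; standard-curve variants of
the telomere assay are not.

## The synthetic-data generators

No imaging data are distributed with the package, so every stage is
exercised on simulated inputs with exact ground truth. The built-in
profiles `"is-default"` and `"cp-default"` carry the published group
conditions: the per-patient median score of every comparison code (e.g.
EOL 0.06 for IS, 0.10 for CP), TEM group means (inter-fold spacing
0.392/0.655 µm, fold length 1.012/1.536 µm, mitochondrial fraction
23.8%/7.8%) with sd back-computed from the printed SEM × √25, and the
published per-subject T/S ratios.

**Images.** Each NMJ's AChR mask is a pretzel-like union of random discs.
With three masks per NMJ only four of the six directional fractions can
be fixed independently, so construction is chained: the third-stain mask
(laminin β2 or SV2) is built against AChR to hit its two drawn fractions
by exact pixel reassignment (a directionally coherent subset of the
reference plus nearest-ring pixels outside it), and the AChE mask is
built against the third-stain mask the same way; the two AChR–AChE
fractions are emergent. The manifest records the exact set-arithmetic
fraction of all six codes, so ground truth is exact by construction for
every code. Patient-level fractions are drawn logit-normal around the
profile medians (sd 0.35 on the logit scale — chosen so the central 95%
of patient medians spans about half the published ranges, which include
extremes and within-patient noise); NMJ-level jitter is normal with sd
0.05 on the fraction scale (the within-patient dispersion is unreported,
so this is a fixed package choice). Channels are rendered with Gaussian
foreground (mean 2500, sd 300) over background (mean 300, sd 80) at
12-bit depth — separation comparable to a well-exposed stain — and
clipped to [0, 4095]. Generation uses per-patient substreams derived from
the master seed, so a patient's data are independent of cohort size.

**TEM traces.** Spacings and fold lengths are drawn truncated-normal
(positive) at the contact-region level with the group sd; the
mitochondrial fraction is drawn from a beta distribution matched to the
group mean and sd, because a zero-truncated normal at mean 7.8% with sd
9 points would inflate the mean by about 3 points, while the beta is
mean-unbiased on [0, 1]. Mitochondria are placed as non-overlapping
squares (or one rectangle) inside a rectangular, convex terminal, so the
measured fraction equals the draw to float precision. Because values are
drawn at region level, the between-NMJ variance of per-NMJ means is
smaller than the published between-NMJ SEM implies — the generator has no
NMJ-level random effect — which the recovery checks should be read
against.

**qPCR plates.** Triplicate wells per (sample, amplicon); the telomere Cq
is offset by −log_E(true T/S) from a base cycle, with per-well Gaussian
Cq noise (sd 0.1). With that noise and triplicates the per-sample ratio
recovers truth with a multiplicative error of roughly 8% sd, so recovery
is validated on the mean absolute error rather than per-sample maxima.

**What passing these tests shows — and does not.** The simulations
validate the estimators (thresholding recovers the designed masks,
scores recover designed fractions, morphometry recovers designed
geometry) under idealized conditions: registered channels, stationary
Gaussian noise, no optics (no point-spread function, no bleed-through,
no autofluorescence), straight clefts, convex terminals. They do not
certify performance on real micrographs, where segmentation and staining
variability dominate; the published patient-level results (real-biopsy
medians, the logistic p = 0.021, the Spearman correlations) are not
reproducible without the original images and are not asserted anywhere.

## Problem sizes and numerical choices

The shipped validation runs use 25 patients × 20 NMJs at 96×96 px for
imaging recovery and 25 NMJs × 5 regions for TEM recovery — the published
cohort sizes at a field of view that keeps a full run in seconds.
Fraction draws are clamped to [0, 0.95]; degenerate target fractions (0
or 1) bypass the logit draw and stay exact. Tiny negative variances from
floating-point cancellation in the threshold scan are clamped to zero.
Mask construction that cannot realize a drawn fraction (footprint too
large for the field) resamples, up to ten attempts. Polygon areas use the
shoelace formula with absolute value, so vertex orientation is free.

## Known limitations

* No NMJ detection: crops are inputs. No registration or illumination
  correction.
* The unweighted threshold objective is provided for comparison but has
  no tie to a published instrument.
* Exact clipping requires convex terminal outlines; concave outlines use
  the rasterization fallback.
* The patient-versus-pool family-wise error guarantee applies per code
  family (the Bonferroni divisor is the number of patients, as
  published); across all ten codes jointly the procedure is more
  permissive.
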