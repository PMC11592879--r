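---
title: "Multimodal lateralization of the temporal-lobe epilepsy focus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal lateralization of the temporal-lobe epilepsy focus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlefocus)
```

## The problem

In temporal lobe epilepsy (TLE), deciding whether the epileptogenic focus
lies in the left or right hemisphere drives diagnosis, treatment and
surgery planning. No single modality answers reliably: scalp EEG can be
ambiguous, and hippocampal sclerosis may be too subtle for visual MRI
reading ("MRI-negative" patients). `tlefocus` implements a three-analysis
pipeline that correlates the modalities and fuses their verdicts:

* **Analysis-1 — hippocampal morphometry.** On T2-weighted coronal slices
  with expert-drawn hippocampus masks, volumes and pixel statistics of
  the left and right hippocampus are measured and a linear discriminant
  classifies LEFT vs RIGHT TLE. Sclerosis shrinks the hippocampus and
  raises its T2 signal, so the volume pair is the discriminative feature.
* **Analysis-2 — simplified voxel-based morphometry (VBM).** The
  patient's gray-matter (GM) probability map is compared voxelwise
  against a control cohort; significant GM reduction inside the
  temporal/limbic region of either hemisphere marks the focus side, and
  no surviving cluster marks the patient MRI-negative.
* **Analysis-3 — ictal EEG energy asymmetry.** During a seizure, signal
  energy rises on the focus side. For each of the eight symmetric
  bipolar channel pairs of the 10–20 longitudinal montage the asymmetry
  score

  $$A = \frac{\sum_n x_\mathrm{left}(n)^2}{\sum_n x_\mathrm{right}(n)^2}$$

  is computed over the annotated ictal epoch; $A > 1$ labels the pair
  $+1$, otherwise $-1$; a positive label sum votes the recording LEFT,
  otherwise RIGHT; recordings vote per patient by strict-LEFT majority.

**Fusion.** Each analysis yields a label encoded LEFT $=+1$,
RIGHT $=-1$, missing/MRI-negative $=0$. The final side is LEFT when the
three-label sum is positive and RIGHT otherwise — so a lone lateralized
analysis decides an otherwise-silent patient, and a 1–1 split with one
abstention falls to RIGHT by the documented tie-break.

The package encodes LEFT as $+1$ deliberately: with this orientation the
"positive sum means left" rule reproduces every row of the packaged
15-patient worked example (`read_label_table()`), including both
zero-sum patients. The tie-to-RIGHT branch is not arbitrary either: it is
verified against the two worked-example rows whose labels sum to zero.

## The worked example

The packaged table carries, for 15 patients, the expert's EEG and MRI
findings and the three analysis decisions. Re-running fusion and the
overlap evaluation reproduces the published agreement figures:

```{r fixture}
tab <- read_label_table()
ft <- fuse_table(tab)
all(ft$fused == ft$final)
reproduce_overlap_table(tab)
```

Eligibility in these ratios follows the evaluation's own rules: a
missing or negative label removes a patient from the denominator, while
a *bilateral* expert MRI finding stays in the denominator but can never
match a side — both conventions are required to reproduce the printed
3/6 and 3/5 fractions. One published comparison (expert MRI vs
Analysis-2, printed as 50% with no fraction) is not reproducible under
any stated matching rule; the package computes and reports it
(`analysis2_vs_expert_mri`) but makes no claim that it matches.

## Statistical core of each analysis

### Morphometry (Analysis-1)

Per slice, `Area = (foreground pixels) × (pixel area)`; the volume is
`sum(Area_i) × slice thickness`. Masked intensity statistics use the
mean and the $N-1$-denominator standard deviation, averaged across
slices with equal slice weights (not pixel-count weights). The LEFT/RIGHT
classifier is a from-scratch two-class Fisher discriminant with equal
priors and pooled within-class covariance
(`weight = S⁻¹(m₁−m₂)`); a ridge fallback covers singular covariances,
and a decision score of exactly zero takes the negative class. Equal
priors were chosen because the target cohorts are small and near
balanced; the evaluation protocol is leave-one-out (`lda_loocv()`),
reported in the output rather than hidden, since no canonical protocol
exists for cohorts this small. The default feature set is the
volume pair — the combination with the best reported discrimination —
with means and standard deviations selectable.

When masks arrive as gray-level expert overlays, `binarize_mask()`
defaults to Otsu's threshold on the overlay histogram; any explicit
threshold overrides it.

### VBM (Analysis-2)

Inputs are assumed co-registered; the package checks shape and affine
equality and refuses mismatched cohorts rather than attempting
registration, which is out of scope. The steps:

1. **Smoothing** with an isotropic Gaussian, default FWHM 8 mm (the
   conventional VBM choice; $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$
   per axis in voxel units). The separable filter renormalizes the
   truncated kernel at volume edges so constants are preserved exactly.
2. **Single-case t-map.** Comparing one patient against $n$ controls is
   the $n_1 = 1$ two-sample t-test, i.e. the Crawford–Howell single-case
   statistic $t = (\bar{x}_c - x_p)/(s_c\sqrt{1 + 1/n})$ with
   $df = n - 1$, oriented so larger $t$ means greater GM reduction. The
   test is one-tailed: only reduction is ever interpreted. Voxels with
   zero control variance get $t = 0$ and are counted.
3. **Thresholding.** Voxel threshold $p < 0.001$ by default ($p < 0.003$
   as the laxer alternative, selectable per patient); cluster-extent
   threshold strictly $> 50$ voxels. Connectivity is 26-neighbor by
   default (the most inclusive; 6 and 18 are configurable).
4. **Decision.** Among surviving clusters intersecting the left∪right
   ROI, the winner is the one containing the maximum $t$ inside the ROI
   union; the side is the sign of the peak's world x-coordinate
   (world $+x$ = subject right, as in MNI space). A midline peak is
   resolved by the hemisphere holding the majority of the cluster's
   voxels. No surviving cluster ⇒ MRI-negative.

All hemisphere logic runs in world space through the affine, never on
storage indices, so x-flipped files lateralize identically.

### EEG (Analysis-3)

The asymmetry score is computed over the full annotated ictal interval
of each recording; when a recording carries several ictal intervals
their energies are summed before the ratio. The epoch-length policy is
deliberately simple because the upstream annotation already bounds the
seizure; optional fixed-length sub-epochs with per-epoch majority voting
are available (`epoch_len`), default off. A flat (zero-energy) channel
pair is excluded from the vote rather than labeled — a 0/0 ratio carries
no lateralization information. Channel-name matching is
case-insensitive and order-free.

## What the synthetic generators emulate

The study data are private, so the package ships seeded generators that
plant known ground truth for every modality:

* `gen_ictal_eeg()` — 18 channels of band-limited Gaussian noise
  (4–30 Hz Butterworth, covering the rhythmic theta/beta seizure range)
  with an amplitude step inside the ictal interval. The focus-side
  temporal chain carries the configured energy ratio (default 4)
  against its homologs; parasagittal pairs carry half the asymmetry,
  mirroring temporal-lobe seizure topography; midline channels stay
  symmetric. Expected pair energy ratios equal the planted ratios
  exactly; realized ratios carry finite-sample error.
* `gen_hippo_study()` — elliptical hippocampus cross-sections on a
  T2-like slice stack; the sclerotic side is smaller (radius ×0.82 by
  default, a volume deficit of roughly one third) and brighter
  (`intensity_boost`, default +20 gray levels on a tissue mean of 100,
  noise sd 5). True volumes follow from mask pixel count × pixel area ×
  slice thickness, so measured volumes match truth exactly.
* `gen_gm_cohort()` — a smooth radial GM template (≈0.75 centrally)
  shared by `n_controls = 14` controls with iid voxel noise
  (sd 0.02), and one patient carrying a hard spherical GM deficit
  (depth 0.4, radius 6 mm) planted inside one hemisphere's ROI box.
  ROIs are axis-aligned boxes standing in for the temporal+limbic
  lobes; atlas parcellation is out of scope. Default grid 48³ at 3 mm —
  large enough that the 8 mm smoothing kernel and the >50-voxel rule
  behave as in realistically sized maps while keeping a full recovery
  study fast.
* `gen_tissue_volume()` — a K-class Gaussian intensity mixture with
  retained voxel labels, the input contract of `gmm_segment()`.

All randomness flows through one seed per call; identical configurations
reproduce bit-identical outputs.

These generators are intentionally idealized: no seizure waveform
morphology (spikes, chirps), no MRI physics or partial-volume effects,
no anatomical template, no registration errors, and noise that is iid
rather than spatially correlated. Passing the planted-truth recovery
tests therefore demonstrates that the decision machinery is correct and
well-calibrated on clean signal of the stated effect sizes — not that
the pipeline attains any particular accuracy on clinical data.

## Numerical choices

* GMM segmentation (`gmm_segment()`) initializes means at evenly spaced
  intensity quantiles (deterministic), runs EM with a log-sum-exp
  E-step, caps iterations at 200 with a relative log-likelihood
  tolerance of 1e-8 (warning + best iterate on cap), re-seeds a
  collapsed component once at a random data point and prunes it if it
  collapses again, and reports components sorted by mean.
* Component standard deviations are floored at 1e-12 to avoid
  degenerate spikes; posterior maps are renormalized to sum to one
  after any pruning.
* The Gaussian kernel is truncated at 4σ; rows of the banded
  convolution matrix are renormalized so smoothing preserves constants
  at the boundary.
* Percentages in the overlap report round half-up to one decimal,
  matching the printed precision of the worked example.
* `region_stats()` refuses empty masks and returns `NA` sigma (with a
  warning) for single-pixel regions.

## Problem sizes used in the shipped checks

The test suite and the acceptance script exercise: 100 seeded EEG
recordings (10 s, energy ratio 2) for recording-side recovery; 20 seeded
GM cohorts (48³ voxels, 14 controls, depth 0.4) for VBM hemisphere
recovery; 16³-voxel mixtures for GMM mean recovery (±0.02 band); 20
synthetic patients per side for leave-one-out LDA; and the exhaustive
3³ label combinations for the fusion invariants. Dense brute-force
oracles (loop sums, full 3D convolution, flood fill, per-voxel t) run on
grids of 8³–11³ where exact agreement to 1e-9 is asserted.

## Known limitations

* Registration/normalization is a precondition, not a feature; the
  package never warps volumes.
* ROI boxes are geometric stand-ins; anatomical naming of peaks (e.g.
  "parahippocampal gyrus") is not attempted.
* The EEG stage assumes expert-annotated ictal intervals; seizure
  detection is out of scope.
* EDF input is not supported; recordings travel as CSV (channel per
  column) with a JSON sidecar for the sampling rate and intervals.
* The real-data accuracies of the source cohorts cannot be reproduced
  here — the clinical data are private; the worked-example table is the
  only real-data artifact, and everything else is validated on
  synthetic planted truth.
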