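---
title: "Shading-map intensity normalization and pseudo-CT synthesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shading-map intensity normalization and pseudo-CT synthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpct)
```

## The problem

MRI intensity is relative: the same tissue imaged with the same sequence can
land at very different intensity levels across scanners, coils, and even
across the field of view of a single scan, because receive-coil sensitivity
and field imperfections multiply the true signal by a smooth, spatially
varying *bias field* (also called shading or intensity inhomogeneity).  Any
method that converts MRI intensities into CT-like Hounsfield units (HU) for
MR-only radiotherapy planning or PET/MR attenuation correction therefore
inherits two problems: the same tissue maps to different HU at different
positions, and a converter calibrated on one scanner is useless on another.

`mrpct` implements a normalization-plus-conversion workflow for non-bone
torso tissues:

1. **Shading-map normalization** brings every tissue to a common per-tissue
   intensity level while preserving edges.
2. **Pointwise pair extraction + a small patch network** learns the
   MRI-to-HU mapping from rigidly registered MRI/CT pairs, using phantom
   template images rather than raw anatomical patches so that residual
   registration error cannot corrupt the training labels.

Everything is verifiable without patient data through a digital
torso-phantom simulator with known tissue labels, bias field and noise.

## The normalization model

Let $I(x)$ be the observed MRI, modeled as $I(x) = L(c(x))\,b(x) +
\varepsilon(x)$, where $c(x)$ is the tissue class at voxel $x$ (air/lung,
soft tissue, fat), $L$ the class's intrinsic level, $b$ a smooth positive
multiplicative field, and $\varepsilon$ noise.  The pipeline
(`normalize_mri()`) estimates $b$ and divides it out:

1. **Segmentation** (`segment_tissues()`): fuzzy c-means on all voxel
   intensities with $k = 3$, fuzziness $m = 2$, deterministic
   quantile-based initialization; clusters are mapped to tissues by
   ascending center (air/lung < soft < fat, the T1-weighted ordering of the
   targeted scanners).
2. **Three-intensity mask** (`build_three_intensity_mask()`): each class is
   replaced by a bulk level $B(c)$, giving $M(x) = B(c(x))$.
3. **Ratio image** (`compute_ratio_image()`): $R = I / M$.  Where the
   segmentation is right and $L \approx B$ up to one global factor, $R
   \propto b$ plus noise and class-wise step errors.
4. **Shading map** (`smooth_ratio()`): a $w \times w$ moving average
   (default $w = 10$ pixels) of $R$, applied per axial slice.  The filter
   passes the low-frequency bias and suppresses both noise and the
   class-boundary steps.
5. **Correction** (`correct_intensity()`): $I_{\text{corr}} = I / S$.
   Because $S$ contains only slow variation, edges and other high-frequency
   content survive; because $S \approx b\,L/B$ within each class, corrected
   tissue means land at the bulk levels regardless of the scanner's overall
   gain.

A direct consequence worth noting: the whole chain is *scale-equivariant* —
multiplying the input MRI by any constant leaves the corrected image
unchanged (FCM centers scale with the data, hence the ratio scales, hence
the shading map scales, and the division cancels it).  This is the exact
mechanism that harmonizes scanners whose intensity ranges differ by a
global gain.

### Parameters that matter

| parameter | default | meaning / why |
|---|---|---|
| bulk levels $B$ | air/lung 18, soft 65, fat 149 a.u. | target per-tissue scale after correction; a stand-in for a site cohort-mean table, always user-overridable (`bulk_intensities()`) |
| smoothing width $w$ | 10 px | passband of the shading estimate; must be much smaller than the bias length scale and larger than the noise correlation length |
| FCM fuzziness $m$ | 2.0 | the conventional default; the method needs only the hard labels |
| FCM tolerance / cap | 1e-4 relative center movement / 300 iterations | convergence is typically reached in well under 100 iterations |

Smoothing is 2-D per axial slice, not 3-D: in-plane pixels (0.66–1.5 mm)
are several times finer than slice spacings (3–8 mm), so a cubic 10-pixel
window would be strongly anisotropic in physical units, and coil shading is
predominantly in-plane.  The even width uses the window
$[i - w/2,\, i + w/2 - 1]$ on each axis with replicated borders; border
replication avoids dark halos at the body outline.  The shading map is
floored at $10^{-6}\times$ its median so division is safe in all-air
regions.  The ratio is computed at every voxel, including background.

### What the method does *not* fix

The bulk table fixes the *ratio* of class levels.  When the true class
levels of a scan are not proportional to the bulk table (different
sequences weight tissues differently, not just with one gain), the ratio
image carries class-dependent offsets, and inside the smoothing window
around each tissue boundary the shading map mixes them.  Voxels within
$w/2$ pixels of a boundary are then biased by up to the relative
level-ratio mismatch.  Thin structures — a subcutaneous fat ring of width
comparable to $w$ — feel this the most.  This is a real property of the
method, visible in the package's cross-preset harmonization measurements:
a pure gain difference harmonizes exactly, while the chest/abdomen preset
pair (whose level tables are deliberately non-proportional) leaves the
corrected fat means a few percent apart.

## Registration

Pseudo-CT training data requires CT aligned to MRI.  `mattes_mi()`
implements the Mattes mutual-information metric: 50 uniformly spaced bins,
500 samples by default (both configurable; tests use thousands of samples
where estimator variance matters), a zero-order kernel on the fixed-image
intensity axis and a cubic B-spline Parzen kernel on the moving axis, bin
edges at the 1st–99th intensity percentiles of the overlap.  Samples are
drawn afresh from the configured seed at every metric evaluation, so the
metric is deterministic and smooth in the transform parameters.

`rigid_register()` maximizes the metric with a derivative-free coordinate
search (golden-section line search per parameter, shrinking brackets, two
resolution levels).  Deformable registration is *not* estimated: the
package applies externally supplied dense displacement fields
(`apply_deformation()`) but deliberately does not estimate them — rigid
alignment plus the pointwise-pair design below already tolerates moderate
residual misalignment.

The estimator's known small-sample bias (about
$(B_f - 1)(B_m - 1)/2N$ nats for a $B_f \times B_m$ histogram from $N$
samples, roughly halved by the spline smoothing) is measurable: two
independent noise images score ~0.12 nats at 50 bins / 5 000 samples
rather than 0.  Tests bound it by repetition instead of pretending it away.

## Pointwise pairs, templates, and the conversion network

From registered, corrected MRI/CT volumes, `extract_pairs()` takes per
slice and tissue the voxels of the class mask sorted by MRI intensity and
samples them at evenly spaced ranks $\lfloor j (M-1)/(n-1) \rfloor$ — 25
pairs for lung and fat, 50 for soft tissue — always including the class
minimum and maximum.  Rank spacing (rather than even intensity spacing) is
robust to skewed histograms and deterministic under ties (ties break by
scan order).  Soft tissue is split per slice at the median rank into
low/high halves (`split_soft_tissue()`), yielding four template kinds:
lung, soft-low, soft-high, fat.

`build_template_pair()` renders each pair set as a pair of block-constant
images (default 40-px blocks on a square grid, pairs placed in ascending
order, surplus blocks cycling): at every pixel the (MRI, CT) value pair is
one of the extracted pairs, which is the only property the network needs;
the exact layout is immaterial.  `crop_patches()` randomly crops seeded
32×32 input patches with centered 18×18 labels.

The converter (`build_model()`, `train_model()`, `predict_volume()`) is a
three-stage valid-convolution network: kernels 7/5/5 (any odd triplet
whose reductions sum to 14 is accepted — the 32×32 → 18×18 shape arithmetic
is enforced), ReLU on the hidden stages, linear output, and deep
supervision through 1×1 auxiliary regression heads after stages 1 and 2
whose center-cropped MSEs join the main loss with weight 0.3 each.
Optimization is SGD with mini-batch 128, learning rate 0.01, momentum 0.9.

Numerical choices made here, and why:

* **Input and target standardization.**  Inputs are affinely scaled to
  zero mean / unit variance of the training set.  Targets are likewise
  standardized *inside the optimizer* and predictions mapped back to HU:
  raw-HU residuals are two to three orders of magnitude larger than
  unit-scale activations, and plain SGD at learning rate 0.01 with
  momentum 0.9 demonstrably diverges on them with any standard
  initialization (the loss curvature seen by the output layer scales with
  fan-in times activation second moments).  All reported losses and all
  predictions are in HU.
* **Gradient-norm clipping** (global norm 5 by default) tames the
  start-of-training transient that momentum otherwise amplifies into
  dead-ReLU collapse; after the first epochs it is inactive.
* **Initialization**: He-scaled normal for rectified stages, variance
  $1/\text{fan-in}$ for the linear output and heads, zero biases, all from
  the model seed.
* **Width**: the channel default is 64/64/1, but the conversion task the
  pairs define is pointwise and nearly piecewise-linear; widths of 4–16
  reach the same accuracy in minutes on one CPU core, so examples, tests
  and the acceptance study use 4–8.
* **Epochs**: default 50 with early stopping (patience 10 on validation
  loss, best weights restored); the package's own studies use 30 fixed
  epochs.

`predict_volume()` tiles each axial slice with reflect-padded 32×32
windows (stride 18 by default, plus edge-flush windows) and averages
overlapping 18×18 outputs.  A transparent piecewise-linear lookup
(`fit_lookup_converter()`) ships alongside as a fast baseline and test
oracle.  Bone is out of scope: `compose_bone()` pastes registered real-CT
values inside a user-supplied bone mask.

## The torso phantom

`make_torso_phantom()` emulates the two acquisition settings the package
targets, as 2-D axial anatomy replicated with slow slice-wise deformation
(±5% radii) across slices:

* **chest** (0.35 T MR-LINAC): elliptical body, subcutaneous fat ring
  (outer 10% of the body radius, the middle of the plausible 8–12% band),
  soft-tissue interior, two lung ellipses; MRI levels 26/125/297 a.u. and
  CT levels −800/35/−108 HU for air-lung/soft/fat, matching the cohort
  statistics of a low-field chest protocol.
* **abdomen** (1.5 T diagnostic): same construction with a bowel-gas
  pocket instead of lungs; MRI levels 65/298/533 a.u., CT levels
  −822/32/−86 HU.  The roughly two-fold level difference reproduces the
  inter-scanner intensity-range mismatch the normalization exists to
  remove — deliberately *not* a pure gain difference, so cross-preset
  experiments exercise the method's boundary-mixing limitation as well.

The bias field (`make_bias_field()`) is either a sum of seeded Gaussian
blobs rescaled to span $1 \pm a$ (default amplitude 0.3, blob scale 40 px)
or a linear ramp, renormalized to spatial mean 1 and constant along the
slice axis (coil shading is predominantly in-plane).  Noise is Gaussian
(default SD 5 a.u.) or Rician.  Defaults were chosen once as realistic for
the emulated scans: a ±30% in-plane shading amplitude is typical of
surface-coil torso imaging, and SD 5 gives the soft-tissue SNR of ~25
seen in such protocols.

What the phantom does **not** emulate: MR physics (no signal equations, no
k-space artifacts), realistic organ atlases, partial-volume ramps at
boundaries, and anatomically textured tissue.  Passing tests therefore
demonstrate correctness of the *estimators* under the stated model — a
multiplicative smooth field on piecewise-constant anatomy — not clinical
performance on patient data.

## Problem sizes used in the bundled studies

The test-suite and acceptance studies run on one CPU core at desk scale,
chosen as the smallest sizes at which each property is cleanly measurable:
24×256×256 phantoms for shading recovery and harmonization; 4×128×128 for
segmentation accuracy; single 96×96 slices with 3 000 metric samples for
registration recovery; 50 000 samples for the closed-form MI comparison;
2 000 training patches / 30 epochs / width-4 channels for the conversion
study.

## Known limitations

* Bulk levels are a calibration input; with a badly mismatched table the
  corrected scale is wrong even though the shading estimate is not.
* Tissue boundaries bias the shading map within half a smoothing width, as
  discussed above; thin fat rings are the worst case.
* FCM with $k = 3$ pools exterior background air with lung; scans whose
  background statistics differ strongly from lung may want a body-mask
  preprocessing step.
* The rigid optimizer is a local search: initial misalignment should be
  within the basin of attraction (a few tens of mm / degrees at the
  default two-level schedule).
* Training is CPU-oriented and deterministic per platform; bitwise
  reproducibility across BLAS implementations is not guaranteed.
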