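---
title: "UATransNet: model, preprocessing and training choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{UATransNet: model, preprocessing and training choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uatransnet)
```

## Scope and model

`uatransnet` implements a U-shaped encoder-decoder segmentation network for
2-D tumor MRI slices, together with the three surrounding method stages that
make it a complete pipeline: a mean-teacher dataset-optimization step, a
classical suspected-region preprocessing pipeline, and a pixel-wise
evaluation suite. The clinical images the method targets are not
redistributable, so the package ships a phantom generator whose output —
bright, roughly elliptical tumors on darker tissue, with blurred edges and
additive Gaussian noise — stands in for them everywhere, including the test
suite.

The network is a residual U-net. Each block applies three 3×3 convolutions,
each followed by group normalization and ReLU, with an additive shortcut
(a 1×1 convolution when the channel count changes). Group normalization is
used instead of batch normalization so behaviour does not depend on batch
size; the default of 8 groups (12 for the full-size preset) follows common
practice. Downsampling is 2×2 max pooling; channel widths double per scale
from `base_width`.

### The attention bottleneck (MGAM)

At the bottleneck, two attention components act on the encoder feature
`F ∈ R^{c×h×w}`:

* **TSAC** (channel-level transformer self-attention). A learned position
  embedding of the bottleneck shape is added, the map is flattened to
  `c × n` (`n = h·w`), and projected with `W_q`, `W_k`, `W_v` (`c × c`).
  The contextual attention map `CAM = softmax(Q Kᵀ / √d_k)` is `c × c` with
  rows normalized; the output is `CAM · V`, reshaped back. With `n_heads >
  1` the channels are split across heads and the concatenated heads are
  mixed by one more `c × c` embedding; the default is a single head, in
  which case no output mixing is applied. `d_k = c / n_heads`.
* **GCAC** (position-level context aggregation). Two 1×1 convolutions
  reduce the channels to `c₁ = max(1, c/8)`, giving `V` and `W`; the
  position attention map `L[i, j] = softmax_i⟨V_i, W_j⟩` is `n × n` with
  columns normalized, and the output at position `j` is `Σ_i L[i,j]·U[:,i]`
  with `U` the flattened input. Written as a matrix product this is
  `U %*% L`. The aggregation must run over `U` (not `W`): aggregating the
  `c₁`-channel `W` would both collapse to `W_j` under the column-stochastic
  `L` and produce the wrong channel count for the fusion below. This
  disambiguation is a deliberate design decision of the package.

The fusion is `a₁·TSAC + a₂·GCAC + F` with both scale parameters *learnable
and initialized to zero*, so the whole network is exactly its attention-free
variant at initialization — a structural identity the test suite asserts.
Shared backbone parameters are drawn before the attention parameters, so
models differing only in `use_mgam` share their backbone initialization at
equal seeds. A fixed grid of `(a₁, a₂)` combinations — (1,0), (0.75,0.25),
(0,1), (0.5,0.5), (0.25,0.75) — is exposed as an experiment mode
(`cmd_alpha_grid()`), with the weights pinned during training.

### Decoder variants

Two skip-fusion schemes are provided. *Residual*: each decoder block
concatenates the encoder skip with the bilinearly upsampled previous decoder
feature and applies a residual block (whose shortcut provides the additive
path). *Dense*: each decoder block concatenates the encoder skip with **all**
previous decoder outputs (bottleneck included), upsampled to the current
resolution, giving `d(d−1)/2` cross-stage feature reuses at depth `d`.
Upsampling is bilinear with aligned corners throughout.

Where exactly the two schemes apply per stage is not prescribed anywhere;
the package treats them as two uniform decoder modes selected by
`skip_mode`, which reproduces the two published model variants as
configuration options.

## Implementation: a micro autodiff engine

No deep-learning framework is used. The network runs on a small
reverse-mode automatic-differentiation tape written for this package, over
C++ (RcppArmadillo) kernels for convolution (im2col + GEMM), 2×2 max
pooling and bilinear resampling; softmax, group normalization and the losses
are differentiated in R with hand-derived backward rules. Every backward
rule is validated against central finite differences in the test suite
(relative error below 1e-4 on random small inputs). Softmax logits are
shifted by their maximum before exponentiation; probabilities entering
logarithms are clipped at 1e-7.

Feature maps are stored channels-last (`h × w × c` arrays), which maps
directly onto Armadillo cube slices; the flattened `c × n` matrices of the
attention components use the channel-first convention stated above.
Coordinates are 1-based `(row, col)` and ROI boxes are closed integer
ranges, the natural conventions in R.

## Classical preprocessing pipeline

`segment_suspected_region()` chains:

1. **ROI detection** — the bounding box (fixed margin, default 2 px) of
   pixels at or above the `bright_percentile` intensity quantile (default
   0.95). This is a deliberately simple intensity-percentile stand-in for a
   learned suspicious-region detector, and relies on the same prior as the
   rest of the pipeline: tumor brighter than surrounding tissue. Constant
   images are rejected ("no suspicious region").
2. **Contrast clipping** — the lowest and highest 5% of cumulative
   histogram mass map to 0 and 1, linearly in between. The source
   description of this step is ambiguous as printed; two-tailed 5% clipping
   is the package's documented reading, chosen because it is monotone
   (never reorders pixels) and parameter-free beyond the 5% weight.
3. **Windowed filtering inside the ROI** — median (impulse noise), then
   mean (false contours), then a Laplacian sharpening `I + λ(−∇²I)` with
   `λ = 0.5`, all with the same window: 5% of the longer ROI side, rounded
   up to the nearest odd integer, floored at 3. The median filter is an
   exact sliding-window median with replicate padding so constant regions
   pass through bit-identically; mean and Laplacian use kernel convolution
   (EBImage) with replicate boundaries.
4. **Size estimation** — Otsu's threshold over a 256-bin histogram of the
   observed ROI range (exhaustive search, ties broken toward the lowest
   bin). The pixel counts of the smaller and larger class bound the
   plausible tumor size; the threshold itself seeds the growth. On a
   near-constant ROI where Otsu is undefined, the caller falls back to
   full-ROI bounds.
5. **Seeded region growing** — the `k = 5` brightest pixels in the central
   third of the ROI (row-major tie-break) seed a breadth-first growth: a
   candidate with intensity `I` joins iff `I > θ` and `μ − I < θ`, with `μ`
   the running mean of the accepted region, updated after every accepted
   pixel (the region mean reads most naturally as the *current* region).
   Rejected frontier pixels are re-examined while the region still grows,
   since `μ` moves. If the grown region is smaller than the lower size
   bound, `θ` is lowered by `theta_step` (default 0.05, i.e. 5% of the
   intensity range) and growth continues, for at most `max_rounds = 20`
   rounds; growth stops once the region reaches the lower bound or exceeds
   the upper one. Connectivity defaults to 4. The decrement, seed count and
   connectivity are not prescribed by the method description; these
   defaults are the package's and are all exposed in
   `region_grow_config()`.

With frozen `μ` the admission test is monotone in `θ`, which is what makes
the adaptive loop sound; the test suite checks this monotonicity against an
order-independent flood-fill oracle.

## Mean-teacher dataset optimization

A binary case classifier (the same residual blocks, max pooling after every
stage, global average pooling, one fully connected unit) is trained as
student and teacher. The student minimizes mean binary cross-entropy on the
labeled part plus a consistency term on the unlabeled part; the teacher is
the exponential moving average `θ′_t = α θ′_{t−1} + (1−α) θ_t` and is never
trained directly. The consistency term is the Jensen-Shannon divergence
between student and teacher predictions (as two-point distributions) under
independent Gaussian input-noise augmentations. JS rather than plain KL is
used because KL is asymmetric; the printed form of the consistency loss
contains a self-KL term that is identically zero, evidently a typo, and the
package implements standard JS with the mixture midpoint. `α` defaults to
0.99 and the consistency weight to 1 with an optional linear ramp-up — none
of these values are prescribed, and all are exposed.

A trained classifier then partitions a dataset into *effective*
(well-delineated; confidence at or above the threshold) and *difficult*
cases. The published effective/difficult proportions on the clinical data
(39.4% / 60.6%) depend on that embargoed dataset and are context, not a
reproducible target; the package's tests instead construct a mix with known
class margins.

## Training schedule and evaluation

Training uses Adam (optimizer unspecified in the source method; logged as a
package default), mini-batch gradient averaging (default batch 8), and a
two-phase learning rate: 1e-3 for the first half of training, 1e-4
afterwards, with cosine annealing over the whole run on top (floor 10% of
the base rate). The segmentation loss is binary cross-entropy plus soft
Dice — the source only specifies losses for the classifier, so the
segmentation loss is a documented addition. Probability maps are cut at 0.5.

Metrics (accuracy, precision, recall, IoU, Dice, F1) are computed per image
from pixel confusion counts and reported both macro-averaged (mean ± sd
across images) and micro-averaged (pooled counts). Ratios with zero
denominators are reported as `NA`, never silently as 0. `DSC =
2·IOU/(1+IOU)` holds identically and is asserted on random masks.
`stratified_split()` reproduces age-stratified cohort splitting with
largest-remainder rounding so the global train count is hit exactly.

## What the phantoms do and do not show

The generator emulates the features the pipeline actually exploits: a
brighter, roughly elliptical tumor (rotated ellipses, uniform angle), blurred
edges (Gaussian blur), sensor noise (additive Gaussian), and variable size
and position. It does not model MRI physics — no bias fields, no Rician
noise, no anatomy, no multi-slice structure. Passing tests therefore
demonstrate that the algorithms are implemented correctly and behave as
designed on images satisfying their stated priors; they do not demonstrate
clinical-grade performance. No quantitative description of the original
images (resolution, intensity distribution) is available, so the phantom
defaults (64×64, foreground 0.8, background 0.2, noise sd 0.05, blur 1 px)
are the package's own choices of a plausible difficulty level, fixed once.

## Problem sizes used in tests and the acceptance script

The shipped checks run the test-scale preset (depth 3, width 8, ~58 k
parameters) on 200 training phantoms at 64×64 for 5 epochs with 20 held
out — chosen as the smallest setup at which held-out Dice comfortably
clears 0.85 (it typically reaches ~0.98 by epoch 5, with the classical
pipeline alone around 0.95 on clean phantoms). The full-size preset (depth
5, width 36, 256×256 input, ≈16.7 M parameters) is only instantiated to
report its parameter count, which sits in the 15–20 M band expected of this
family of lightweight attention U-nets.

## Known limitations

* Single-image (batch-size-1) kernels; mini-batches are realized by
  gradient accumulation, so there is no cross-image normalization anywhere
  (GroupNorm makes this exact by design).
* The R/C++ engine is CPU-only and orders of magnitude slower than a GPU
  framework; the full-size preset is practical for parameter accounting and
  single forwards, not for training at clinical scale.
* The learned ROI detector of the original pipeline stage is out of scope
  and replaced by the intensity-percentile box above.
* 2-D only; no DICOM; NIfTI input is accepted only as single slices.
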