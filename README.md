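# uatransnet

Segmentation of tumors in 2-D MRI slices for researchers who need a complete,
inspectable pipeline rather than a black box: a classical suspected-region
preprocessor, a U-shaped attention segmentation network (UATransNet), a
mean-teacher dataset-optimization stage, and a pixel-wise evaluation suite.
Because clinical MRI data of this kind are rarely redistributable, the
package also ships a reproducible phantom generator (bright elliptical
tumors on darker tissue, blurred edges, additive noise) so every stage runs
and is tested without any external data.

## The model

UATransNet is a residual U-net with a *multilevel guided self-aware
attention module* (MGAM) at the bottleneck. For an encoder feature
`F ∈ R^{c×h×w}` (flattened to `c × n`, `n = h·w`):

* **TSAC** — channel-level self-attention. With projections
  `Q = W_q F`, `K = W_k F`, `V = W_v F` and a learned position embedding
  added to `F`, the contextual attention map is
  `CAM = softmax(Q Kᵀ / √d_k) ∈ R^{c×c}` (row-stochastic), output `CAM·V`.
* **GCAC** — position-level context aggregation. Two 1×1 convolutions give
  `V, W ∈ R^{c₁×n}` with `c₁ = c/8`; the position attention map
  `L[i,j] = softmax_i ⟨V_i, W_j⟩ ∈ R^{n×n}` (column-stochastic) aggregates
  the flattened input `U` as `U L`.
* **Fusion** — `a₁·TSAC + a₂·GCAC + F`, with `a₁, a₂` learnable and
  initialized to 0, so the module is exactly the identity at initialization.

The decoder fuses multiscale features through either *residual* or *dense*
skip connections (both provided), with bilinear upsampling and
group-normalized residual convolution blocks throughout. Training,
backpropagation included, runs on a compact autodiff engine built for this
package over C++ convolution/pooling/resampling kernels — no deep-learning
framework required.

Around the network: seeded region growing (a candidate pixel joins when
`I > θ` and `μ − I < θ`, with `μ` the running region mean and `θ` adapted
from an Otsu-based tumor-size estimate), and a mean-teacher scheme whose
teacher is the EMA of the student (`θ′_t = α θ′_{t−1} + (1−α) θ_t`) with a
Jensen-Shannon consistency loss on unlabeled data.

## Worked example

```r
library(uatransnet)

# a reproducible phantom with known ground truth
it <- generate_phantom(phantom_spec(seed = 3))

# classical pipeline: ROI -> clipping -> filters -> Otsu -> region growing
mask <- segment_suspected_region(it$image)
dsc_from_masks(mask, it$mask)
#> [1] 0.9930796

# scaled-down network: 200 phantoms, depth 3 / width 8, 10 epochs
items <- generate_dataset(phantom_spec(), 240, seed = 11)
model <- build_model(net_config_preset("test-scale"), seed = 11)
model
#> uat_model (segmentation): depth 3, base width 8, skip 'residual', mgam on
#>   parameters: 58,371
model <- train_segmenter(model, items[1:200], epochs = 10,
                         val_items = items[201:210], seed = 11, verbose = TRUE)
#> epoch 1: lr 1.00e-03 loss 0.4754 val_dsc 0.936
#> ...
#> epoch 10: lr 1.00e-05 loss 0.0240 val_dsc 0.988
evaluate_segmenter(model, items[211:240])$macro$mean[["dsc"]]
#> [1] 0.987
```

The printed numbers are what they look like: Dice overlap between predicted
and true masks (1 = perfect). The classical pipeline alone recovers clean
phantoms at DSC ≈ 0.95–0.99; the trained test-scale network reaches ≈ 0.99
held-out on the same phantom distribution.

A thin CLI wraps the same functions
(`generate | preprocess | optimize-dataset | train | eval | segment |
alpha-grid`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/uatransnet.R", package="uatransnet"))')" \
    generate --out phantoms --n 50 --seed 1
```

## Package layout

* `R/phantom.R` — phantom generator and augmentations (rot90/180/270 —
  counter-clockwise — flips, rescale)
* `R/preprocess.R` — ROI detection, histogram clipping, windowed filters,
  Otsu size estimation, adaptive seeded region growing
* `R/mgam.R`, `R/network.R` — attention components and network assembly
* `R/autograd.R`, `src/kernels.cpp` — the autodiff tape and C++ kernels
* `R/semisupervised.R` — losses, EMA teacher, mean-teacher training,
  effective/difficult partition
* `R/metrics.R` — confusion counts, metric suite, stratified splitting
* `R/train.R`, `R/pipeline.R`, `inst/cli/uatransnet.R` — training loop,
  commands, CLI
* `vignettes/uatransnet-methods.Rmd` — model assumptions, parameter
  defaults, numerical choices and limitations
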