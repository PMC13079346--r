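# maefunet

Few-shot deployment of masked-autoencoder (MAE) MRI transformers, in R, at
desk scale. The package is aimed at neuroimaging methods researchers who want
to study *how* a pretrained MAE vision transformer is reused under severe
annotation scarcity — for MRI sequence classification by frozen-encoder
linear probing, and for skull stripping / anatomical segmentation by fusing
frozen transformer embeddings into a U-Net decoder — without GPU
infrastructure or access-controlled cohorts. Every stage runs on a bundled
synthetic brain phantom with exact ground truth.

## What it implements

**Coverage-weighted MAE pretraining.** Slices are patchified, 75% of patches
masked, and an encoder-decoder transformer reconstructs the masked patches.
The batch loss is the weighted mean of per-sample masked-patch MSEs,

    L = (1/N) Σ_i w_i l̃_i,   w_i = w_min + (1 − w_min) α_i,

where α_i is the slice's brain-coverage fraction from a binary brain mask, so
background-dominated slices pull less on the representation. The batch
gradient is exactly the weighted average of per-sample gradients.

**MAE-classify.** A linear head (C×d weights + C biases, i.e. C(d+1)
trainable parameters) on the frozen encoder's final-layer CLS embedding,
trained with cross-entropy.

**MAE-FUnet.** A U-Net backbone fused at the bottleneck and every decoder
scale with projected patch tokens from tapped encoder layers,
h_s = Fuse(f_s, Π_s(g(x))), where Π_s is a linear channel map plus bilinear
spatial resize. Fusion strategies: channel concatenation (+1×1 reduction),
element-wise addition, and single-head cross-attention (CNN positions as
queries, patch tokens as keys/values) — drop-in interchangeable, with
trainable parameters ordered add < concat < attention. Trained with the
hybrid loss Dice + Focal(γ=2, α=0.25) + pixel-wise cross-entropy. A
fusion-free token-upsampling head (MAE-direct) and a plain U-Net mode serve
as baselines.

**Few-shot protocols and metrics.** Slice-level sampling with volume-level
train/test separation; sparse stride sampling (every k-th slice: floor(n/k)
slices, e.g. 56/44/37/32/28/24/22 on a 224-slice axis for strides 4–10);
volume-level sampling with tri-axial remapping and empty-mask filtering.
Metrics: accuracy/precision/recall, micro/macro/weighted F1, per-class
Dice/IoU, and mean ± population-std stability summaries.

All networks are hand-implemented with explicit forward/backward passes over
BLAS matrix products (no deep-learning framework), finite-difference-verified
in the test suite.

## Worked example

```r
library(maefunet)

# exact few-shot training-set sizes from the stride sampler (224-slice axis)
sapply(4:10, function(k) length(stride_sample(224, k)))
#> [1] 56 44 37 32 28 24 22

# stability summary (mean / population std) of seven per-stride IoU scores
s <- stability(c(95.16, 95.24, 95.23, 95.25, 95.18, 95.16, 95.12))
round(c(mean = s$mean, std = s$std), 3)
#>   mean    std
#> 95.191  0.045

# phantom -> slices -> desk-scale MAE pretraining
vols <- generate_phantom(phantom_spec(grid_size = 64, seed = 11))
slices <- unlist(lapply(names(vols), function(sq)
  remap_volume_to_slices(vols[[sq]], axes = "axial", min_foreground = 0,
                         volume_id = sq)), recursive = FALSE)
ds <- as_slice_dataset(slices)
ck <- mae_pretrain(ds, vit_config("tiny"), epochs = 40, batch_size = 8,
                   lr = 1e-3, seed = 7)
range(ck$loss_curve$loss)
#> [1] 0.007051499 0.055257829
```

The first number printed by `stability()` is the arithmetic mean of the
seven runs (95.19 after rounding: the protocol is stable across strides);
`std` is the population standard deviation, 0.045 — the dispersion of the
score across annotation-scarcity levels. The pretraining loss curve falls by
roughly an order of magnitude over 40 epochs, indicating the tiny encoder
has learned to inpaint masked anatomy. Downstream, with 10 labeled slices
per sequence the frozen-encoder probe reaches ~0.95 held-out sequence
accuracy on the phantom, and MAE-FUnet trained on 32 stride-sampled slices
reaches ~0.93 test Dice for skull stripping (see the acceptance tests, which
assert ≥0.9 and ≥0.8).

A thin CLI over the same functions is installed at
`inst/scripts/maefew` (verbs: `phantom`, `pretrain`, `probe`, `segment`,
`evaluate`, `sweep`).

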