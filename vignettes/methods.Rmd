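---
title: "Methods: a multi-encoder U-Net with bidirectional feature pyramids and attention decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a multi-encoder U-Net with bidirectional feature pyramids and attention decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The segmentation problem

Gliomas are delineated on multi-modal MRI as three nested clinical regions:
the whole tumor (WT: necrotic core, edema/non-enhancing tissue and enhancing
tumor), the tumor core (TC: necrotic plus enhancing) and the enhancing tumor
(EnT).  BraTS-style data provide four co-registered, skull-stripped
modalities (t1, t1ce, t2, flair) at 240×240×155 voxels with 1 mm isotropic
spacing and expert label volumes coded {0, 1, 2, 4}.  `triunet` segments a
single axial slice per case into the four classes background, necrotic
core, edema/non-enhancing and enhancing, from which the three clinical
regions are derived as label unions (WT = {1,2,3}, TC = {1,3}, EnT = {3} in
the package's contiguous internal coding; the file code 4 maps to class 3).

## Preprocessing

Each modality volume is reduced to one axial plane — index 90 for the
canonical 155-slice depth, where all tumor compartments are typically
visible, and the middle plane `floor(D/2)` otherwise — then center-cropped
from 240×240 to 224×224 (for an odd margin the trailing side loses the
extra pixel; 240→224 is even so this is a tie-break only), Gaussian-denoised
and z-score normalized, and the three channels t1, t1ce, t2 are stacked in
that fixed order.  Design notes:

* **Population standard deviation** in the z-score.  This is the image
  normalization convention; the output then has mean 0 and population sd 1
  exactly, and the operation is idempotent to floating tolerance.  A
  constant image is a degenerate input and raises an error rather than
  producing NaN.
* **Gaussian denoising** uses a separable kernel of radius 3σ, with the
  truncated kernel renormalized near borders so constants are preserved
  exactly and an interior impulse response sums to one.  The default
  σ = 0.5 px is deliberately mild — slice intensities are averaged over a
  ±1–2 px neighbourhood — and configurable; denoising precedes
  normalization and follows cropping.
* **Augmentation** emits the original pair plus horizontal/vertical flips,
  rotations in multiples of 90° (applied identically to image and mask as
  pure pixel permutations, so label histograms are invariant), additive
  Gaussian noise on the image only (sd 0.05 in z-score units) and an
  integer translation with zero padding (≤ 10 px).  Magnitudes are package
  defaults; seeds make every draw reproducible.

## Network

The network is U-Net-like with three parallel encoders: VGG-19, ResNet50
and MobileNetV2 topologies, classification heads removed, each exposing
five tap features.  VGG-19 taps are the last activation of each conv block
(native resolutions 224…14); ResNet50 and MobileNetV2 taps are their five
distinct-resolution stage outputs (strides 2…32).  A lateral 1×1
convolution brings every tap to a uniform 32 channels and resamples it
bilinearly onto the canonical pyramid (224, 112, 56, 28, 14) — necessary
because the three topologies do not natively share resolutions.  Pretrained
initialization is an opt-in flag taking a local weights snapshot; builds
are otherwise random (He initialization for convolutions) and require no
network access.  Fine-tuning is the default; encoders can be frozen, in
which case their parameters are excluded from optimizer updates.

Each encoder's pyramid is enriched by one five-level bidirectional feature
pyramid pass: a top-down sweep produces mid nodes L4mid → L2mid and the
finest output L1out, then a bottom-up sweep produces L2out → L4out from
three-term sums (level input + its mid node + resized finer output) and
finally L5out.  Fusion sums are unweighted, exactly as the layer is
defined; the learned fusion-weight variants of other detection networks
are intentionally not used.  "Conv" in the layer is realised as a
depthwise-separable block — 3×3 depthwise then 1×1 pointwise convolution,
each followed by batch normalization and a ReLU6 activation (the clipped
rectifier `min(max(x,0),6)`, matching the MobileNet lineage of the block).
Upsampling is bilinear ×2; downsampling is 2×2 max-pooling, both stride 2.
The number of stacked passes is configurable and defaults to one.

The three enriched pyramids are merged per level by channel concatenation
(3×32 → 96) followed by a 1×1 convolution back to 32 channels; an
elementwise-sum merge is available as a config alternative.  A learnable
concat–project merge subsumes plain summation and matches the published
32-channel post-fusion shape.

The decoder starts from the fused 14×14×32 bottleneck and applies four
UpAtt stages.  Each stage (i) derives a gating signal from the incoming
decoder feature by 1×1 convolution + batch norm, upsampled ×2 to the skip
resolution — the standard additive-attention reading, recomputed at every
depth; (ii) gates the skip feature with
`α = σ(ψ(ReLU(Wx·x + Wg·g + b_g)) + b_ψ)` where Wx, Wg, ψ are 1×1
channel-wise maps with 128 intermediate channels, Xavier-initialized, and
α ∈ [0,1] multiplies the skip feature with broadcasting over channels;
(iii) upsamples the decoder feature ×2, concatenates it with the gated
skip and applies a double convolution (two 3×3 convolutions with 128
kernels, batch norm + ReLU each).  The head is a 1×1 convolution to 4
channels, batch norm and a per-pixel softmax.  Ablation variants are
first-class build configurations: `single` (one encoder, plain decoder),
`multi`, `multi_att`, `multi_bifpn` and `full` (the default method).

## Training

The loss is dice loss over the four classes:
`Dice_c = 2·Σ p g / (Σ p² + Σ g²)` per class with a smoothing epsilon of
1e-6 in numerator and denominator (guards 0/0 on absent classes), and
`loss = 1 − mean(Dice_c)` — the unweighted four-class mean.  Optimization
is Adam (framework-default betas) with the polynomial decay
`α = α₀ (1 − e/Ne)^0.9`, α₀ = 1e-4, stepped per epoch with a 0-based
epoch counter so the first epoch uses exactly α₀ and the schedule reaches
0 at e = Ne = 350.  Batch size defaults to 5.  Cases are split 80:10:10
(train share `floor(0.8 n)`, remainder split evenly, validation taking the
odd case), which yields 295/37/37 at n = 369.  A checkpoint of the best
validation dice — chosen over validation loss as the quantity actually
reported — is kept and restored after training.  `Ne` (the schedule
horizon) and the number of epochs actually run are separate knobs, so
early-stopped runs keep the published schedule shape.

The layers run on a small reverse-mode autodiff engine built into the
package, with compiled im2col/GEMM convolutions, depthwise convolutions,
max-pooling and bilinear resampling kernels whose backward passes are
exact adjoints (each is verified against brute-force and
finite-difference oracles in the test suite).  Batch normalization uses
batch statistics in training and exponential running statistics
(momentum 0.1) in evaluation.

## Synthetic phantoms

The phantom generator emulates the *structure* of a BraTS case so the whole
pipeline is testable without any download: four co-registered modality
volumes plus a label volume in file codes, with the tumor modelled as
nested ellipsoids — necrotic core innermost, an enhancing rim around it,
an edema shell as the whole-tumor extent — inside an ellipsoidal brain
mask.  Per-tissue mean intensities are chosen so t1ce is brightest in the
enhancing rim and flair brightest in edema, plus additive Gaussian noise
(sd 5 on a tissue-mean scale of ~100).  The defaults are a 64×64×32 volume
(desk-scale; 240×240×155 is available) with in-plane radii 22%/14%/8% of
the image side, so the default extracted slice contains all three regions
and every metric code path sees non-empty masks.

What the phantoms do **not** emulate: MRI physics (bias fields, partial
volume, acquisition artifacts), anatomical texture, irregular or
multi-focal tumor geometry, and inter-case intensity variation beyond
geometric jitter.  Passing tests therefore demonstrate correctness of the
pipeline and the ability of the network to fit simple contrast-coded
structure — not clinical segmentation quality on real data.

## Numerical choices and degenerate inputs

* Metric conventions: DSC and IoU of two empty masks are 1; the
  95th-percentile Hausdorff distance (HD95) of two empty masks is 0, and
  it is reported as undefined (NA, excluded from averages) when exactly
  one mask is empty.  IoU is computed as `|G∩S|/|G∪S|`, which satisfies
  `IoU = DSC/(2 − DSC)` exactly — the identity the published region
  metrics themselves satisfy.
* HD95 takes the 95th percentile of boundary nearest-neighbour distances
  in each direction (boundary = mask pixels with a 4-connected background
  neighbour, image border counting as background; a boundary-free mask
  falls back to all its pixels), then the maximum of the two directed
  values.  The percentile is the community meaning of the "95"; the
  sup–inf form is available via `percentile = 1`.
* Pixel metrics with a zero denominator return 0 with a `degenerate` flag
  rather than NaN.
* Weight initialization: He for convolutions, Xavier for the attention
  gate maps, zeros/ones for BN shifts/scales; builds are reproducible
  under a seed.

## Problem sizes used in the tests

The suite exercises the full method at two scales.  The published-scale
model (224×224 inputs, full encoder widths, 32/128-channel pyramid and
decoder) is built once and run forward to verify every published layer
shape.  All learning tests use the `tiny` profile — identical topology at
64×64 inputs, 1/8 encoder widths, 8-channel pyramids, 16-channel
decoder/attention — which trains at a few seconds per step on a single
CPU.  The learning smoke test overfits four phantom slices for 50
optimizer steps with α₀ = 3e-2 on the slow (Ne = 350) schedule — a
deliberately aggressive overfit configuration, distinct from the published
training protocol, chosen to demonstrate optimization health rather than
generalization — and each ablation variant is checked to reduce its
training loss on a single-sample overfit.

## Known limitations

* 2-D only: one axial slice per case, as in the method it implements;
  volumetric (2.5-D/3-D) segmentation is out of scope.
* The engine is CPU-bound and single-threaded apart from BLAS; it is meant
  for desk-scale verification, not for training at the published scale
  (hours of GPU time on the real dataset).
* Pretrained encoder weights are supported only as local snapshots; the
  package never downloads.
* Batch norm at batch size 1 in training mode degenerates to instance
  statistics; the pipeline defaults keep batches ≥ 2 where it matters.
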