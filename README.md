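# triunet

Brain-tumor segmentation on multi-modal MRI with a U-Net-like network that
combines **three parallel encoders** (VGG-19, ResNet50 and MobileNetV2
topologies), a **five-level bidirectional feature pyramid** applied to each
encoder, **cross-encoder fusion**, and an **attention-gated decoder** with a
four-class softmax head.

The package is aimed at researchers who want a fully inspectable,
CPU-runnable implementation of this architecture family: every stage — the
BraTS-style preprocessing chain, the network, dice-loss training and the
clinical evaluation metrics — is ordinary R code over a small built-in
autodiff engine with compiled convolution kernels, and the whole pipeline is
testable on synthetic phantoms without downloading any data.

## The model

An input slice is the modality stack [t1, t1ce, t2], center-cropped to
224×224 and z-scored per channel ((i − μ)/σ, population σ). Each encoder
exposes five tap features that a lateral 1×1 convolution maps to a uniform
32-channel pyramid at resolutions (224, 112, 56, 28, 14). One bidirectional
pyramid pass enriches each encoder's levels L1…L5:

    L4mid = Conv(L4in + Up(L5in))        L2out = Conv(L2in + L2mid + Down(L1out))
    L3mid = Conv(L3in + Up(L4mid))       L3out = Conv(L3in + L3mid + Down(L2out))
    L2mid = Conv(L2in + Up(L3mid))       L4out = Conv(L4in + L4mid + Down(L3out))
    L1out = Conv(L1in + Up(L2mid))       L5out = Conv(L5in + Down(L4out))

with Conv a depthwise-separable block (3×3 depthwise + 1×1 pointwise, batch
norm + activation after each convolution), bilinear ×2 upsampling and 2×2
max-pool downsampling. The three pyramids are fused per level
(concat → 1×1 conv → 32 channels). The decoder runs four UpAtt stages from
the 14×14 bottleneck; each gates its skip feature with additive attention

    α = σ₂( ψᵀ σ₁(Wxᵀ xl + Wgᵀ gi + b_g) + b_ψ ),   x_out = xl · α

(σ₁ = ReLU, σ₂ = sigmoid, 1×1 channel-wise maps, α ∈ [0,1]), upsamples ×2,
concatenates and applies a double 3×3 convolution with 128 kernels. Training
minimizes the four-class dice loss, `Dice = 2Σpg / (Σp² + Σg²)` per class,
with Adam and the polynomial decay `α = α₀(1 − e/Ne)^0.9` (α₀ = 1e-4,
Ne = 350, batch 5, 80:10:10 split). Evaluation reports DSC, IoU, HD95 and
pixel metrics over the clinical regions WT/TC/EnT.

See `vignettes/methods.Rmd` for the full methods account, parameter
defaults and design rationale.

## Worked example

Synthesize four phantom cases (nested tumor compartments, four modalities),
preprocess, overfit the desk-scale model and evaluate:

```r
library(triunet)

dirs  <- synthesize_cases(file.path(tempdir(), "phantoms"), n_cases = 4,
                          shape = c(64, 64, 32), seed = 7)
pairs <- lapply(dirs, function(d)
  preprocess_case(read_case(d), sigma = 0.5, target = 64))

model   <- build_model("full", profile = "tiny", seed = 11)
config  <- train_config(alpha0 = 3e-2, Ne = 350, epochs = 50,
                        batch_size = 4, seed = 11)
history <- train_model(model, list(train = pairs), config,
                       restore_best = FALSE)
report  <- evaluate_split(model, pairs)
```

Printed output (about three minutes on one CPU):

```
<triunet_model 'full' (tiny profile): vgg19+resnet50+mobilenetv2 encoder(s)
 + Bi-FPN + attention decoder, 762626 parameters>
<train_history: 50 epochs, best epoch 50 (dice 0.9792)>
  region   dsc   iou hd95 precision recall    f1 accuracy
1     WT 0.928 0.867 1.85     0.867  1.000 0.928    0.979
2     TC 0.937 0.882 2.21     0.882  1.000 0.937    0.993
3    EnT 0.916 0.845 1.00     0.883  0.952 0.916    0.995
```

The training dice rising to ~0.98 shows the optimizer and architecture are
healthy (an overfit sanity check, not a generalization claim); the report
lists mean per-region dice/IoU (fractions), 95th-percentile Hausdorff
distance (mm) and pixel metrics of the predicted versus true label maps.
`build_model()` also exposes the ablation variants (`single`, `multi`,
`multi_att`, `multi_bifpn`) and a `"full"` profile that reproduces the
published 224×224 layer shapes.

Real BraTS cases work through the same entry points: point `read_case()` at
a case directory with `_t1/_t1ce/_t2/_flair/_seg` NIfTI files, or drive
everything from the command line via `inst/cli/triunet.R`
(`synth`, `preprocess`, `train`, `evaluate`, `predict` subcommands, YAML
config, JSON run manifests).

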