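# dcfnet

`dcfnet` is an R implementation of **DCF-Net**, a dual-attention,
cross-layer-fusion network for 2D medical image segmentation — the problem
of assigning every pixel of a CT, MRI or dermoscopy image to an anatomical
class (organ, cardiac structure, lesion, background). It is aimed at
methods researchers and tool builders who want a fully inspectable,
dependency-light segmentation stack in R: every layer, gradient, loss and
metric is plain code in this package, validated against independent oracles.

The architecture is a hybrid CNN-Transformer encoder-decoder:

* a convolutional encoder of **CPCA** blocks (channel-prior convolutional
  attention) producing features at 1/4, 1/8 and 1/16 scale;
* a decoder built from **CASA** blocks (channel-adaptive sparse attention),
  each the residual cascade LN→XCA, LN→MixFFN, LN→TKSA, LN→MixFFN, where

  * XCA is cross-covariance attention
    `XCA(Q,K,V) = V · Softmax(KᵀQ / τ)` over l2-normalized channel columns,
  * TKSA sparsifies the channel similarity `S = (QᵀK) ⊙ τ` per head with a
    top-k mask at k = C/2, 2C/3, 3C/4 and 4C/5, combining the four branches
    with learnable weights α₁..α₄;

* **SSCF** skip-fusion blocks that concatenate encoder and decoder features
  and refine them with a dual-residual SCSA + Lite-FFN block
  (`x_s = x_cat + γ₁·SCSA(LN(x_cat))`, `x_f = x_s + γ₂·LiteFFN(LN(x_s))`)
  before pointwise channel compression;
* patch-expanding upsamplers (channels halve, resolution doubles) and a
  linear projection head;
* the hybrid objective `Loss = λ·L_CE + (1−λ)·L_Dice`.

The default configuration is budget-calibrated to 42.04M parameters and
18.37 GFLOPs for one 224×224 forward pass. Evaluation covers per-class
Dice, Hausdorff distance (maximum and 95th percentile) and the binary
confusion panel (accuracy, precision, sensitivity, specificity, IoU), with
per-slice or stacked-volume aggregation.

Networks run on a small reverse-mode autodiff tape built into the package
(with compiled convolution kernels), so no external deep-learning framework
is required. A seeded phantom generator produces multi-organ CT-like,
cardiac MRI-like and lesion-like image/mask datasets, making the entire
training and evaluation pipeline testable offline.

## Worked example

Train a width-reduced model on synthetic lesion phantoms and evaluate on a
held-out set (a few minutes on one CPU):

```r
library(dcfnet)
set.seed(1)

spec <- phantom_spec("lesion", img_size = 48L, n_images = 80L, seed = 7L)
phs  <- lapply(1:80, function(i) generate_phantom(spec, i))
imgs <- lapply(phs, `[[`, "image")
msks <- lapply(phs, `[[`, "mask")

cfg   <- model_config(stage_plan = stage_plan(c(16L, 32L, 48L)),
                      img_size = 48L, num_classes = 2L)
model <- build_model(cfg)
tc    <- train_config("adam", lr = 2e-3, epochs = 1L, batch_size = 8L,
                      lam = 0.5, weight_decay = 0, seed = 1L)
res   <- train_model(model, imgs[1:64], msks[1:64], tc, steps = 240L)
tail(res$history$loss, 1)
#> 0.0172

evaluate_model(model, imgs[1:64], msks[1:64])$mean_dsc   # training fit
#> 0.98
ev <- evaluate_model(model, imgs[65:80], msks[65:80])    # held out
ev$mean_dsc
#> 0.731
rep <- segmentation_report(ev$pred, msks[65:80], num_classes = 2L)
summarize_report(rep)$mean_hd95
#> 6.32
```

The training loss has the hybrid form above (λ = 0.5 here); the mean DSC of
0.98 on the training images shows the pipeline fits, and 0.73 on held-out
phantoms shows it generalizes on this small, deliberately noisy synthetic
task (contrast 0.5, boundary blur 1.5 px, noise 0.05). The budget report
for the full-width default model:

```r
cmd_info(model_config())
#> params: 42.04M  flops: 18.37G (img_size 224)
```

A command-line wrapper with `train`, `evaluate`, `predict`, `info` and
`make-phantoms` subcommands is installed at `inst/cli/dcfnet.R`:

```sh
Rscript inst/cli/dcfnet.R make-phantoms --out data/ --regime lesion --n 40 --size 48
Rscript inst/cli/dcfnet.R info
```

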