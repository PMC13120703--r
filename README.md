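# medspectralnet

A lightweight dual-stream convolutional classifier for medical images,
implemented in R from the linear algebra up: a small tape-based reverse-mode
autodiff core with compiled (RcppArmadillo) convolution kernels, and on top
of it the full architecture, training loop, metrics, profiler, and Grad-CAM
interpretability.

## The model

Medical image classification needs both high-frequency texture (lesion
boundaries, speckle) and low-frequency anatomy (organ shape, context).
Self-attention models both but at quadratic cost in the pixel count. This
architecture gets the same kind of global awareness at linear cost with two
modules over a ResNet-18 backbone:

* **SpectralFlow** splits a feature map x into complementary streams. A 1×1
  convolution reduces x to `x_l` (C/2 channels); a softmax-normalized filter
  generated from the *globally pooled* descriptor turns each non-overlapping
  k×k patch of `x_l` into its weighted mean, giving a piecewise-constant
  low-frequency map `x_la`; after projection back to C channels the
  high-frequency residue is defined exactly as

      x_h = x − x̃_la

  so the two streams always reconstruct the input. Learned per-channel
  attention (a_l + a_h = 1) reweights the streams before a final 1×1 mixing
  convolution.

* **ContextGate** runs three pathways on the same input — spatial (depthwise
  3×3 + SpectralFlow + 1×1 to ⌊C/3⌋ channels), gating (1×1 + GELU), identity
  (1×1) — and fuses them as

      x_mod   = g̃ ⊙ Concat(c_out, i)
      x_final = Conv1×1(x_mod) + x

  so that the block with zeroed parameters is exactly the identity.

The full network is `f_b = backbone(image)`, then
`fused = f_b + SpectralFlow(f_b) + ContextGate(f_b)`, a second residual
SpectralFlow refinement, batch normalization, global average pooling, and a
linear head. Standard metrics (TPR = TP/(TP+FN), FPR = FP/(FP+TN),
precision, recall, accuracy = (TP+TN)/total, ROC/PR areas) and a
conv+linear multiply-accumulate profiler round out the toolkit.

## Worked example

Train on the built-in synthetic two-frequency task (4 classes whose identity
is split between a low-frequency blob and a high-frequency grating), then
evaluate:

```r
library(medspectralnet)

train <- synth_generate(synthetic_spec(num_classes = 4, samples_per_class = 50,
                                       image_size = 32, seed = 101))
test  <- synth_generate(synthetic_spec(num_classes = 4, samples_per_class = 25,
                                       image_size = 32, seed = 202))

fit <- medspectralnet(train, validation = test, input_size = 32,
                      epochs = 10, batch_size = 32, seed = 1)
print(fit)
#> Dual-stream frequency-decomposed classifier (SpectralFlow + ContextGate)
#>   4 classes, input 32x32, patch size k = 3
#>   parameters: 18.32 M
#>   trained 10 epochs (adam); final train acc 0.975, best test acc 1.000

ev <- evaluate(fit$model, as_image_batch(test, 32), curves = TRUE)
round(ev$accuracy, 3)
#> [1] 1
round(ev$ovr$auc, 3)
#> [1] 1 1 1 1
```

The fit reaches perfect held-out accuracy within a few epochs because the
synthetic classes are separable in both frequency bands — the point of the
check is that a randomly initialized network learns them through the full
dual-stream graph. `plot(fit)` draws the loss/accuracy curves;
`predict(fit, newdata)` returns probabilities; `gradcam(fit, image,
"spectralflow2.output", class_index)` returns a normalized heatmap over the
input.

Profiling uses the convention (convolution and linear MACs only) that
reproduces the canonical 11.7 M / 1.81 G figures for a bare ResNet-18 at
224×224:

```r
profile_model(new_resnet18(num_classes = 1000), 224)
#> Profile at input 224 x 224
#>   convention: conv+linear MACs; norm/act/pool/elementwise = 0
#>   total params: 11,689,512 (11.69 M)
#>   total MACs:   1,814,073,344 (1.81 G)
```

A command-line interface with `synth`, `train`, `eval`, `profile`, and
`explain` subcommands is installed under `inst/cli/medspectralnet-cli.R`.

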