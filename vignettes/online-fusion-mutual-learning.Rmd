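---
title: "Online fusion mutual learning for histopathology image classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Online fusion mutual learning for histopathology image classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Classifying H&E-stained breast-tissue images requires two kinds of evidence
at once: local nuclear morphology (pleomorphism, chromatin texture) and the
global arrangement of glandular structures. Convolutional networks excel at
the former and under-represent the latter; transformers the reverse. `ofml`
trains both jointly and makes them teach each other *online* — within every
mini-batch, rather than distilling from a fixed pretrained teacher.

**Branch 1** is a bottleneck residual CNN in the ResNet-50 layout
(stem 7×7/2 → max-pool → four residual stages). Besides its logits $A_1$,
it exposes three tap points for intermediate features, numbered shallow to
deep: the stem/max-pool output, the first residual stage, and the second
residual stage. Tap numbering is anchored by shape, not by naming
convention: the deepest tap is the one with per-sample shape
$(512, 28, 28)$ at 224-px input, and that is the default feature handed to
the fusion classifier.

**Branch 2** is a multi-view transformer. An image $x \in \mathbb{R}^{H
\times Z \times 3}$ is cut into $N = (H/Q)(Z/Q)$ patches of side $Q = 16$;
each flattened patch is mapped by a learned matrix $E$ to the view's width,
a learnable class token is prepended and a learnable positional embedding
added. Each of the (default three) views runs its own encoder of $L$
pre-norm blocks

$$y_\ell = \mathrm{MSA}(\mathrm{LN}(A_{\ell-1})) + A_{\ell-1}, \qquad
  A_\ell = \mathrm{MLP}(\mathrm{LN}(y_\ell)) + y_\ell,$$

with GELU between the two MLP projections. Views differ only in hidden
width (256, 384, 512 by default). Adjacent views are fused by **cross-view
attention** (CVA): queries from view $i$, keys/values from view $i+1$ after
a learned projection $Z_{proj}$ to view $i$'s width,

$$\mathrm{CVA}(x, y) = \mathrm{softmax}\!\left(\frac{Z_Q x \, (Z_K
y)^\top}{\sqrt{d_k}}\right) Z_V y .$$

*Fusion schedule.* The fusion cascades from the deepest view down:
$\tilde A^{(n)} = A^{(n)}$ and $\tilde A^{(i)} = \mathrm{CVA}(A^{(i)},
Z_{proj,i}\, \tilde A^{(i+1)})$, the final fused sequence entering a global
encoder at view 1's width whose class token feeds the classification head.
We chose the cascade (rather than fusing one fixed pair) because it applies
the same adjacent-pair rule to every view while guaranteeing that gradients
reach every view's embedding, positional and projection parameters — with a
single fused pair, the remaining views would receive no training signal at
all. The tapped transformer feature is a *view encoder's* patch tokens
(class token dropped) on their $\sqrt N \times \sqrt N$ grid; view 3 gives
the $(512, 14, 14)$ map at 224 px. The "view $k$ + CNN tap $k$" pairings
are exactly the AFC1–3 ablation variants.

## The mutual-learning objective

With softened distributions $q(T) = \mathrm{softmax}(z / T)$ and $T = 4$
throughout:

* **Ensemble classifier** $A_e = (A_1 + A_2)/2$, supervised by
  cross-entropy at $T = 1$.
* **Fusion classifier**: both tapped maps adaptively average-pooled to
  1×1, concatenated ($c_1 + c_2$ channels), then a pointwise convolution to
  $C$ logits $A_f$ — $(c_1 + c_2)C + C$ parameters, so the head adds no
  large tunable block and accepts any two spatial sizes.
* **Branch totals** $L_b = \mathrm{CE}(q_b(1), y) + T^2\,
  \mathrm{KL}(q_b(T) \,\|\, q_f(T))$ for $b = 1, 2$, the fusion classifier
  acting as a detached teacher (no gradient flows into it through these
  terms).
* **Total** $L_f = L_1 + L_2 + T^2\, \mathrm{CE}(q_e(1), y) + w_{epkt}\,
  \mathrm{KL}(q_e(T)\,\|\,q_f(T)) + w_{fce}\, \mathrm{CE}(q_f(1), y)$.

Two printed-formula ambiguities were resolved on mathematical grounds and
are worth restating. First, the cross-entropies are standard negative
log-likelihoods (a minimized loss must be non-negative). Second, the bare
three-term total leaves the fusion head without any supervised signal, so
its parameters would never train; the defaults $w_{epkt} = w_{fce} = 1$ add
the ensemble-to-fusion transfer and a fusion cross-entropy, and
`literal_total = TRUE` (or zero weights) restores the bare objective for
comparison. The $T^2$ factor on the ensemble cross-entropy is kept as
specified even though it scales a plain CE by 16 at $T = 4$.

Classification at inference time uses the fusion classifier's softmax;
branch, ensemble and fusion probabilities are all exposed by `predict()`.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| `temperature` | 4 | softening of all transfer distributions; higher = softer teachers |
| `learning_rate`, `adam_beta1` | 0.01, 0.8 | Adam step and first-moment decay ("momentum" has no single Adam analogue; β₁ is the closest) |
| `weight_decay` | 5e-4 | L2 added to gradients |
| `batch_size`, `epochs` | 64, 300 | full-scale schedule (`configs/full.yaml`) |
| `mixup$alpha`, `mixup$factor` | 0.2, 4 | Beta concentration and expansion multiple; the first copy is the untouched originals |
| `cnn$tap_stage`, `mvt$tap_layer` | 3, 3 | which intermediate features feed the fusion head |
| `w_epkt`, `w_fce` | 1, 1 | auxiliary terms training the fusion head |

Mixup partners are drawn from the whole training set by default;
`within_class = TRUE` restricts pairing to a sample's own class, which is
also the mode that preserves per-class counts exactly under expansion. The
test set is never expanded.

## The synthetic data and what passing tests mean

`generate_synthetic_dataset()` draws dark elliptical "nuclei" on a pink
eosin-like background; classes differ in blob count, radius range and stain
darkness. The defaults were calibrated once so that a pixel-mean
nearest-centroid classifier exceeds 0.9 training accuracy (it reaches 0.91
on 4×50 at 64 px) and then frozen. These images emulate the color scheme
and blob statistics of H&E tissue, but none of its real difficulty: no
stain variation, no glandular architecture, no magnification effects, no
label noise. Passing the suite therefore demonstrates that the machinery —
token calculus, mutual-learning losses, joint optimization, heads,
explanations — is correct and trainable, not that the model reaches
clinical accuracy on real slides.

The CPU-scale study configuration (`tiny_config()`) uses 4 classes × 25
images at 32 px, stem width 16 with one block per residual stage, view
widths (32, 48, 64) with one layer per view, a one-block global encoder,
2 heads, patch 8, Mixup ×4, 30 epochs, Adam at 2e-3 with batches of 16.
The reduced widths and batch are deliberate: at 100 training images a batch
of 64 yields only ~7 optimizer steps per epoch, too few for the fusion head
to converge within the 30-epoch study. Under this configuration the fusion
classifier overfits the separable classes (≥ 0.95 training accuracy) while
every loss component stays finite and non-negative.

## Numerical and implementation choices

* All gradients come from a reverse-mode tape over dense arrays; every
  structured operation (convolution via cached im2col gathers, max-pool,
  batch/layer norm, attention) is verified against central finite
  differences in the test suite.
* Inputs are standardized per channel with training-set statistics (stored
  in the model and its checkpoints) — the conventional normalization step of
  image pipelines; without it the patch-embedding branch barely trains at
  desk scale, since raw H&E-like images have channel means near 0.8.
* Softmaxes are max-stabilized; logarithms clamp their argument at 1e-12
  (a warning is emitted if a supported class is clamped in a
  cross-entropy). Batch-norm running statistics use momentum 0.1 and drive
  all evaluation-mode forwards, making repeated prediction deterministic.
* Split sizes are floored per class, which both keeps the per-class
  training fraction within one image of the target and guarantees a
  non-empty test set; labels follow lexicographic class-directory order so
  folder datasets need no manifest.
* Initialization: He for convolutions, Xavier for transformer projections
  (the cross-view attention has no residual path, so tiny initializations
  would starve the global encoder), 0.02-scaled normals for class/positional
  tokens. All randomness flows from the configuration seed; identical
  configurations reproduce identical fits.
* The 2-D feature embedding delegates to Sammon mapping (`MASS`), a
  classical nonlinear embedding that is deterministic given its
  classical-scaling initialization; exact duplicate feature vectors are
  nudged by a fixed fraction of the smallest positive distance, and fully
  constant features are rejected with an explanatory error.
* Grad-CAM heatmaps weight a tapped activation by its spatially averaged
  gradients, rectify, min–max normalize and bilinearly upsample. On the
  synthetic data the peak lands on the nucleus region for nucleus-dense
  classes; for the sparsest class the evidence is the *absence* of nuclei,
  so its heatmap legitimately peaks on clean background — the localization
  check in the tests is therefore stated over images with ≥ 5% nucleus
  coverage, with the blob mask dilated by the tap's upsampling half-stride.

## Known limitations

* No stain normalization, no whole-slide tiling, no pretrained weights, no
  GPU path: full-scale training (224 px, 300 epochs) is far outside this
  implementation's intended envelope, which is correctness and desk-scale
  experimentation.
* The tiny study demonstrates overfitting capacity, not generalization;
  held-out accuracy of a 30-epoch run on 100 images is modest by design.
* Whether the ensemble logits should additionally enter the fusion head's
  forward pass is an open reading of the architecture; here they couple
  only through the loss (the ensemble-to-fusion KL), the more conservative
  interpretation.
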