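---
title: "Methods: a shifted-window transformer over fused CNN features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a shifted-window transformer over fused CNN features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(winshift)
```

## The model

`winshift` classifies 2-D MRI slices (glioma / meningioma / pituitary and
similar multi-class layouts) with a hybrid architecture in three parts.

**Frozen ensemble features.** Several pretrained CNN backbones, run with
their classification heads removed, each emit a spatial feature map
$(S_i, S_i, C_i)$ from a $224 \times 224 \times 3$ input. Because the
spatial sides differ across architectures (7 for DenseNet201 and VGG16, 5
for InceptionV3 and InceptionResNetV2), all maps are zero-padded into the
top-left corner of a common $T \times T$ canvas ($T = 12$ by default) and
concatenated along channels. For the default three-member ensemble the
fused map is $(12, 12, 1920 + 2048 + 1536) = (12, 12, 5504)$. The backbones
are frozen: no gradient ever reaches them, and in this package their
feature maps are computed once per image and cached for the whole of
training.

**Shifted-window encoder.** The fused map receives a learned absolute
position embedding (one parameter per position per channel), is cut into
non-overlapping $p \times p$ patches ($p = 2$), each flattened to a
$p^2 C$ vector — $36$ tokens of dimension $22{,}016$ at the default sizes —
and projected by a shared affine map to the working dimension $C = 96$.
Two transformer blocks follow. Each block is

$$z' = \mathrm{WMSA}(\mathrm{LN}(z)) + z,\qquad
  z'' = \mathrm{MLP}(\mathrm{LN}(z')) + z',$$

where the attention is computed independently inside $M \times M$ token
windows ($M = 2$), and the MLP is two affine maps with a GELU between
(hidden width 24). The first block uses unshifted windows; the second
cyclically rolls the token grid by $(-M/2, -M/2)$ before windowing and
rolls back afterwards, with an additive $-10^9$ mask blocking attention
between tokens that originate from different pre-shift regions (the
standard 3-band slicing per axis). This alternation lets information cross
window boundaries while keeping the per-window cost: global attention on an
$h \times w$ token grid costs $4hwC^2 + 2(hw)^2C$ operations, windowed
attention $4hwC^2 + 2M^2hwC$ — linear rather than quadratic in $hw$ for
fixed $M$ (`complexityMsa()` / `complexityWmsa()`).

After each block a patch-merging layer concatenates every $2 \times 2$
token neighborhood ($4C$ features, row-major) and linearly reduces it to
$2C$, halving the grid. With the defaults the grid chain is
$6 \times 6 \times 96 \to 3 \times 3 \times 192 \to$ (pad)
$4 \times 4 \times 192 \to 2 \times 2 \times 384$, and the flattened 1,536
features feed the head.

**Head and loss.** Two ReLU dense layers (256 units, dropout 0.5; 96
units, dropout 0.1) and a softmax output trained with categorical
cross-entropy.

## Training protocol

Adam at learning rate $10^{-4}$ with per-element gradient clipping at 0.2,
up to 100 epochs with minibatches of 16. Validation loss drives both
schedules: reduce-on-plateau multiplies the learning rate by 0.2 when no
improvement beyond $10^{-5}$ is seen for 7 epochs, and early stopping ends
the run after 10 such epochs, restoring the best-validation weights.
Dropout and drop-path (stochastic depth on both residual branches, shared
per sample between the spatial and class-token streams) are active only in
training mode; two evaluation-mode passes are bit-identical.

The tuned regularization rates — MLP dropout 0.2995, attention dropout
0.7605, block-end dropout 0.5855, drop-path 0.4789, with 4 heads,
$C = 96$, 24 MLP nodes — are returned verbatim by
`tunedHyperparameters()` and are the package defaults.

## Hyperparameter search

`runStudy()` implements a Tree-structured Parzen Estimator: after a random
warmup, completed trials are split at the top quantile ($\gamma = 0.25$)
into good and bad sets, and each dimension proposes the candidate
maximizing the ratio of good to bad densities (Gaussian kernels with a
Silverman-style bandwidth floor for continuous dimensions; Laplace-smoothed
frequencies for categorical ones). No Bayesian-optimization package exists
in this R stack, so the sampler is implemented here and validated against
a grid-search oracle on a known quadratic objective and against the median
of equal-budget random search. The default search space brackets every
tuned value; every candidate embedding dimension is divisible by every
candidate head count so all sampled configurations are constructible. The
objective at desk scale is validation accuracy of a truncated training run
(a handful of epochs), which ranks configurations well enough for the
sanity checks; whether the original study used full or truncated runs is
not stated, and the choice only affects wall-clock cost here.

## Design decisions in detail

Several aspects of the architecture are stated only loosely by its
description; the package fixes them as follows.

* **Readout.** The operative default flattens all final tokens into the
  head (matching the published layer dimensions). A class-token variant
  (`readout = "cls"`) is available: the token is appended after the linear
  embedding, passes through every block via a singleton attention window
  and the shared MLP, is linearly lifted $C \to 2C$ at each merge to track
  the widening channels, and is read out through a parameter-free layer
  norm. It is a config option, not the default, because only the flatten
  path is consistent with the published head sizes.
* **Padding.** Grids whose sides are not divisible by the window (or by 2
  at a merge) are zero-padded bottom/right; padded tokens then behave as
  ordinary tokens. This is the minimal literal reading of "merge after
  every block" for the $3 \times 3$ intermediate grid.
* **Mask constant and regions.** $-10^9$ added pre-softmax; region ids from
  the standard 3-band slicing on the shifted grid. Verified against a dense
  masked-attention brute force on every grid up to $8 \times 8$.
* **No relative position bias** inside attention: position information
  enters once, through the absolute embedding before partition.
* **Dropout placement.** "After attention" is applied to the attention
  probabilities; "end of block" after the output projection; "after each
  MLP layer" after both dense layers of the MLP.
* **Initialization.** Truncated normal (sd 0.02, clipped at 2 sd) for all
  projections, zeros for biases, ones for layer-norm gains, under a fixed
  seed.
* **Clip value.** Interpreted as per-element gradient value clipping (the
  common meaning in Keras-style APIs), not norm clipping.
* **Splitting.** 80/10/10 with global sizes
  $\lfloor 0.8n\rfloor/\lfloor 0.1n\rfloor/\text{rest}$, allocated per
  class by largest remainder, so the split is stratified to within one
  image per class while hitting the global sizes exactly (3,064 images
  split 2,451/306/307).
* **Crop.** Otsu threshold, morphological opening, largest connected
  component, bounding box with a 5-px margin. Cropping precedes resizing
  for every split; augmentation (shift $\le 10\%$, shear $\le 10^\circ$,
  zoom $[0.9, 1.1]$, horizontal flip) applies to the training split only.
  Magnitudes are conservative, label-preserving choices; none are given by
  the source protocol.
* **Resize.** Bilinear, as in common image stacks; scaling by $1/255$ is
  skipped for inputs already in $[0,1]$, making the operation idempotent.

## The synthetic test bed

`generateSyntheticDataset()` emulates the class structure of the real
task at desk scale: each image is one bright axis-aligned ellipse on a
noisy dark background, with class identity carried by the blob's radius
band and intensity (defaults: radii 10–16 / 20–28 / 32–42 px, intensities
0.55 / 0.75 / 0.95, Gaussian pixel noise sd 0.05). At zero noise the
classes are separable by a nearest-centroid rule on mean intensity, which
anchors the end-to-end expectation: a pipeline trained on 300 such images
(240/30/30 split) should exceed 90% held-out accuracy. Raising `noiseSd`
degrades that separability monotonically, giving a one-knob difficulty
dial. The generator does not attempt MRI physics — no bias fields,
partial-volume effects, anatomy, or 3-D structure — so passing tests
demonstrate that the architecture, gradients and training loop work, not
that the model transfers to clinical data.

The companion `tinyBackbone()` stands in for the pretrained extractors: a
frozen, fixed-seed, bias-free stack of strided convolutions (bilinear
pooling to an $8S$ grid, an $8 \times 8$-stride patch convolution, a
$1 \times 1$ convolution, ReLUs). The first filter of each stage is a box
(mean-brightness) kernel and the rest are random, so low-frequency
intensity structure — the signal the synthetic classes are built on —
survives the frozen bank the way luminance features survive real
pretrained CNNs. With no biases, an all-zero input yields an all-zero
feature map. Declared output shapes are enforced exactly, for any
grid side (7, 5, ...).

## Numerical choices and scale

All kernels are plain BLAS matrix operations; the backward pass is
hand-written per layer and verified against central finite differences
(tolerance $10^{-4}$ on gradients of every layer family, both readouts).
Layer norm uses $\varepsilon = 10^{-5}$; softmax subtracts the row max;
the cross-entropy adds $10^{-12}$ inside the log. Problem sizes in the
tests and the acceptance script are desk-scale by design: two tiny
backbones (7×7×8 and 5×5×8) fused on an 8×8 canvas, 16 tokens, the
published block configuration, 300 synthetic images — a full training run
takes a few CPU minutes. The full-size $12 \times 12 \times 5504$ chain is
exercised for its dimensions and a forward pass, not trained.

## Known limitations

* Real pretrained backbones are not bundled; `referenceBackbones()` carries
  their declared shapes only, so published full-dataset accuracies are out
  of reach here by construction.
* The published ensemble output shape is internally inconsistent between
  two of its printed tables; the package follows the dimension chain that
  is self-consistent (target side 12, 5,504 fused channels) and ignores the
  other figure.
* Training determinism is exact under a fixed seed on a given BLAS; across
  BLAS implementations bit-level results may differ.
* Parameter counts of the published per-model classification heads are not
  reproducible (their composition is unpublished) and are treated as
  diagnostics only.
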