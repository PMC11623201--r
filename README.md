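# winshift

Multi-class brain-tumor classification from 2-D MRI slices with a hybrid
architecture: an ensemble of **frozen CNN backbones** whose feature maps are
zero-padded to a common grid and concatenated along channels, a compact
**shifted-window (Swin-style) transformer encoder**, and a dense softmax
head, trained end-to-end. The package is aimed at researchers who want a
fully inspectable, CPU-scale reference implementation of this pipeline —
every numerical kernel (windowed multi-head attention with cyclic shifts
and masks, patch partition/merging, layer norm, the backward pass, Adam,
the TPE hyperparameter sampler) is plain, tested R.

## The model

Each backbone emits a spatial feature map `(S_i, S_i, C_i)`; maps are
zero-padded to a `T x T` canvas (default `T = 12`) and concatenated, e.g.
`1920 + 2048 + 1536 = 5504` fused channels for the default three-member
ensemble. After a learned absolute position embedding, the map is cut into
`p x p = 2 x 2` patches — 36 tokens of dimension 22,016 — and projected to
the working dimension `C = 96`. Two transformer blocks follow, each

    z'  = W-MSA(LN(z)) + z
    z'' = MLP(LN(z')) + z'

with attention restricted to `M x M = 2 x 2` token windows; the second
block shifts the window grid by `M/2` via a cyclic roll plus an additive
mask, so information crosses window boundaries on alternate blocks. Global
attention on an `h x w` grid costs `4hwC^2 + 2(hw)^2 C` operations;
windowed attention costs `4hwC^2 + 2M^2 hwC` — linear instead of quadratic
in `hw`. A patch-merging layer after each block concatenates `2 x 2` token
neighborhoods and halves the grid. The flattened final tokens feed a
256-ReLU / 96-ReLU / softmax head trained with categorical cross-entropy
(Adam, lr 1e-4, gradient value clipping 0.2, reduce-on-plateau x0.2,
early stopping with best-weight restore).

Pretrained backbones are not bundled: `referenceBackbones()` carries their
declared output shapes for dimension bookkeeping, and `tinyBackbone()`
provides frozen, fixed-seed strided-convolution extractors so the whole
pipeline runs and trains on CPU. A synthetic-image generator
(`generateSyntheticDataset()`) produces labelled blob-on-noise images with
a controllable difficulty dial.

## Worked example

Train the default pipeline on 300 synthetic three-class images (100 per
class, low noise), with two tiny frozen backbones fused on an 8 x 8 canvas
and the published encoder configuration:

```r
library(winshift)

ds    <- generateSyntheticDataset(syntheticSpec(nPerClass = 100, noiseSd = 0.05, seed = 1))
proc  <- preprocessImageSet(ds, crop = FALSE)
parts <- splitImageSet(proc, splitSpec(seed = 1))   # 240 / 30 / 30

ens   <- ensembleSpec(list(tinyBackbone(7, 8, seed = 7),
                           tinyBackbone(5, 8, seed = 8)), targetSpatial = 8)
tuned <- tunedHyperparameters()
model <- buildModel(ens, tuned$block, tuned$head, nClasses = 3,
                    classes = levels(labels(ds)), seed = 42)
model
#> WinShiftModel: 3-class, 2 frozen backbones, 2 encoder blocks, readout 'flatten'
#>   trainable parameters: 700787; trained epochs: 0

model <- trainModel(model, parts$train, parts$validation,
                    opt = optimizerConfig(), seed = 1)
tail(trainingHistory(model), 1)
#>    epoch trainLoss trainAcc   valLoss    valAcc    lr
#> 68    68 0.3271558   0.8875 0.2611470 0.8333333 2e-05
```

Early stopping ended the run at epoch 68 (best-validation weights
restored; the learning-rate trace shows one plateau reduction,
1e-4 -> 2e-5). Evaluating on the untouched unseen split:

```r
pr <- predict(model, parts$unseen)
cm <- confusion(as.character(labels(parts$unseen)), as.character(pr$labels),
                classes = model@classes)
cm
#> ConfusionMatrix (rows = true, cols = predicted):
#>        class1 class2 class3
#> class1     10      0      0
#> class2      1      9      0
#> class3      0      2      8

classificationReport(cm)$accuracy
#> [1] 0.9
rocAuc(as.integer(labels(parts$unseen)), pr$probabilities,
       classes = model@classes)$auc
#> class1 class2 class3
#>  0.995  0.975  1.000
```

90% held-out accuracy and per-class AUCs near 1: the three blob classes
are recovered almost perfectly from frozen random features plus the
trained encoder/head. `gradCam(model, images(proc)[[i]])` returns a
`[0, 1]` heatmap whose peak sits on the class-discriminative blob.

## Command line

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/winshift.R simulate --out data --n-per-class 100 --seed 1
Rscript inst/cli/winshift.R train    --data data --out run --seed 1
Rscript inst/cli/winshift.R tune     --trials 40 --out tune --seed 1
Rscript inst/cli/winshift.R evaluate --data data --model run/model.rds --out eval
```

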