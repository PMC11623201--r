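#' @import methods
NULL

# ---------------------------------------------------------------------------
# ImageSet: an in-memory labelled image collection
# ---------------------------------------------------------------------------

#' Labelled image collection
#'
#' Holds a list of image arrays (H x W or H x W x 3, values in [0, 255] for
#' raw images or [0, 1] for processed ones) together with their class labels
#' and optional per-image metadata (for synthetic images, the generating blob
#' geometry).
#'
#' @slot images list of numeric arrays.
#' @slot labels factor of class labels, one per image.
#' @slot meta data.frame of per-image metadata (may have zero columns).
#' @exportClass ImageSet
setClass("ImageSet",
  representation(images = "list", labels = "factor", meta = "data.frame"),
  validity = function(object) {
    if (length(object@images) != length(object@labels))
      return("number of images and labels differ")
    if (nrow(object@meta) > 0 && nrow(object@meta) != length(object@images))
      return("meta rows must match number of images")
    TRUE
  }
)

#' Construct an ImageSet
#' @param images list of numeric arrays.
#' @param labels factor or character vector of class labels.
#' @param meta optional data.frame of per-image metadata.
#' @return An [ImageSet-class] object.
#' @export
ImageSet <- function(images, labels, meta = data.frame()) {
  new("ImageSet", images = images, labels = as.factor(labels), meta = meta)
}

#' @describeIn ImageSet number of images
#' @param x an ImageSet.
#' @export
setMethod("length", "ImageSet", function(x) length(x@images))

#' Accessors for ImageSet
#' @param x an ImageSet.
#' @return `images()` the list of arrays; `labels()` the label factor;
#'   `imageMeta()` the metadata data.frame.
#' @export
images <- function(x) x@images

#' @rdname images
#' @export
setGeneric("labels")

#' @rdname images
#' @export
setMethod("labels", "ImageSet", function(object, ...) object@labels)

#' @rdname images
#' @export
imageMeta <- function(x) x@meta

#' Subset an ImageSet
#' @param x an ImageSet.
#' @param i integer or logical index.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "ImageSet", function(x, i, j, ..., drop = FALSE) {
  meta <- if (nrow(x@meta)) x@meta[i, , drop = FALSE] else x@meta
  new("ImageSet", images = x@images[i], labels = droplevels(x@labels[i]) ,
      meta = meta)
})

setMethod("show", "ImageSet", function(object) {
  d <- if (length(object)) paste(dim(object@images[[1]]), collapse = "x") else "?"
  cat("ImageSet with", length(object), "images (first:", d, ")\n")
  print(table(object@labels))
})

# ---------------------------------------------------------------------------
# Backbone / ensemble configuration
# ---------------------------------------------------------------------------

#' Frozen feature-extraction backbone
#'
#' Describes one frozen convolutional backbone by its declared output shape
#' (spatial side and channel count of the last convolutional feature map).
#' A backbone with non-empty `weights` is a runnable tiny backbone (see
#' [tinyBackbone()]); reference backbones carry only declared shapes.
#'
#' @slot name backbone identifier.
#' @slot outSpatial spatial side of the output feature map.
#' @slot outChannels channel count of the output feature map.
#' @slot frozen always TRUE: the backbone is never trained.
#' @slot weights list of weight matrices (empty for declared-shape-only specs).
#' @exportClass BackboneSpec
setClass("BackboneSpec",
  representation(name = "character", outSpatial = "integer",
                 outChannels = "integer", frozen = "logical",
                 weights = "list"),
  validity = function(object) {
    if (object@outSpatial < 1L || object@outChannels < 1L)
      return("output spatial side and channel count must be positive")
    if (!isTRUE(object@frozen)) return("backbones are always frozen")
    TRUE
  }
)

#' Construct a BackboneSpec
#' @param name identifier.
#' @param outSpatial,outChannels declared output feature-map shape.
#' @param weights optional list of weights making the spec runnable.
#' @return A [BackboneSpec-class].
#' @export
backboneSpec <- function(name, outSpatial, outChannels, weights = list()) {
  new("BackboneSpec", name = name, outSpatial = as.integer(outSpatial),
      outChannels = as.integer(outChannels), frozen = TRUE, weights = weights)
}

setMethod("show", "BackboneSpec", function(object) {
  cat(sprintf("BackboneSpec '%s': output (%d, %d, %d), frozen%s\n",
              object@name, object@outSpatial, object@outSpatial,
              object@outChannels,
              if (length(object@weights)) ", runnable" else ""))
})

#' Ensemble of frozen backbones
#'
#' @slot members list of [BackboneSpec-class] objects.
#' @slot targetSpatial common spatial side that all member feature maps are
#'   zero-padded to before channel concatenation.
#' @exportClass EnsembleSpec
setClass("EnsembleSpec",
  representation(members = "list", targetSpatial = "integer"),
  validity = function(object) {
    if (length(object@members) < 1L) return("ensemble needs >= 1 member")
    if (!all(vapply(object@members, is, logical(1), class2 = "BackboneSpec")))
      return("members must be BackboneSpec objects")
    sides <- vapply(object@members, function(b) b@outSpatial, integer(1))
    if (any(sides > object@targetSpatial))
      return("a member's spatial side exceeds targetSpatial")
    TRUE
  }
)

#' Construct an EnsembleSpec
#' @param members list of [BackboneSpec-class].
#' @param targetSpatial common padded spatial side (default 12, the value
#'   that makes the published dimension chain come out).
#' @return An [EnsembleSpec-class].
#' @export
ensembleSpec <- function(members, targetSpatial = 12L) {
  new("EnsembleSpec", members = members, targetSpatial = as.integer(targetSpatial))
}

#' @rdname ensembleSpec
#' @param x an EnsembleSpec.
#' @export
fusedChannels <- function(x) {
  sum(vapply(x@members, function(b) b@outChannels, integer(1)))
}

setMethod("show", "EnsembleSpec", function(object) {
  cat(sprintf("EnsembleSpec: %d members, target spatial %d, fused channels %d\n",
              length(object@members), object@targetSpatial, fusedChannels(object)))
  for (m in object@members) show(m)
})

# ---------------------------------------------------------------------------
# Encoder block configuration
# ---------------------------------------------------------------------------

#' Shifted-window transformer block configuration
#'
#' @slot window window side M in tokens.
#' @slot shift cyclic shift in tokens (0 for W-MSA, M/2 for SW-MSA).
#' @slot heads number of attention heads.
#' @slot embedDim working embedding dimension C.
#' @slot mlpNodes hidden width of the 2-layer GELU MLP.
#' @slot dropoutMlp dropout rate after each MLP dense layer.
#' @slot dropoutAttn dropout rate on the attention probabilities.
#' @slot dropoutBlock dropout rate at the end of the attention module.
#' @slot dropPath stochastic-depth rate on both residual branches.
#' @exportClass SwinBlockConfig
setClass("SwinBlockConfig",
  representation(window = "integer", shift = "integer", heads = "integer",
                 embedDim = "integer", mlpNodes = "integer",
                 dropoutMlp = "numeric", dropoutAttn = "numeric",
                 dropoutBlock = "numeric", dropPath = "numeric"),
  validity = function(object) {
    if (object@shift < 0L || object@shift >= object@window)
      return("shift must satisfy 0 <= shift < window")
    if (object@embedDim %% object@heads != 0L)
      return("embedDim must be divisible by heads")
    r <- c(object@dropoutMlp, object@dropoutAttn, object@dropoutBlock, object@dropPath)
    if (any(r < 0) || any(r > 1)) return("all rates must be in [0, 1]")
    TRUE
  }
)

#' Construct a SwinBlockConfig
#'
#' Defaults follow the published tuned configuration: window 2, 4 heads,
#' embedding dimension 96, MLP width 24, and the tuned dropout/drop-path
#' rates (see [tunedHyperparameters()]).
#'
#' @param window window side M (tokens).
#' @param shift cyclic shift, 0 or window/2.
#' @param heads attention heads.
#' @param embedDim embedding dimension C.
#' @param mlpNodes MLP hidden width.
#' @param dropoutMlp,dropoutAttn,dropoutBlock,dropPath regularization rates.
#' @return A [SwinBlockConfig-class].
#' @export
swinBlockConfig <- function(window = 2L, shift = 0L, heads = 4L,
                            embedDim = 96L, mlpNodes = 24L,
                            dropoutMlp = 0.2995, dropoutAttn = 0.7605,
                            dropoutBlock = 0.5855, dropPath = 0.4789) {
  new("SwinBlockConfig", window = as.integer(window), shift = as.integer(shift),
      heads = as.integer(heads), embedDim = as.integer(embedDim),
      mlpNodes = as.integer(mlpNodes), dropoutMlp = dropoutMlp,
      dropoutAttn = dropoutAttn, dropoutBlock = dropoutBlock,
      dropPath = dropPath)
}

setMethod("show", "SwinBlockConfig", function(object) {
  cat(sprintf(paste0("SwinBlockConfig: M=%d shift=%d heads=%d C=%d mlp=%d ",
                     "drop(mlp/attn/block/path)=%.4g/%.4g/%.4g/%.4g\n"),
              object@window, object@shift, object@heads, object@embedDim,
              object@mlpNodes, object@dropoutMlp, object@dropoutAttn,
              object@dropoutBlock, object@dropPath))
})

# ---------------------------------------------------------------------------
# Training configuration
# ---------------------------------------------------------------------------

#' Classification head configuration
#'
#' Two ReLU dense layers with dropout, then a softmax output layer.
#' Defaults are the published head: 256 units / dropout 0.5, 96 units /
#' dropout 0.1.
#'
#' @param units1,units2 dense layer widths.
#' @param dropout1,dropout2 dropout rates after each dense layer.
#' @return A list of class "headConfig".
#' @export
headConfig <- function(units1 = 256L, units2 = 96L,
                       dropout1 = 0.5, dropout2 = 0.1) {
  stopIf(dropout1 < 0 || dropout1 > 1 || dropout2 < 0 || dropout2 > 1,
         "dropout rates must be in [0, 1]")
  structure(list(units1 = as.integer(units1), units2 = as.integer(units2),
                 dropout1 = dropout1, dropout2 = dropout2),
            class = c("headConfig", "list"))
}

setOldClass(c("headConfig", "list"))
setOldClass(c("optimizerConfig", "list"))
setOldClass(c("scheduleConfig", "list"))

#' Optimizer configuration
#'
#' Adam with per-element gradient value clipping, as in the published
#' training protocol (learning rate 1e-4, clip value 0.2, 100 epochs).
#'
#' @param learningRate initial Adam learning rate.
#' @param clipValue per-element gradient clipping bound (0 disables).
#' @param epochs maximum number of epochs.
#' @param batchSize minibatch size.
#' @return A list of class "optimizerConfig".
#' @export
optimizerConfig <- function(learningRate = 1e-4, clipValue = 0.2,
                            epochs = 100L, batchSize = 16L) {
  stopIf(learningRate <= 0, "learningRate must be positive")
  structure(list(learningRate = learningRate, clipValue = clipValue,
                 epochs = as.integer(epochs), batchSize = as.integer(batchSize)),
            class = c("optimizerConfig", "list"))
}

#' Learning-rate schedule and early-stopping configuration
#'
#' Reduce-on-plateau (factor 0.2, epsilon 1e-5, patience 7) and early
#' stopping (patience 10, best-validation weights restored), both keyed on
#' validation loss.
#'
#' @param plateauFactor multiplicative LR reduction on plateau.
#' @param plateauEpsilon minimum improvement that resets the plateau counter.
#' @param plateauPatience epochs without improvement before reducing LR.
#' @param earlyStopPatience epochs without improvement before stopping.
#' @return A list of class "scheduleConfig".
#' @export
scheduleConfig <- function(plateauFactor = 0.2, plateauEpsilon = 1e-5,
                           plateauPatience = 7L, earlyStopPatience = 10L) {
  stopIf(plateauFactor <= 0 || plateauFactor >= 1,
         "plateauFactor must be in (0, 1)")
  structure(list(plateauFactor = plateauFactor, plateauEpsilon = plateauEpsilon,
                 plateauPatience = as.integer(plateauPatience),
                 earlyStopPatience = as.integer(earlyStopPatience)),
            class = c("scheduleConfig", "list"))
}

# ---------------------------------------------------------------------------
# The model object
# ---------------------------------------------------------------------------

#' Hybrid shifted-window transformer classifier
#'
#' The full model: a frozen backbone ensemble whose fused feature map feeds
#' a position-embedded, patch-partitioned shifted-window transformer encoder
#' and a dense softmax head. Trainable parameters live in `params`; the
#' backbone weights inside `ensemble` are frozen by construction and never
#' updated.
#'
#' @slot ensemble an [EnsembleSpec-class] of runnable backbones.
#' @slot blocks list of [SwinBlockConfig-class], one per encoder block.
#' @slot patchSize patch side p used by the patch-partition layer.
#' @slot head a [headConfig()] list.
#' @slot nClasses number of output classes.
#' @slot classes class labels, in output-unit order.
#' @slot readout "flatten" (all tokens into the head) or "cls" (class token).
#' @slot params named list of trainable arrays.
#' @slot layout internal precomputed index structures per encoder stage.
#' @slot history data.frame of per-epoch training metrics (empty before
#'   training).
#' @exportClass WinShiftModel
setClass("WinShiftModel",
  representation(ensemble = "EnsembleSpec", blocks = "list",
                 patchSize = "integer", head = "list", nClasses = "integer",
                 classes = "character", readout = "character",
                 params = "list", layout = "list", history = "data.frame"),
  validity = function(object) {
    if (object@nClasses < 2L) return("need at least 2 classes")
    if (!object@readout %in% c("flatten", "cls"))
      return("readout must be 'flatten' or 'cls'")
    TRUE
  }
)

setMethod("show", "WinShiftModel", function(object) {
  np <- sum(vapply(object@params, length, integer(1)))
  cat(sprintf(paste0("WinShiftModel: %d-class, %d frozen backbones, ",
                     "%d encoder blocks, readout '%s'\n"),
              object@nClasses, length(object@ensemble@members),
              length(object@blocks), object@readout))
  cat(sprintf("  trainable parameters: %d; trained epochs: %d\n",
              np, nrow(object@history)))
})

#' Training history of a model
#' @param model a [WinShiftModel-class].
#' @return data.frame with per-epoch train/validation loss and accuracy and
#'   the learning-rate trace.
#' @export
trainingHistory <- function(model) model@history

#' Confusion matrix with one-vs-rest per-class counts
#'
#' @slot counts K x K integer matrix, rows = true class, cols = predicted.
#' @slot classes class labels.
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix",
  representation(counts = "matrix", classes = "character"),
  validity = function(object) {
    if (nrow(object@counts) != ncol(object@counts))
      return("counts must be square")
    if (any(object@counts < 0)) return("counts must be non-negative")
    if (length(object@classes) != nrow(object@counts))
      return("classes length must match matrix size")
    TRUE
  }
)

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (rows = true, cols = predicted):\n")
  m <- object@counts
  dimnames(m) <- list(object@classes, object@classes)
  print(m)
})
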