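# Synthetic labelled images and a tiny deterministic backbone, so the whole
# pipeline runs on CPU with no downloads and no pretrained weights.

#' Synthetic dataset specification
#'
#' Describes a set of labelled images with one bright elliptical blob per
#' image on a noisy dark background, mimicking the tumor/background contrast
#' of T1-weighted MRI slices. Classes differ by blob radius band and blob
#' intensity, so a simple intensity-based classifier separates them when the
#' noise is low; raising `noiseSd` degrades separability monotonically.
#'
#' Default class signatures (3 classes): radii 10-16 / 20-28 / 32-42 px and
#' intensities 0.55 / 0.75 / 0.95, which keep the per-class mean-intensity
#' distributions disjoint at zero noise.
#'
#' @param nPerClass images per class.
#' @param nClasses 2 or 3 classes.
#' @param imageSize square image side in pixels (default 224).
#' @param blobRadiusRange list of length-2 numeric ranges, one per class.
#' @param blobIntensity numeric vector in [0, 1], one per class.
#' @param noiseSd Gaussian pixel-noise standard deviation (intensity units).
#' @param seed RNG seed; the generated set is a pure function of the spec.
#' @param classNames optional class labels.
#' @return A list of class "syntheticSpec".
#' @export
syntheticSpec <- function(nPerClass, nClasses = 3L, imageSize = 224L,
                          blobRadiusRange = NULL, blobIntensity = NULL,
                          noiseSd = 0.05, seed = 1L, classNames = NULL) {
  nClasses <- as.integer(nClasses)
  stopIf(!nClasses %in% c(2L, 3L), "nClasses must be 2 or 3")
  stopIf(nPerClass < 1L, "nPerClass must be >= 1")
  stopIf(imageSize < 32L, "imageSize must be >= 32")
  stopIf(noiseSd < 0, "noiseSd must be non-negative")
  if (is.null(blobRadiusRange))
    blobRadiusRange <- list(c(10, 16), c(20, 28), c(32, 42))[seq_len(nClasses)]
  if (is.null(blobIntensity))
    blobIntensity <- c(0.55, 0.75, 0.95)[seq_len(nClasses)]
  stopIf(length(blobRadiusRange) != nClasses || length(blobIntensity) != nClasses,
         "blob parameters must have one entry per class")
  maxr <- max(vapply(blobRadiusRange, max, numeric(1)))
  stopIf(2 * (maxr + 5) >= imageSize,
         "largest blob radius does not fit the image with its margin")
  if (is.null(classNames)) classNames <- paste0("class", seq_len(nClasses))
  structure(list(nPerClass = as.integer(nPerClass), nClasses = nClasses,
                 imageSize = as.integer(imageSize),
                 blobRadiusRange = blobRadiusRange,
                 blobIntensity = blobIntensity, noiseSd = noiseSd,
                 seed = as.integer(seed), classNames = classNames),
            class = "syntheticSpec")
}

#' Generate a synthetic labelled image set
#'
#' Each image is a dark background with clipped Gaussian noise and a single
#' axis-aligned ellipse whose radii and intensity are drawn from its class
#' band; the center is uniform within a margin so the blob never crosses the
#' border. Pixels are integer-valued in [0, 255]. Generation is bitwise
#' reproducible for a fixed spec (including its seed).
#'
#' @param spec a [syntheticSpec()].
#' @return An [ImageSet-class] with `nPerClass * nClasses` images; per-image
#'   blob geometry (center, radii, intensity) is kept in `imageMeta()`.
#' @export
generateSyntheticDataset <- function(spec) {
  stopIf(!inherits(spec, "syntheticSpec"), "spec must be a syntheticSpec")
  n <- spec$nPerClass * spec$nClasses
  sz <- spec$imageSize
  withSeed(spec$seed, {
    imgs <- vector("list", n)
    labs <- character(n)
    meta <- data.frame(centerRow = numeric(n), centerCol = numeric(n),
                       radiusRow = numeric(n), radiusCol = numeric(n),
                       intensity = numeric(n))
    rowg <- matrix(seq_len(sz), sz, sz)
    colg <- matrix(seq_len(sz), sz, sz, byrow = TRUE)
    k <- 0L
    for (cls in seq_len(spec$nClasses)) {
      rng <- spec$blobRadiusRange[[cls]]
      for (i in seq_len(spec$nPerClass)) {
        k <- k + 1L
        r1 <- stats::runif(1, rng[1], rng[2])
        r2 <- stats::runif(1, rng[1], rng[2])
        margin <- max(r1, r2) + 5
        cr <- stats::runif(1, margin, sz - margin)
        cc <- stats::runif(1, margin, sz - margin)
        img <- matrix(0, sz, sz)
        if (spec$noiseSd > 0)
          img <- img + matrix(stats::rnorm(sz * sz, 0, spec$noiseSd), sz, sz)
        inside <- ((rowg - cr) / r1)^2 + ((colg - cc) / r2)^2 <= 1
        img[inside] <- spec$blobIntensity[cls] +
          if (spec$noiseSd > 0) stats::rnorm(sum(inside), 0, spec$noiseSd) else 0
        img <- pmin(pmax(img, 0), 1)
        imgs[[k]] <- round(img * 255)
        labs[k] <- spec$classNames[cls]
        meta[k, ] <- c(cr, cc, r1, r2, spec$blobIntensity[cls])
      }
    }
    ImageSet(imgs, factor(labs, levels = spec$classNames), meta)
  })
}

#' Write an ImageSet to disk as one-folder-per-class PNGs
#'
#' Writes `<root>/<class>/img_####.png` plus a `manifest.csv` with columns
#' path, label, split (split is empty unless provided).
#'
#' @param set an [ImageSet-class].
#' @param root output directory (created if absent).
#' @param split optional character vector of split names per image.
#' @return Invisibly, the manifest data.frame.
#' @export
writeImageSet <- function(set, root, split = NULL) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  labs <- as.character(labels(set))
  paths <- character(length(set))
  counter <- integer(0)
  for (i in seq_along(set@images)) {
    cls <- labs[i]
    dir.create(file.path(root, cls), showWarnings = FALSE)
    counter[cls] <- if (is.na(counter[cls])) 1L else counter[cls] + 1L
    paths[i] <- file.path(root, cls, sprintf("img_%04d.png", counter[cls]))
    img <- set@images[[i]]
    png::writePNG(img / 255, paths[i])  # png arrays are [row, col], as ours
  }
  manifest <- data.frame(path = paths, label = labs,
                         split = if (is.null(split)) "" else split,
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(root, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read an image file as a raw [0, 255] array
#'
#' PNG is read with the png package; other formats fall back to
#' EBImage::readImage. Color images come back as H x W x 3, grayscale as
#' H x W, with rows indexing the vertical axis.
#'
#' @param path image file path.
#' @return numeric array in [0, 255].
#' @export
readImageFile <- function(path) {
  a <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    EBImage::imageData(EBImage::readImage(path))
  }
  if (length(dim(a)) == 3 && dim(a)[3] == 4) a <- a[, , 1:3]  # drop alpha
  if (!grepl("\\.png$", path, ignore.case = TRUE)) {
    # EBImage arrays are [x, y]; ours are [row, col] with row vertical
    a <- if (length(dim(a)) == 3) aperm(a, c(2, 1, 3)) else t(a)
  }
  a * 255
}

# ---------------------------------------------------------------------------
# Tiny deterministic backbone
# ---------------------------------------------------------------------------

#' Create a tiny frozen backbone
#'
#' A fixed-seed, bias-free stack of strided convolutions at desk scale: the
#' 224 x 224 x 3 input is bilinearly pooled to an `8 * outSpatial` grid, cut
#' into non-overlapping 8 x 8 patches (a strided convolution), and passed
#' through two bias-free linear maps with ReLU between and after. Weights
#' are drawn once from `seed` and frozen; the backbone is never trained.
#' With no biases, an all-zero input maps to an all-zero feature map.
#'
#' @param outSpatial output grid side (e.g. 7 or 5).
#' @param outChannels output channel count.
#' @param hidden hidden width of the first convolution (default 16).
#' @param seed weight seed.
#' @param name identifier.
#' @return A runnable [BackboneSpec-class] with declared output
#'   `(outSpatial, outSpatial, outChannels)`.
#' @export
tinyBackbone <- function(outSpatial, outChannels, hidden = 16L, seed = 7L,
                         name = sprintf("tiny%dx%dx%d", outSpatial, outSpatial,
                                        outChannels)) {
  k <- 8L
  withSeed(seed, {
    w1 <- matrix(stats::rnorm(k * k * 3 * hidden, 0, 1 / sqrt(k * k * 3)),
                 k * k * 3, hidden)
    # first filter is a box (mean-brightness) kernel so low-frequency
    # intensity structure survives the frozen random bank
    w1[, 1] <- 1 / (k * k * 3)
    w2 <- matrix(stats::rnorm(hidden * outChannels, 0, 1 / sqrt(hidden)),
                 hidden, outChannels)
    w2[, 1] <- c(1, rep(0, hidden - 1L))
    backboneSpec(name, outSpatial, outChannels,
                 weights = list(w1 = w1, w2 = w2, pool = k))
  })
}

#' Reference backbone shapes of the published ensembles
#'
#' Declared last-convolutional-layer output shapes of the pretrained
#' extractors used by the two ensembles: DenseNet201 (7,7,1920), GoogleNet /
#' InceptionV3 (5,5,2048), InceptionResNetV2 (5,5,1536), VGG16 (7,7,512).
#' These specs carry shapes only; they are not runnable here (no pretrained
#' weights), but they drive the dimension bookkeeping of the fusion stage.
#'
#' @return Named list of [BackboneSpec-class] objects.
#' @export
referenceBackbones <- function() {
  list(densenet201     = backboneSpec("densenet201", 7L, 1920L),
       googlenet       = backboneSpec("googlenet", 5L, 2048L),
       inceptionresnetv2 = backboneSpec("inceptionresnetv2", 5L, 1536L),
       vgg16           = backboneSpec("vgg16", 7L, 512L))
}

#' Ensemble A composition (declared shapes)
#'
#' DenseNet201 + GoogleNet(InceptionV3) + InceptionResNetV2 with the default
#' target spatial side 12, giving 1920 + 2048 + 1536 = 5504 fused channels.
#' @return An [EnsembleSpec-class].
#' @export
ensembleA <- function() {
  b <- referenceBackbones()
  ensembleSpec(list(b$densenet201, b$googlenet, b$inceptionresnetv2))
}
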