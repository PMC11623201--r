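# Data preparation: brain-region cropping, resize to 224x224 with 1/255
# scaling, stratified 80/10/10 splitting, and label-preserving augmentation.

#' Crop the brain region from an MRI slice
#'
#' Otsu threshold on the grayscale intensity, morphological opening to drop
#' speckle, connected-component labelling, then the tight bounding box of
#' the largest foreground component, expanded by a margin and clipped to the
#' image. A blank image (no foreground after opening) is returned unchanged
#' with a warning.
#'
#' @param image numeric array H x W or H x W x 3, values in [0, 255].
#' @param margin bounding-box margin in pixels (default 5).
#' @return the cropped array (same channel structure as the input).
#' @export
cropBrainRegion <- function(image, margin = 5L) {
  d <- dim(image)
  stopIf(d[1] < 32 || d[2] < 32, "image sides must be >= 32")
  gray <- if (length(d) == 3) apply(image, c(1, 2), mean) else image
  gray <- gray / 255
  th <- tryCatch(EBImage::otsu(EBImage::Image(gray)), error = function(e) NA)
  mask <- if (is.na(th)) matrix(FALSE, d[1], d[2]) else gray > th
  if (any(mask)) {
    opened <- EBImage::opening(EBImage::Image(mask * 1),
                               EBImage::makeBrush(5, shape = "disc"))
    mask <- EBImage::imageData(opened) > 0.5
  }
  if (!any(mask)) {
    warning("no foreground found; returning the image unchanged")
    return(image)
  }
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  areas <- tabulate(lab[lab > 0])
  big <- which(lab == which.max(areas), arr.ind = TRUE)
  r <- range(big[, 1]); c <- range(big[, 2])
  r1 <- max(1L, r[1] - margin); r2 <- min(d[1], r[2] + margin)
  c1 <- max(1L, c[1] - margin); c2 <- min(d[2], c[2] + margin)
  if (length(d) == 3) image[r1:r2, c1:c2, , drop = FALSE]
  else image[r1:r2, c1:c2, drop = FALSE]
}

#' Resize to 224 x 224 x 3 and scale intensities to [0, 1]
#'
#' Bilinear resize; grayscale inputs are replicated to 3 channels; values
#' are divided by 255 when the input is on the raw [0, 255] scale (inputs
#' already in [0, 1] are left unscaled, which makes the operation idempotent
#' on already-processed images).
#'
#' @param image numeric array H x W or H x W x 3.
#' @param size output side (default 224).
#' @return numeric array size x size x 3, values in [0, 1].
#' @export
resizeAndScale <- function(image, size = 224L) {
  d <- dim(image)
  stopIf(is.null(d) || d[1] < 1 || d[2] < 1, "invalid image")
  if (max(image) > 1) image <- image / 255
  if (length(d) == 2) image <- array(image, c(d[1], d[2], 3))
  if (d[1] != size || d[2] != size) {
    out <- array(0, c(size, size, 3))
    for (k in 1:3)
      out[, , k] <- EBImage::imageData(
        EBImage::resize(EBImage::Image(image[, , k]), w = size, h = size))
    image <- out
  }
  pmin(pmax(image, 0), 1)
}

#' Split specification
#' @param fractions train/validation/unseen fractions (must sum to 1).
#' @param seed shuffling seed.
#' @param shuffle shuffle within class before assignment.
#' @return A list of class "splitSpec".
#' @export
splitSpec <- function(fractions = c(train = 0.8, validation = 0.1, unseen = 0.1),
                      seed = 1L, shuffle = TRUE) {
  stopIf(abs(sum(fractions) - 1) > 1e-8, "fractions must sum to 1")
  structure(list(fractions = fractions, seed = as.integer(seed),
                 shuffle = shuffle), class = "splitSpec")
}

#' Stratified train/validation/unseen split
#'
#' Global split sizes are floor(f1 n) / floor(f2 n) / remainder; images are
#' allocated per class by largest remainder so every class keeps its
#' proportion within one image of each split, and the three splits partition
#' the input exactly.
#'
#' @param manifest data.frame with at least columns `path` (or any id) and
#'   `label`.
#' @param spec a [splitSpec()].
#' @return named list of three manifests (`train`, `validation`, `unseen`),
#'   each the input rows of that split with a `split` column added.
#' @export
splitDataset <- function(manifest, spec = splitSpec()) {
  stopIf(nrow(manifest) < 10, "need at least 10 images to split")
  labs <- as.character(manifest$label)
  tab <- table(labs)
  stopIf(any(tab < 3), "every class needs at least 3 images to stratify")
  n <- nrow(manifest)
  sizes <- c(floor(spec$fractions[1] * n), floor(spec$fractions[2] * n))
  sizes <- c(sizes, n - sum(sizes))
  classes <- names(tab)
  # largest-remainder allocation of each split's quota over classes
  alloc <- matrix(0L, length(classes), 3, dimnames = list(classes, NULL))
  remaining <- as.integer(tab)
  for (s in 1:2) {
    ideal <- as.numeric(tab) * sizes[s] / n
    base <- pmin(floor(ideal), remaining)
    left <- sizes[s] - sum(base)
    frac <- ideal - floor(ideal)
    ord <- order(frac, decreasing = TRUE)
    i <- 1L
    while (left > 0L) {
      k <- ord[(i - 1L) %% length(ord) + 1L]
      if (remaining[k] - base[k] > 0L) { base[k] <- base[k] + 1L; left <- left - 1L }
      i <- i + 1L
    }
    alloc[, s] <- base
    remaining <- remaining - base
  }
  alloc[, 3] <- remaining
  assign <- character(n)
  withSeed(spec$seed, {
    for (cl in classes) {
      idx <- which(labs == cl)
      if (spec$shuffle) idx <- sample(idx)
      a <- alloc[cl, ]
      assign[idx[seq_len(a[1])]] <- "train"
      assign[idx[a[1] + seq_len(a[2])]] <- "validation"
      assign[idx[a[1] + a[2] + seq_len(a[3])]] <- "unseen"
    }
  })
  out <- lapply(c(train = "train", validation = "validation", unseen = "unseen"),
                function(s) {
                  m <- manifest[assign == s, , drop = FALSE]
                  m$split <- s
                  m
                })
  out
}

#' Split an ImageSet directly
#' @param set an [ImageSet-class].
#' @param spec a [splitSpec()].
#' @return named list of three ImageSets.
#' @export
splitImageSet <- function(set, spec = splitSpec()) {
  manifest <- data.frame(idx = seq_along(set@images),
                         label = as.character(labels(set)))
  parts <- splitDataset(manifest, spec)
  lapply(parts, function(m) set[m$idx])
}

#' Augmentation specification
#'
#' Conservative label-preserving transforms for the training split: random
#' shifts up to `shiftFraction` of the side, shear up to `shearDegrees`,
#' zoom in `zoomRange`, and optional horizontal flip.
#'
#' @param shiftFraction maximum |shift| as a fraction of the image side.
#' @param shearDegrees maximum |shear| angle in degrees.
#' @param zoomRange length-2 multiplicative zoom range.
#' @param horizontalFlip allow mirroring across the vertical axis.
#' @return A list of class "augmentationSpec".
#' @export
augmentationSpec <- function(shiftFraction = 0.1, shearDegrees = 10,
                             zoomRange = c(0.9, 1.1), horizontalFlip = TRUE) {
  structure(list(shiftFraction = shiftFraction, shearDegrees = shearDegrees,
                 zoomRange = zoomRange, horizontalFlip = horizontalFlip),
            class = "augmentationSpec")
}

#' Apply one random augmentation to a processed image
#'
#' Samples shift, shear, zoom and flip from the spec's ranges (deterministic
#' under `seed`), composes them into a single affine map about the image
#' center with zero fill, and clips the result to [0, 1]. A zero-magnitude
#' spec is the identity.
#'
#' @param image processed array size x size x 3 in [0, 1].
#' @param spec an [augmentationSpec()].
#' @param seed RNG seed for this draw (optional; uses the current RNG stream
#'   when NULL, as during training).
#' @return augmented array, same shape, values in [0, 1].
#' @export
augmentImage <- function(image, spec = augmentationSpec(), seed = NULL) {
  run <- function() {
    d <- dim(image)
    dx <- stats::runif(1, -1, 1) * spec$shiftFraction * d[1]
    dy <- stats::runif(1, -1, 1) * spec$shiftFraction * d[2]
    sh <- stats::runif(1, -1, 1) * spec$shearDegrees * pi / 180
    zo <- stats::runif(1, spec$zoomRange[1], spec$zoomRange[2])
    fl <- spec$horizontalFlip && stats::runif(1) < 0.5
    if (fl) image <- image[, rev(seq_len(d[2])), , drop = FALSE]
    # affine about the center (row-vector convention y = (x 1) %*% A):
    # zoom + shear linear part, then translation
    cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
    S <- matrix(c(zo, 0, zo * tan(sh), zo), 2, 2)
    A <- rbind(S, c(cx, cy) - c(cx, cy) %*% S + c(dx, dy))
    if (isTRUE(all.equal(A, rbind(diag(2), c(0, 0)), check.attributes = FALSE)))
      return(image)
    out <- array(0, d)
    for (k in 1:3)
      out[, , k] <- EBImage::imageData(
        EBImage::affine(EBImage::Image(image[, , k]), A, bg.col = 0))
    pmin(pmax(out, 0), 1)
  }
  if (is.null(seed)) run() else withSeed(seed, run())
}

#' Shift an image by whole pixels with zero padding
#' @param image array H x W x C (or H x W).
#' @param dr,dc row/column shift in pixels (positive moves content down/right).
#' @return shifted array, zero-filled border.
#' @export
shiftImage <- function(image, dr, dc) {
  d <- dim(image)
  out <- array(0, d)
  src_r <- seq_len(d[1]) - dr; src_c <- seq_len(d[2]) - dc
  ok_r <- src_r >= 1 & src_r <= d[1]; ok_c <- src_c >= 1 & src_c <= d[2]
  if (length(d) == 3) {
    out[which(ok_r), which(ok_c), ] <- image[src_r[ok_r], src_c[ok_c], , drop = FALSE]
  } else {
    out[which(ok_r), which(ok_c)] <- image[src_r[ok_r], src_c[ok_c], drop = FALSE]
  }
  out
}

#' Preprocess an ImageSet end-to-end
#'
#' Optional crop, then resize-and-scale, for every image.
#' @param set an [ImageSet-class] of raw images.
#' @param crop apply [cropBrainRegion()] first.
#' @param size output side.
#' @return An [ImageSet-class] of processed size x size x 3 images.
#' @export
preprocessImageSet <- function(set, crop = TRUE, size = 224L) {
  imgs <- lapply(set@images, function(img) {
    if (crop) img <- cropBrainRegion(img)
    resizeAndScale(img, size)
  })
  new("ImageSet", images = imgs, labels = labels(set), meta = set@meta)
}
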