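test_that("cropping finds the bounding box of the dominant foreground region", {
  img <- matrix(0, 100, 100)
  img[41:60, 41:60] <- 255
  out <- cropBrainRegion(img)
  # tight box plus the 5 px margin on each side
  expect_equal(dim(out), c(30, 30))
  expect_equal(sum(out > 0), 400)

  # two blobs: the crop encloses the larger one only
  # (oracle: component areas counted directly from the construction)
  img2 <- matrix(0, 120, 120)
  img2[20:39, 20:34] <- 200   # 20 x 15 = 300 px
  img2[90:96, 90:96] <- 200                 # 49 px
  out2 <- cropBrainRegion(img2)
  expect_lte(nrow(out2), 31); expect_lte(ncol(out2), 26)
  expect_equal(sum(out2 == 200), 300)
})

test_that("a blank image is returned unchanged with a warning", {
  img <- matrix(0, 64, 64)
  expect_warning(out <- cropBrainRegion(img), "no foreground")
  expect_identical(out, img)
})

test_that("resize-and-scale maps constants exactly and replicates gray to 3 channels", {
  expect_equal(resizeAndScale(matrix(255, 64, 64)),
               array(1, c(224, 224, 3)))
  expect_equal(resizeAndScale(matrix(0, 64, 64)),
               array(0, c(224, 224, 3)))
  out <- resizeAndScale(matrix(128, 100, 150))
  expect_equal(dim(out), c(224, 224, 3))
  expect_equal(out[, , 1], out[, , 3])
})

test_that("2x downsampling of a checkerboard averages to the closed-form block mean", {
  a <- 40; b <- 200
  cb <- matrix(b, 448, 448)
  cb[(row(cb) + col(cb)) %% 2 == 0] <- a
  out <- resizeAndScale(cb)
  expect_equal(max(abs(out - (a + b) / 2 / 255)), 0, tolerance = 1e-6)
})

test_that("resize-and-scale is idempotent on already-processed input", {
  img <- array(runif(224 * 224 * 3), c(224, 224, 3))
  expect_equal(resizeAndScale(img), img)
})

test_that("the 80/10/10 split hits the published sizes on 3,064 images", {
  # the three-class slice counts of the public dataset
  manifest <- data.frame(path = sprintf("img%04d", 1:3064),
                         label = rep(c("glioma", "meningioma", "pituitary"),
                                     c(1426, 708, 930)))
  parts <- splitDataset(manifest, splitSpec(seed = 1))
  expect_equal(nrow(parts$train), 2451L)
  expect_equal(nrow(parts$validation), 306L)
  expect_equal(nrow(parts$unseen), 307L)
  # stratification: every class within one image of its overall proportion
  for (cl in unique(manifest$label)) {
    frac <- sum(manifest$label == cl) / nrow(manifest)
    for (p in parts)
      expect_lte(abs(sum(p$label == cl) - frac * nrow(p)), 1)
  }
})

test_that("splits partition the input deterministically for any seed", {
  manifest <- data.frame(path = sprintf("i%03d", 1:57),
                         label = rep(c("a", "b", "c"), c(30, 18, 9)))
  for (seed in c(1, 7, 123)) {
    parts <- splitDataset(manifest, splitSpec(seed = seed))
    all_paths <- sort(unname(unlist(lapply(parts, `[[`, "path"))))
    expect_equal(all_paths, sort(manifest$path))
    expect_equal(sum(vapply(parts, nrow, integer(1))), 57L)
    again <- splitDataset(manifest, splitSpec(seed = seed))
    expect_identical(parts, again)
  }
  # single class of 10 -> 8 / 1 / 1
  single <- data.frame(path = letters[1:10], label = "x")
  sizes <- vapply(splitDataset(single, splitSpec(seed = 2)), nrow, integer(1))
  expect_equal(unname(sizes), c(8L, 1L, 1L))
})

test_that("degenerate splits are rejected", {
  expect_error(splitDataset(data.frame(path = letters[1:5], label = "x")),
               "at least 10")
  m <- data.frame(path = letters[1:12], label = rep(c("a", "b"), c(10, 2)))
  expect_error(splitDataset(m), "at least 3")
})

test_that("zero-magnitude augmentation is the identity", {
  img <- array(runif(224 * 224 * 3), c(224, 224, 3))
  spec <- augmentationSpec(shiftFraction = 0, shearDegrees = 0,
                           zoomRange = c(1, 1), horizontalFlip = FALSE)
  expect_equal(augmentImage(img, spec, seed = 1), img, tolerance = 1e-12)
})

test_that("augmentation is deterministic under a seed and stays in range", {
  img <- resizeAndScale(images(generateSyntheticDataset(
    syntheticSpec(nPerClass = 1, nClasses = 2, seed = 5)))[[1]])
  a1 <- augmentImage(img, augmentationSpec(), seed = 42)
  a2 <- augmentImage(img, augmentationSpec(), seed = 42)
  expect_identical(a1, a2)
  expect_true(min(a1) >= 0 && max(a1) <= 1)
  a3 <- augmentImage(img, augmentationSpec(), seed = 43)
  expect_false(identical(a1, a3))
})

test_that("horizontal flip mirrors blob columns about the image center", {
  ds <- generateSyntheticDataset(syntheticSpec(nPerClass = 1, nClasses = 3,
                                               noiseSd = 0, seed = 8))
  img <- resizeAndScale(images(ds)[[3]], 224)
  spec <- augmentationSpec(shiftFraction = 0, shearDegrees = 0,
                           zoomRange = c(1, 1), horizontalFlip = TRUE)
  # draw until the flip branch fires (flip is a fair coin under the seed)
  flipped <- NULL
  for (s in 1:10) {
    cand <- augmentImage(img, spec, seed = s)
    if (!isTRUE(all.equal(cand, img))) { flipped <- cand; break }
  }
  expect_false(is.null(flipped))
  cm <- function(x) {
    w <- apply(x[, , 1], 2, sum)
    sum(w * seq_along(w)) / sum(w)
  }
  # column c maps to (width + 1) - c
  expect_equal(cm(flipped), 225 - cm(img), tolerance = 0.5)
})

test_that("shifting +10 then -10 pixels restores everything except the border", {
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  back <- shiftImage(shiftImage(img, 10, 10), -10, -10)
  expect_equal(back[1:54, 1:54, ], img[1:54, 1:54, ])
  expect_true(all(back[55:64, , ] == 0))
  expect_true(all(back[, 55:64, ] == 0))
})
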