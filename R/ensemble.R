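# Frozen-backbone feature extraction, zero-padding uniformization, and
# channel concatenation into the fused map the encoder consumes.

#' Extract the feature map of one frozen backbone
#'
#' Runs a runnable backbone (see [tinyBackbone()]) on a processed
#' 224 x 224 x 3 image and checks the declared output shape. Reference
#' specs without weights (pretrained architectures) cannot be run here and
#' raise an error; their declared shapes still drive dimension bookkeeping.
#'
#' @param image processed array 224 x 224 x 3, values in [0, 1].
#' @param spec a [BackboneSpec-class].
#' @return numeric array (outSpatial, outSpatial, outChannels).
#' @export
extractFeatures <- function(image, spec) {
  d <- dim(image)
  stopIf(length(d) != 3 || d[1] != 224 || d[2] != 224 || d[3] != 3,
         "backbone input must be 224 x 224 x 3")
  stopIf(min(image) < 0 || max(image) > 1, "backbone input must be in [0, 1]")
  stopIf(length(spec@weights) == 0,
         sprintf("backbone '%s' has no weights here (pretrained architecture); use tinyBackbone()",
                 spec@name))
  k <- spec@weights$pool
  S <- spec@outSpatial
  side <- S * k
  pooled <- array(0, c(side, side, 3))
  for (ch in 1:3)
    pooled[, , ch] <- EBImage::imageData(
      EBImage::resize(EBImage::Image(image[, , ch]), w = side, h = side))
  # strided convolution: non-overlapping k x k patches -> linear -> ReLU x2
  np <- S * S
  patches <- matrix(0, np, k * k * 3)
  for (pr in seq_len(S)) for (pc in seq_len(S)) {
    block <- pooled[(pr - 1) * k + seq_len(k), (pc - 1) * k + seq_len(k), ]
    patches[(pr - 1) * S + pc, ] <- as.vector(block)
  }
  h <- pmax(patches %*% spec@weights$w1, 0)
  o <- pmax(h %*% spec@weights$w2, 0)
  out <- array(0, c(S, S, spec@outChannels))
  for (pr in seq_len(S)) for (pc in seq_len(S))
    out[pr, pc, ] <- o[(pr - 1) * S + pc, ]
  stopIf(!all(dim(out) == c(S, S, spec@outChannels)),
         "backbone output violates its declared shape")
  out
}

#' Zero-pad feature maps to a common spatial side
#'
#' Each map is placed in the top-left corner of a target x target canvas;
#' all padding entries are exactly zero, so the sum of entries is preserved.
#' A map already at the target size is returned unchanged; a larger map is
#' a configuration error.
#'
#' @param maps list of numeric arrays (S, S, C) with possibly different S, C.
#' @param targetSpatial common output side.
#' @return list of arrays (targetSpatial, targetSpatial, C).
#' @export
zeroPadUniformize <- function(maps, targetSpatial) {
  lapply(maps, function(m) {
    d <- dim(m)
    stopIf(d[1] > targetSpatial || d[2] > targetSpatial,
           "feature map larger than targetSpatial")
    if (d[1] == targetSpatial && d[2] == targetSpatial) return(m)
    out <- array(0, c(targetSpatial, targetSpatial, d[3]))
    out[seq_len(d[1]), seq_len(d[2]), ] <- m
    out
  })
}

#' Concatenate feature maps along channels
#'
#' All maps must share the same spatial side; member order is preserved in
#' the channel order of the output.
#'
#' @param maps list of numeric arrays (S, S, C_i).
#' @return numeric array (S, S, sum C_i).
#' @export
concatChannels <- function(maps) {
  sides <- vapply(maps, function(m) dim(m)[1], numeric(1))
  stopIf(length(unique(sides)) != 1 ||
           length(unique(vapply(maps, function(m) dim(m)[2], numeric(1)))) != 1,
         "maps must share the same spatial side")
  S1 <- dim(maps[[1]])[1]; S2 <- dim(maps[[1]])[2]
  ctot <- sum(vapply(maps, function(m) dim(m)[3], numeric(1)))
  out <- array(0, c(S1, S2, ctot))
  at <- 0L
  for (m in maps) {
    ck <- dim(m)[3]
    out[, , at + seq_len(ck)] <- m
    at <- at + ck
  }
  out
}

#' Run the whole ensemble on one image and fuse the outputs
#'
#' extract -> zero-pad to the ensemble's target side -> channel concat.
#'
#' @param image processed array 224 x 224 x 3.
#' @param ensemble an [EnsembleSpec-class] of runnable backbones.
#' @return fused array (targetSpatial, targetSpatial, fusedChannels).
#' @export
fuseFeatures <- function(image, ensemble) {
  maps <- lapply(ensemble@members, function(b) extractFeatures(image, b))
  concatChannels(zeroPadUniformize(maps, ensemble@targetSpatial))
}
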