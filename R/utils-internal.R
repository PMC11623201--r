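# Internal helpers shared across modules.

#' Run code with a temporary RNG seed, restoring the caller's RNG state.
#' @noRd
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Truncated-normal init (sd 0.02, clipped at 2 sd), the transformer default.
#' @noRd
truncNormal <- function(n, sd = 0.02) {
  pmin(pmax(stats::rnorm(n, 0, sd), -2 * sd), 2 * sd)
}

initMatrix <- function(nrow, ncol, sd = 0.02) {
  matrix(truncNormal(nrow * ncol, sd), nrow, ncol)
}

#' @noRd
stopIf <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

#' Row-wise softmax with max-shift for numerical stability.
#' @noRd
rowSoftmax <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

#' Bilinear upsampling of a 2-D map to a target size (used by Grad-CAM).
#' @noRd
upsampleBilinear <- function(map, nrow_out, ncol_out) {
  img <- EBImage::resize(EBImage::Image(map), w = nrow_out, h = ncol_out)
  EBImage::imageData(img)
}
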