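# Shared fixtures: tiny ensembles and small models, built in code.

tinyEnsemble <- function(targetSpatial = 8L) {
  ensembleSpec(list(tinyBackbone(7, 8, seed = 7), tinyBackbone(5, 8, seed = 8)),
               targetSpatial = targetSpatial)
}

smallBlockConfig <- function(...) {
  args <- list(embedDim = 16L, heads = 2L, mlpNodes = 8L,
               dropoutMlp = 0, dropoutAttn = 0, dropoutBlock = 0,
               dropPath = 0)
  args[names(list(...))] <- list(...)
  do.call(swinBlockConfig, args)
}

smallModel <- function(nClasses = 3L, seed = 3L, ...) {
  buildModel(tinyEnsemble(), smallBlockConfig(), headConfig(12L, 8L),
             nClasses = nClasses, seed = seed, ...)
}

randomFused <- function(model, n = 2L, seed = 1L) {
  L <- model@layout
  withr::with_seed(seed, lapply(seq_len(n), function(i)
    array(rnorm(L$T * L$T * L$Cin), c(L$T, L$T, L$Cin))))
}

# dense masked attention over a whole token grid: the brute-force oracle for
# shifted-window attention. Tokens i, j may attend iff, after the cyclic
# roll, they fall in the same window AND the shift mask allows the pair.
denseAttentionOracle <- function(grid, cfg, params) {
  d <- dim(grid)
  M <- cfg@window; s <- cfg@shift
  X <- matrix(0, d[1] * d[2], d[3])
  for (k in seq_len(d[3])) X[, k] <- as.vector(t(grid[, , k]))
  n <- nrow(X)
  # shifted coordinates of each token (0-based)
  pos <- cbind(rep(seq_len(d[1]) - 1L, each = d[2]),
               rep(seq_len(d[2]) - 1L, times = d[1]))
  shifted <- cbind((pos[, 1] - s) %% d[1], (pos[, 2] - s) %% d[2])
  winId <- (shifted[, 1] %/% M) * (d[2] %/% M) + shifted[, 2] %/% M
  band <- function(u, H) ifelse(u < H - M, 0L, ifelse(u < H - s, 1L, 2L))
  regId <- if (s > 0) band(shifted[, 1], d[1]) * 3L + band(shifted[, 2], d[2])
           else rep(0L, n)
  allowed <- outer(winId, winId, "==") & outer(regId, regId, "==")
  C <- d[3]; dh <- C %/% cfg@heads
  Q <- sweep(X %*% params$Wq, 2, params$bq, "+")
  K <- sweep(X %*% params$Wk, 2, params$bk, "+")
  V <- sweep(X %*% params$Wv, 2, params$bv, "+")
  O <- matrix(0, n, C)
  for (h in seq_len(cfg@heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dh)
    S[!allowed] <- -Inf
    A <- exp(S - apply(S, 1, max))
    A <- A / rowSums(A)
    O[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  out <- sweep(O %*% params$Wo, 2, params$bo, "+")
  g <- array(0, d)
  for (k in seq_len(C)) g[, , k] <- matrix(out[, k], d[1], d[2], byrow = TRUE)
  g
}

# windowed attention on a grid through the package's implementation path
# (the same kernel and index machinery modelForward uses), eval mode
windowedAttention <- function(grid, cfg, params) {
  d <- dim(grid)
  M <- cfg@window; s <- cfg@shift
  X <- winshift:::gridToSeq(grid)
  winPerm <- winshift:::windowPermutation(d[1], d[2], M)
  comb <- if (s > 0) winshift:::shiftPermutation(d[1], d[2], s)[winPerm]
          else winPerm
  inv <- integer(length(comb)); inv[comb] <- seq_along(comb)
  masks <- buildShiftMask(d[1], d[2], M, s)
  att <- winshift:::attentionForward(X[comb, , drop = FALSE], cfg@heads,
                                     params$Wq, params$bq, params$Wk, params$bk,
                                     params$Wv, params$bv, params$Wo, params$bo,
                                     masks, length(masks), 0, FALSE)
  winshift:::seqToGrid(att$out[inv, , drop = FALSE], d[1], d[2])
}

randomAttnParams <- function(C, seed = 1L) {
  withr::with_seed(seed, list(
    Wq = matrix(rnorm(C * C, 0, 0.3), C, C), bq = rnorm(C, 0, 0.1),
    Wk = matrix(rnorm(C * C, 0, 0.3), C, C), bk = rnorm(C, 0, 0.1),
    Wv = matrix(rnorm(C * C, 0, 0.3), C, C), bv = rnorm(C, 0, 0.1),
    Wo = matrix(rnorm(C * C, 0, 0.3), C, C), bo = rnorm(C, 0, 0.1)))
}

randomGrid <- function(Hg, Wg, C, seed = 1L) {
  withr::with_seed(seed, array(rnorm(Hg * Wg * C), c(Hg, Wg, C)))
}

# the confusion matrix printed for the held-out split of the three-class
# dataset: 142 meningioma, 70 glioma, 93 pituitary correct, with one
# meningioma and one glioma swapped into each other
paperConfusion <- function() {
  cm <- matrix(0L, 3, 3)
  cm[1, 1] <- 142L; cm[1, 2] <- 1L   # one meningioma predicted glioma
  cm[2, 2] <- 70L;  cm[2, 1] <- 1L   # one glioma predicted meningioma
  cm[3, 3] <- 93L
  new("ConfusionMatrix", counts = cm,
      classes = c("meningioma", "glioma", "pituitary"))
}
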