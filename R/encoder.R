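# Shifted-window encoder primitives: position embedding, patch partition,
# linear embedding, window partition, cyclic shift, shift masks, patch
# merging, and the attention complexity formulas.
#
# Token convention: a token grid Hg x Wg x C is flattened to an n x C
# sequence in raster order, token t = (r - 1) * Wg + c.

#' Add a learned absolute position embedding to a feature map
#'
#' @param map numeric array (S, S, C).
#' @param epos numeric array of the same shape (one parameter per position
#'   per channel).
#' @return map + epos, shape unchanged.
#' @export
addPositionEmbedding <- function(map, epos) {
  stopIf(!all(dim(map) == dim(epos)), "position embedding shape mismatch")
  map + epos
}

# linear indices mapping a (possibly padded) S1 x S2 x C array to an
# n x (p^2 C) token matrix; row-major over patches and within patch,
# channels fastest
patchIndex <- function(S1, S2, C, p) {
  H <- as.integer(ceiling(S1 / p) * p)
  W <- as.integer(ceiling(S2 / p) * p)
  Hg <- H %/% p; Wg <- W %/% p
  d <- p * p * C
  idx <- matrix(0L, Hg * Wg, d)
  for (pr in seq_len(Hg)) for (pc in seq_len(Wg)) {
    t <- (pr - 1L) * Wg + pc
    m <- 0L
    for (i in seq_len(p)) for (j in seq_len(p)) {
      r <- (pr - 1L) * p + i
      cc <- (pc - 1L) * p + j
      idx[t, m + seq_len(C)] <- r + (cc - 1L) * H + (seq_len(C) - 1L) * H * W
      m <- m + C
    }
  }
  list(idx = idx, H = H, W = W, Hg = Hg, Wg = Wg, d = d)
}

#' Partition a feature map into patch tokens
#'
#' Cuts the map into non-overlapping p x p patches (zero-padding the bottom
#' and right if a side is not divisible by p) and flattens each patch to a
#' p^2 * C vector: patches in raster order, pixels row-major within the
#' patch, channels fastest. The inverse ([patchUnpartition()]) recovers the
#' map exactly.
#'
#' @param map numeric array (S1, S2, C).
#' @param p patch side.
#' @return n x (p^2 C) token matrix with attributes `Hg`, `Wg` (token grid).
#' @export
patchPartition <- function(map, p) {
  d <- dim(map)
  pi <- patchIndex(d[1], d[2], d[3], p)
  padded <- if (pi$H == d[1] && pi$W == d[2]) map else {
    out <- array(0, c(pi$H, pi$W, d[3])); out[seq_len(d[1]), seq_len(d[2]), ] <- map; out
  }
  tok <- matrix(padded[as.vector(pi$idx)], nrow = nrow(pi$idx))
  attr(tok, "Hg") <- pi$Hg; attr(tok, "Wg") <- pi$Wg
  attr(tok, "shape") <- d; attr(tok, "p") <- p
  tok
}

#' Reassemble a feature map from patch tokens
#' @param tok token matrix from [patchPartition()] (attributes intact), or
#'   any n x (p^2 C) matrix with `shape` and `p` supplied.
#' @param shape original map dimensions (defaults to the stored attribute).
#' @param p patch side (defaults to the stored attribute).
#' @return the reconstructed (S1, S2, C) array.
#' @export
patchUnpartition <- function(tok, shape = attr(tok, "shape"), p = attr(tok, "p")) {
  pi <- patchIndex(shape[1], shape[2], shape[3], p)
  padded <- array(0, c(pi$H, pi$W, shape[3]))
  padded[as.vector(pi$idx)] <- as.vector(tok)
  padded[seq_len(shape[1]), seq_len(shape[2]), , drop = FALSE]
}

#' Shared linear embedding of patch tokens
#' @param tok n x d token matrix.
#' @param E d x C projection matrix.
#' @param b optional length-C bias.
#' @return n x C embedded tokens.
#' @export
linearEmbed <- function(tok, E, b = NULL) {
  stopIf(ncol(tok) != nrow(E), "token dimension does not match E")
  out <- tok %*% E
  if (!is.null(b)) out <- sweep(out, 2, b, "+")
  out
}

# permutation grouping a raster token sequence into M x M windows
# (windows row-major, tokens row-major within each window)
windowPermutation <- function(Hg, Wg, M) {
  stopIf(Hg %% M != 0 || Wg %% M != 0, "grid sides must be divisible by M")
  perm <- integer(Hg * Wg)
  t <- 0L
  for (wr in seq_len(Hg %/% M)) for (wc in seq_len(Wg %/% M))
    for (i in seq_len(M)) for (j in seq_len(M)) {
      t <- t + 1L
      r <- (wr - 1L) * M + i; cc <- (wc - 1L) * M + j
      perm[t] <- (r - 1L) * Wg + cc
    }
  perm
}

#' Partition a token grid into non-overlapping M x M windows
#' @param grid numeric array (Hg, Wg, C) of tokens.
#' @param M window side (must divide both grid sides).
#' @return list of M^2 x C matrices, windows in raster order.
#' @export
windowPartition <- function(grid, M) {
  d <- dim(grid)
  seqmat <- gridToSeq(grid)
  perm <- windowPermutation(d[1], d[2], M)
  W <- M * M
  lapply(seq_len(length(perm) %/% W), function(g)
    seqmat[perm[(g - 1L) * W + seq_len(W)], , drop = FALSE])
}

#' Reverse [windowPartition()]
#' @param windows list of M^2 x C matrices in raster window order.
#' @param Hg,Wg grid sides.
#' @param M window side.
#' @return numeric array (Hg, Wg, C).
#' @export
windowReverse <- function(windows, Hg, Wg, M) {
  C <- ncol(windows[[1]])
  seqmat <- matrix(0, Hg * Wg, C)
  perm <- windowPermutation(Hg, Wg, M)
  W <- M * M
  for (g in seq_along(windows))
    seqmat[perm[(g - 1L) * W + seq_len(W)], ] <- windows[[g]]
  seqToGrid(seqmat, Hg, Wg)
}

# raster sequence <-> grid array converters
gridToSeq <- function(grid) {
  d <- dim(grid)
  m <- matrix(0, d[1] * d[2], d[3])
  for (k in seq_len(d[3])) m[, k] <- as.vector(t(grid[, , k]))
  m
}
seqToGrid <- function(seqmat, Hg, Wg) {
  C <- ncol(seqmat)
  g <- array(0, c(Hg, Wg, C))
  for (k in seq_len(C)) g[, , k] <- matrix(seqmat[, k], Hg, Wg, byrow = TRUE)
  g
}

# sequence permutation realizing a cyclic roll by (-s, -s):
# shifted[r', c'] = grid[(r' + s - 1) %% Hg + 1, (c' + s - 1) %% Wg + 1]
shiftPermutation <- function(Hg, Wg, s) {
  perm <- integer(Hg * Wg)
  t <- 0L
  for (r1 in seq_len(Hg)) for (c1 in seq_len(Wg)) {
    t <- t + 1L
    r <- (r1 - 1L + s) %% Hg + 1L
    cc <- (c1 - 1L + s) %% Wg + 1L
    perm[t] <- (r - 1L) * Wg + cc
  }
  perm
}

#' Cyclically shift a token grid by (-s, -s) with wrap-around
#' @param grid numeric array (Hg, Wg, C).
#' @param s shift in tokens (0 <= s < window side).
#' @return shifted grid; [cyclicShift()] with `inverse = TRUE` undoes it.
#' @param inverse apply the inverse roll (+s, +s).
#' @export
cyclicShift <- function(grid, s, inverse = FALSE) {
  if (s == 0) return(grid)
  d <- dim(grid)
  sqm <- gridToSeq(grid)
  perm <- shiftPermutation(d[1], d[2], s)
  if (inverse) {
    inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
    perm <- inv
  }
  seqToGrid(sqm[perm, , drop = FALSE], d[1], d[2])
}

#' Attention masks for shifted windows
#'
#' After the cyclic roll, tokens that wrapped around originate from
#' non-adjacent image regions; attention between tokens of different origin
#' regions is blocked with a large negative additive constant before the
#' softmax. Region ids follow the standard 3-band slicing per axis
#' ((0, H-M), (H-M, H-s), (H-s, H)) on the shifted grid.
#'
#' @param Hg,Wg token-grid sides (divisible by M).
#' @param M window side.
#' @param s shift; `s = 0` yields all-zero masks.
#' @param large magnitude of the blocking constant (default 1e9).
#' @return list of M^2 x M^2 additive masks (entries 0 or -large), one per
#'   window in raster window order.
#' @export
buildShiftMask <- function(Hg, Wg, M, s, large = 1e9) {
  nWin <- (Hg %/% M) * (Wg %/% M)
  W <- M * M
  if (s == 0) return(rep(list(matrix(0, W, W)), nWin))
  band <- function(u, H) ifelse(u < H - M, 0L, ifelse(u < H - s, 1L, 2L))
  region <- matrix(0L, Hg, Wg)
  for (r in seq_len(Hg)) for (cc in seq_len(Wg))
    region[r, cc] <- band(r - 1L, Hg) * 3L + band(cc - 1L, Wg)
  regseq <- as.vector(t(region))
  perm <- windowPermutation(Hg, Wg, M)
  lapply(seq_len(nWin), function(g) {
    ids <- regseq[perm[(g - 1L) * W + seq_len(W)]]
    m <- outer(ids, ids, function(a, b) ifelse(a == b, 0, -large))
    m
  })
}

#' Windowed multi-head self-attention over a list of windows
#'
#' Per window and head, scaled dot-product attention with an additive mask
#' applied before the softmax, heads concatenated and projected by Wo.
#'
#' @param windows list of W x C token matrices.
#' @param heads number of heads (C must be divisible by heads).
#' @param Wq,Wk,Wv,Wo C x C projection matrices.
#' @param masks optional list of W x W additive masks (recycled if length 1).
#' @return list of W x C attended windows.
#' @export
windowAttention <- function(windows, heads, Wq, Wk, Wv, Wo, masks = NULL) {
  C <- ncol(windows[[1]])
  stopIf(C %% heads != 0, "embedding dim must be divisible by heads")
  dh <- C %/% heads
  lapply(seq_along(windows), function(g) {
    X <- windows[[g]]
    Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
    O <- matrix(0, nrow(X), C)
    mask <- if (is.null(masks)) NULL
            else masks[[(g - 1L) %% length(masks) + 1L]]
    for (h in seq_len(heads)) {
      cols <- (h - 1L) * dh + seq_len(dh)
      S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dh)
      if (!is.null(mask)) S <- S + mask
      A <- rowSoftmax(S)
      O[, cols] <- A %*% V[, cols, drop = FALSE]
    }
    O %*% Wo
  })
}

#' Merge 2 x 2 token neighborhoods
#'
#' Concatenates each 2 x 2 neighborhood (4C features, row-major order) and
#' reduces it linearly to 2C, halving both grid sides (odd sides are
#' zero-padded bottom/right first). A 1 x 1 grid passes through unchanged.
#'
#' @param grid numeric array (Hg, Wg, C).
#' @param Wmerge 4C x 2C reduction matrix.
#' @param b optional length-2C bias.
#' @return numeric array (ceil(Hg/2), ceil(Wg/2), 2C).
#' @export
patchMerging <- function(grid, Wmerge, b = NULL) {
  d <- dim(grid)
  if (d[1] == 1 && d[2] == 1) return(grid)
  He <- d[1] + d[1] %% 2; We <- d[2] + d[2] %% 2
  if (He != d[1] || We != d[2]) {
    padded <- array(0, c(He, We, d[3]))
    padded[seq_len(d[1]), seq_len(d[2]), ] <- grid
    grid <- padded
  }
  Ho <- He %/% 2; Wo <- We %/% 2
  gathered <- matrix(0, Ho * Wo, 4 * d[3])
  for (r in seq_len(Ho)) for (cc in seq_len(Wo)) {
    t <- (r - 1L) * Wo + cc
    block <- grid[2 * r - 1:0, 2 * cc - 1:0, , drop = FALSE]
    gathered[t, ] <- c(block[1, 1, ], block[1, 2, ], block[2, 1, ], block[2, 2, ])
  }
  stopIf(nrow(Wmerge) != 4 * d[3] || ncol(Wmerge) != 2 * d[3],
         "Wmerge must be 4C x 2C")
  out <- gathered %*% Wmerge
  if (!is.null(b)) out <- sweep(out, 2, b, "+")
  seqToGrid(out, Ho, Wo)
}

#' Operation count of global multi-head self-attention
#'
#' 4 h w C^2 + 2 (h w)^2 C: quadratic in the patch count h*w.
#' @param h,w patch-grid sides.
#' @param C channel (embedding) dimension.
#' @return exact operation count.
#' @export
complexityMsa <- function(h, w, C) {
  stopIf(h < 1 || w < 1 || C < 1, "parameters must be positive")
  4 * h * w * C^2 + 2 * (h * w)^2 * C
}

#' Operation count of window-based multi-head self-attention
#'
#' 4 h w C^2 + 2 M^2 h w C: linear in the patch count when M is fixed, and
#' equal to [complexityMsa()] when h = w = M (one window covers everything).
#' @param h,w patch-grid sides.
#' @param C channel (embedding) dimension.
#' @param M window side (M <= min(h, w)).
#' @return exact operation count.
#' @export
complexityWmsa <- function(h, w, C, M) {
  stopIf(h < 1 || w < 1 || C < 1 || M < 1, "parameters must be positive")
  stopIf(M > min(h, w), "M must not exceed min(h, w)")
  4 * h * w * C^2 + 2 * M^2 * h * w * C
}

#' Initialize parameters for one standalone transformer block
#' @param cfg a [SwinBlockConfig-class].
#' @param seed init seed.
#' @param zero all-zero projections (useful to expose the pure residual path).
#' @return named list of block parameters.
#' @export
initSwinBlockParams <- function(cfg, seed = 1L, zero = FALSE) {
  C <- cfg@embedDim
  mk <- function(nr, nc) if (zero) matrix(0, nr, nc) else initMatrix(nr, nc)
  withSeed(seed, list(
    ln1g = rep(1, C), ln1b = numeric(C),
    Wq = mk(C, C), bq = numeric(C), Wk = mk(C, C), bk = numeric(C),
    Wv = mk(C, C), bv = numeric(C), Wo = mk(C, C), bo = numeric(C),
    ln2g = rep(1, C), ln2b = numeric(C),
    mlpW1 = mk(C, cfg@mlpNodes), mlpb1 = numeric(cfg@mlpNodes),
    mlpW2 = mk(cfg@mlpNodes, C), mlpb2 = numeric(C)))
}

#' Apply one shifted-window transformer block to a token grid
#'
#' LN -> (cyclic shift) -> windowed masked MSA -> (inverse shift) ->
#' residual, then LN -> 2-layer GELU MLP -> residual. Evaluation mode:
#' dropout and drop-path are inactive. Shape is preserved.
#'
#' @param grid numeric array (Hg, Wg, C) with sides divisible by the window.
#' @param cfg a [SwinBlockConfig-class].
#' @param params block parameters from [initSwinBlockParams()].
#' @return transformed (Hg, Wg, C) array.
#' @export
swinBlock <- function(grid, cfg, params = initSwinBlockParams(cfg)) {
  d <- dim(grid)
  M <- cfg@window; s <- cfg@shift
  stopIf(d[1] %% M != 0 || d[2] %% M != 0, "grid sides must be divisible by M")
  X <- gridToSeq(grid)
  n <- nrow(X)
  ln1 <- lnForward(X, params$ln1g, params$ln1b)$out
  comb <- if (s > 0) shiftPermutation(d[1], d[2], s)[windowPermutation(d[1], d[2], M)]
          else windowPermutation(d[1], d[2], M)
  inv <- integer(n); inv[comb] <- seq_len(n)
  masks <- buildShiftMask(d[1], d[2], M, s)
  att <- attentionForward(ln1[comb, , drop = FALSE], cfg@heads,
                          params$Wq, params$bq, params$Wk, params$bk,
                          params$Wv, params$bv, params$Wo, params$bo,
                          masks, length(masks), 0, FALSE)
  X <- X + att$out[inv, , drop = FALSE]
  ln2 <- lnForward(X, params$ln2g, params$ln2b)$out
  h <- geluForward(sweep(ln2 %*% params$mlpW1, 2, params$mlpb1, "+"))$out
  X <- X + sweep(h %*% params$mlpW2, 2, params$mlpb2, "+")
  seqToGrid(X, d[1], d[2])
}
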