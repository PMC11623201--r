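# Model assembly and the batched forward/backward pass through the full
# pipeline: fused feature map -> position embedding -> patch partition ->
# linear embedding -> alternating W-MSA / SW-MSA blocks with patch merging
# -> flatten (or class-token) readout -> dense softmax head.

# precompute per-stage index structures for a given fused-map geometry
computeLayout <- function(targetSpatial, fusedChannels, patchSize, blocks,
                          readout) {
  p <- patchSize
  pi <- patchIndex(targetSpatial, targetSpatial, fusedChannels, p)
  Hg <- pi$Hg; Wg <- pi$Wg
  C <- blocks[[1]]@embedDim
  stages <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    cfg <- blocks[[i]]
    M <- cfg@window; s <- cfg@shift
    Hp <- as.integer(ceiling(Hg / M) * M)
    Wp <- as.integer(ceiling(Wg / M) * M)
    padRows <- if (Hp != Hg || Wp != Wg) {
      as.vector(t(outer(seq_len(Hg) - 1L, seq_len(Wg), function(r, cc) r * Wp + cc)))
    } else NULL
    winPerm <- windowPermutation(Hp, Wp, M)
    comb <- if (s > 0) shiftPermutation(Hp, Wp, s)[winPerm] else winPerm
    invComb <- integer(length(comb)); invComb[comb] <- seq_along(comb)
    masks <- buildShiftMask(Hp, Wp, M, s)
    hasMerge <- !(Hp == 1 && Wp == 1)
    if (hasMerge) {
      He <- Hp + Hp %% 2L; We <- Wp + Wp %% 2L
      Ho <- He %/% 2L; Wo <- We %/% 2L
      mergeIdx <- matrix(0L, Ho * Wo, 4)
      for (r in seq_len(Ho)) for (cc in seq_len(Wo)) {
        t <- (r - 1L) * Wo + cc
        rr <- 2L * r - 1L; c2 <- 2L * cc - 1L
        at <- function(a, b) if (a <= Hp && b <= Wp) (a - 1L) * Wp + b else NA_integer_
        mergeIdx[t, ] <- c(at(rr, c2), at(rr, c2 + 1L), at(rr + 1L, c2),
                           at(rr + 1L, c2 + 1L))
      }
    } else { Ho <- Hp; Wo <- Wp; mergeIdx <- NULL }
    stages[[i]] <- list(cfg = cfg, Hg = Hg, Wg = Wg, Hp = Hp, Wp = Wp,
                        n = Hp * Wp, C = C, padRows = padRows,
                        comb = comb, invComb = invComb, masks = masks,
                        winPerImage = length(masks), W = M * M,
                        hasMerge = hasMerge, mergeIdx = mergeIdx,
                        Ho = Ho, Wo = Wo, Cout = if (hasMerge) 2L * C else C)
    Hg <- Ho; Wg <- Wo
    C <- stages[[i]]$Cout
  }
  finalN <- Hg * Wg
  list(T = targetSpatial, Cin = fusedChannels, p = p, pi = pi,
       Hg0 = pi$Hg, Wg0 = pi$Wg, n0 = pi$Hg * pi$Wg, d0 = pi$d,
       D = blocks[[1]]@embedDim, stages = stages,
       finalN = finalN, finalC = C,
       flatDim = if (readout == "cls") C else finalN * C)
}

#' Build the hybrid shifted-window transformer classifier
#'
#' Wires the frozen backbone ensemble to the encoder and head and
#' initializes all trainable parameters (truncated normal, sd 0.02, biases
#' zero; layer-norm gains one). By default two encoder blocks alternate
#' unshifted (W-MSA) and shifted (SW-MSA, shift = window/2) attention, each
#' followed by patch merging, and the flattened final tokens feed the head.
#'
#' @param ensemble an [EnsembleSpec-class] of runnable backbones.
#' @param blockConfig a [swinBlockConfig()] template (its shift is set per
#'   block by the alternation rule).
#' @param head a [headConfig()].
#' @param nClasses number of classes.
#' @param classes optional class labels (length nClasses).
#' @param nBlocks number of encoder blocks (default 2).
#' @param patchSize patch side p (default 2).
#' @param readout "flatten" (default, all final tokens) or "cls" (class
#'   token carried through the encoder and read out at index 0).
#' @param seed parameter-initialization seed.
#' @return A [WinShiftModel-class].
#' @export
buildModel <- function(ensemble, blockConfig = swinBlockConfig(),
                       head = headConfig(), nClasses = 3L, classes = NULL,
                       nBlocks = 2L, patchSize = 2L, readout = "flatten",
                       seed = 42L) {
  nClasses <- as.integer(nClasses)
  if (is.null(classes)) classes <- paste0("class", seq_len(nClasses))
  blocks <- lapply(seq_len(nBlocks) - 1L, function(i) {
    cfg <- blockConfig
    cfg@shift <- if (i %% 2L == 0L) 0L else cfg@window %/% 2L
    cfg
  })
  Cin <- fusedChannels(ensemble)
  layout <- computeLayout(ensemble@targetSpatial, Cin, as.integer(patchSize),
                          blocks, readout)
  D <- layout$D
  params <- withSeed(seed, {
    P <- list(
      epos = array(truncNormal(layout$T^2 * Cin), c(layout$T, layout$T, Cin)),
      embedW = initMatrix(layout$d0, D),
      embedb = numeric(D)
    )
    if (readout == "cls") P$cls <- matrix(truncNormal(D), 1, D)
    for (i in seq_along(blocks)) {
      C <- layout$stages[[i]]$C
      mlp <- blocks[[i]]@mlpNodes
      pre <- sprintf("b%d.", i)
      P[[paste0(pre, "ln1g")]] <- rep(1, C)
      P[[paste0(pre, "ln1b")]] <- numeric(C)
      for (w in c("Wq", "Wk", "Wv", "Wo"))
        P[[paste0(pre, w)]] <- initMatrix(C, C)
      for (b in c("bq", "bk", "bv", "bo"))
        P[[paste0(pre, b)]] <- numeric(C)
      P[[paste0(pre, "ln2g")]] <- rep(1, C)
      P[[paste0(pre, "ln2b")]] <- numeric(C)
      P[[paste0(pre, "mlpW1")]] <- initMatrix(C, mlp)
      P[[paste0(pre, "mlpb1")]] <- numeric(mlp)
      P[[paste0(pre, "mlpW2")]] <- initMatrix(mlp, C)
      P[[paste0(pre, "mlpb2")]] <- numeric(C)
      if (layout$stages[[i]]$hasMerge) {
        P[[paste0(pre, "mergeW")]] <- initMatrix(4L * C, 2L * C)
        P[[paste0(pre, "mergeb")]] <- numeric(2L * C)
        if (readout == "cls")
          P[[paste0(pre, "clsLift")]] <- initMatrix(C, 2L * C)
      }
    }
    FD <- layout$flatDim
    P$headW1 <- initMatrix(FD, head$units1)
    P$headb1 <- numeric(head$units1)
    P$headW2 <- initMatrix(head$units1, head$units2)
    P$headb2 <- numeric(head$units2)
    P$headW3 <- initMatrix(head$units2, nClasses)
    P$headb3 <- numeric(nClasses)
    P
  })
  new("WinShiftModel", ensemble = ensemble, blocks = blocks,
      patchSize = as.integer(patchSize), head = head, nClasses = nClasses,
      classes = classes, readout = readout, params = params,
      layout = layout, history = data.frame())
}

# replicate a per-image permutation across a batch
batchPerm <- function(perm, B, n) rep(perm, B) + rep((seq_len(B) - 1L) * n, each = length(perm))

# ---------------------------------------------------------------------------
# Full forward pass. fused: list of (T, T, Cin) arrays. Returns logits,
# probabilities, optional loss/gradient seed, and caches for the backward.
# ---------------------------------------------------------------------------
modelForward <- function(model, fused, y = NULL, training = FALSE) {
  P <- model@params
  L <- model@layout
  B <- length(fused)
  cls <- model@readout == "cls"
  tok <- vector("list", B)
  for (i in seq_len(B)) {
    stopIf(!all(dim(fused[[i]]) == c(L$T, L$T, L$Cin)),
           "fused map shape does not match the model")
    tok[[i]] <- patchPartition(fused[[i]] + P$epos, L$p)
  }
  X0 <- do.call(rbind, tok)
  emb <- denseForward(X0, P$embedW, P$embedb)
  X <- emb$out
  Xc <- if (cls) P$cls[rep(1, B), , drop = FALSE] else NULL
  caches <- list(B = B, emb = emb, stages = vector("list", length(L$stages)))
  n <- L$n0
  for (si in seq_along(L$stages)) {
    st <- L$stages[[si]]
    pre <- sprintf("b%d.", si)
    sc <- list()
    # stage-entry zero padding to a window-divisible grid
    if (!is.null(st$padRows)) {
      Xp <- matrix(0, B * st$n, st$C)
      rows <- batchPerm(st$padRows, B, st$n)
      Xp[rows, ] <- X
      sc$padRowsB <- rows
      X <- Xp
    }
    n <- st$n
    # --- attention sublayer ---
    ln1 <- lnForward(X, P[[paste0(pre, "ln1g")]], P[[paste0(pre, "ln1b")]])
    perm <- batchPerm(st$comb, B, n)
    iperm <- batchPerm(st$invComb, B, n)
    att <- attentionForward(ln1$out[perm, , drop = FALSE], st$cfg@heads,
                            P[[paste0(pre, "Wq")]], P[[paste0(pre, "bq")]],
                            P[[paste0(pre, "Wk")]], P[[paste0(pre, "bk")]],
                            P[[paste0(pre, "Wv")]], P[[paste0(pre, "bv")]],
                            P[[paste0(pre, "Wo")]], P[[paste0(pre, "bo")]],
                            st$masks, st$winPerImage, st$cfg@dropoutAttn,
                            training)
    blkdrop <- dropoutForward(att$out, st$cfg@dropoutBlock, training)
    branch <- blkdrop$out[iperm, , drop = FALSE]
    dp1 <- dropPathMask(B, st$cfg@dropPath, training)
    dp1row <- rep(dp1, each = n)
    X1 <- X + branch * dp1row
    # class token: singleton self-attention through the same projections
    if (cls) {
      c_ln1 <- lnForward(Xc, P[[paste0(pre, "ln1g")]], P[[paste0(pre, "ln1b")]])
      cV <- sweep(c_ln1$out %*% P[[paste0(pre, "Wv")]], 2,
                  P[[paste0(pre, "bv")]], "+")
      cAtt <- sweep(cV %*% P[[paste0(pre, "Wo")]], 2, P[[paste0(pre, "bo")]], "+")
      cDrop <- dropoutForward(cAtt, st$cfg@dropoutBlock, training)
      Xc1 <- Xc + cDrop$out * dp1
      sc$c_ln1 <- c_ln1$cache; sc$cV <- cV; sc$cDrop <- cDrop$cache
    }
    # --- MLP sublayer ---
    ln2 <- lnForward(X1, P[[paste0(pre, "ln2g")]], P[[paste0(pre, "ln2b")]])
    d1 <- denseForward(ln2$out, P[[paste0(pre, "mlpW1")]], P[[paste0(pre, "mlpb1")]])
    ge <- geluForward(d1$out)
    md1 <- dropoutForward(ge$out, st$cfg@dropoutMlp, training)
    d2 <- denseForward(md1$out, P[[paste0(pre, "mlpW2")]], P[[paste0(pre, "mlpb2")]])
    md2 <- dropoutForward(d2$out, st$cfg@dropoutMlp, training)
    dp2 <- dropPathMask(B, st$cfg@dropPath, training)
    dp2row <- rep(dp2, each = n)
    X2 <- X1 + md2$out * dp2row
    if (cls) {
      c_ln2 <- lnForward(Xc1, P[[paste0(pre, "ln2g")]], P[[paste0(pre, "ln2b")]])
      cd1 <- denseForward(c_ln2$out, P[[paste0(pre, "mlpW1")]], P[[paste0(pre, "mlpb1")]])
      cge <- geluForward(cd1$out)
      cd2 <- denseForward(cge$out, P[[paste0(pre, "mlpW2")]], P[[paste0(pre, "mlpb2")]])
      Xc2 <- Xc1 + cd2$out * dp2
      sc$c_ln2 <- c_ln2$cache; sc$cd1 <- cd1$cache; sc$cge <- cge$cache
      sc$cd2 <- cd2$cache; sc$Xc1 <- Xc1
    }
    # --- patch merging ---
    if (st$hasMerge) {
      no <- nrow(st$mergeIdx)
      gath <- matrix(0, B * no, 4L * st$C)
      for (q in 1:4) {
        src <- st$mergeIdx[, q]
        ok <- !is.na(src)
        rows <- batchPerm(ifelse(ok, src, 1L), B, n)
        blockv <- X2[rows, , drop = FALSE]
        if (any(!ok)) blockv[rep(!ok, B), ] <- 0
        gath[, (q - 1L) * st$C + seq_len(st$C)] <- blockv
      }
      mg <- denseForward(gath, P[[paste0(pre, "mergeW")]], P[[paste0(pre, "mergeb")]])
      Xout <- mg$out
      if (cls) {
        XcOut <- Xc2 %*% P[[paste0(pre, "clsLift")]]
        sc$Xc2 <- Xc2
      }
      sc$mg <- mg$cache
      n <- no
    } else {
      Xout <- X2
      if (cls) XcOut <- Xc2
    }
    sc$ln1 <- ln1$cache; sc$att <- att$cache; sc$blkdrop <- blkdrop$cache
    sc$perm <- perm; sc$iperm <- iperm; sc$dp1row <- dp1row; sc$dp1 <- dp1
    sc$ln2 <- ln2$cache; sc$d1 <- d1$cache; sc$ge <- ge$cache
    sc$md1 <- md1$cache; sc$d2 <- d2$cache; sc$md2 <- md2$cache
    sc$dp2row <- dp2row; sc$dp2 <- dp2; sc$n <- n
    caches$stages[[si]] <- sc
    X <- Xout
    if (cls) Xc <- XcOut
  }
  # readout
  if (cls) {
    fln <- lnForward(Xc, rep(1, ncol(Xc)), numeric(ncol(Xc)))
    FEAT <- fln$out
    caches$fln <- fln$cache
  } else {
    nf <- L$finalN; Cf <- L$finalC
    FEAT <- matrix(0, B, nf * Cf)
    for (i in seq_len(B))
      FEAT[i, ] <- as.vector(t(X[(i - 1L) * nf + seq_len(nf), , drop = FALSE]))
  }
  caches$Xfinal_dim <- dim(X)
  h1 <- denseForward(FEAT, P$headW1, P$headb1)
  r1 <- reluForward(h1$out)
  hd1 <- dropoutForward(r1$out, model@head$dropout1, training)
  h2 <- denseForward(hd1$out, P$headW2, P$headb2)
  r2 <- reluForward(h2$out)
  hd2 <- dropoutForward(r2$out, model@head$dropout2, training)
  h3 <- denseForward(hd2$out, P$headW3, P$headb3)
  logits <- h3$out
  caches <- c(caches, list(h1 = h1$cache, r1 = r1$cache, hd1 = hd1$cache,
                           h2 = h2$cache, r2 = r2$cache, hd2 = hd2$cache,
                           h3 = h3$cache, FEAT = FEAT))
  out <- list(logits = logits, probs = rowSoftmax(logits), caches = caches)
  if (!is.null(y)) {
    sce <- softmaxCrossEntropy(logits, y)
    out$loss <- sce$loss
    out$dlogits <- sce$dlogits
    out$probs <- sce$probs
  }
  out
}

# ---------------------------------------------------------------------------
# Full backward pass. dlogits seeds the chain; returns flat named gradient
# list and, when inputGrad, the gradient at each fused input map.
# ---------------------------------------------------------------------------
modelBackward <- function(model, caches, dlogits, inputGrad = FALSE) {
  P <- model@params
  L <- model@layout
  B <- caches$B
  cls <- model@readout == "cls"
  G <- list()
  bk <- denseBackward(dlogits, caches$h3)
  G$headW3 <- bk$dW; G$headb3 <- bk$db
  d <- dropoutBackward(bk$dX, caches$hd2)
  d <- reluBackward(d, caches$r2)
  bk <- denseBackward(d, caches$h2)
  G$headW2 <- bk$dW; G$headb2 <- bk$db
  d <- dropoutBackward(bk$dX, caches$hd1)
  d <- reluBackward(d, caches$r1)
  bk <- denseBackward(d, caches$h1)
  G$headW1 <- bk$dW; G$headb1 <- bk$db
  dFEAT <- bk$dX
  if (cls) {
    lb <- lnBackward(dFEAT, caches$fln)
    dXc <- lb$dX
    dX <- matrix(0, caches$Xfinal_dim[1], caches$Xfinal_dim[2])
  } else {
    nf <- L$finalN; Cf <- L$finalC
    dX <- matrix(0, B * nf, Cf)
    for (i in seq_len(B))
      dX[(i - 1L) * nf + seq_len(nf), ] <-
        matrix(dFEAT[i, ], nf, Cf, byrow = TRUE)
    dXc <- NULL
  }
  for (si in rev(seq_along(L$stages))) {
    st <- L$stages[[si]]
    sc <- caches$stages[[si]]
    pre <- sprintf("b%d.", si)
    n <- st$n
    if (st$hasMerge) {
      if (cls) {
        G[[paste0(pre, "clsLift")]] <- t(sc$Xc2) %*% dXc
        dXc <- dXc %*% t(P[[paste0(pre, "clsLift")]])
      }
      bk <- denseBackward(dX, sc$mg)
      G[[paste0(pre, "mergeW")]] <- bk$dW
      G[[paste0(pre, "mergeb")]] <- bk$db
      dGath <- bk$dX
      dX2 <- matrix(0, B * n, st$C)
      for (q in 1:4) {
        src <- st$mergeIdx[, q]
        ok <- !is.na(src)
        rows <- batchPerm(ifelse(ok, src, 1L), B, n)
        dpart <- dGath[, (q - 1L) * st$C + seq_len(st$C), drop = FALSE]
        if (any(!ok)) dpart[rep(!ok, B), ] <- 0
        # each source token feeds exactly one merge output, so plain assign
        dX2[rows[rep(ok, B)], ] <- dX2[rows[rep(ok, B)], ] +
          dpart[rep(ok, B), , drop = FALSE]
      }
      dX <- dX2
    }
    # MLP sublayer backward
    dBranch <- dX * sc$dp2row
    dBranch <- dropoutBackward(dBranch, sc$md2)
    bk <- denseBackward(dBranch, sc$d2)
    G[[paste0(pre, "mlpW2")]] <- bk$dW
    G[[paste0(pre, "mlpb2")]] <- bk$db
    dmid <- dropoutBackward(bk$dX, sc$md1)
    dmid <- geluBackward(dmid, sc$ge)
    bk <- denseBackward(dmid, sc$d1)
    G[[paste0(pre, "mlpW1")]] <- bk$dW
    G[[paste0(pre, "mlpb1")]] <- bk$db
    lb <- lnBackward(bk$dX, sc$ln2)
    G[[paste0(pre, "ln2g")]] <- lb$dg
    G[[paste0(pre, "ln2b")]] <- lb$db
    dX1 <- dX + lb$dX
    if (cls) {
      dcB <- dXc * sc$dp2
      bk <- denseBackward(dcB, sc$cd2)
      G[[paste0(pre, "mlpW2")]] <- G[[paste0(pre, "mlpW2")]] + bk$dW
      G[[paste0(pre, "mlpb2")]] <- G[[paste0(pre, "mlpb2")]] + bk$db
      dcg <- geluBackward(bk$dX, sc$cge)
      bk <- denseBackward(dcg, sc$cd1)
      G[[paste0(pre, "mlpW1")]] <- G[[paste0(pre, "mlpW1")]] + bk$dW
      G[[paste0(pre, "mlpb1")]] <- G[[paste0(pre, "mlpb1")]] + bk$db
      lb <- lnBackward(bk$dX, sc$c_ln2)
      G[[paste0(pre, "ln2g")]] <- G[[paste0(pre, "ln2g")]] + lb$dg
      G[[paste0(pre, "ln2b")]] <- G[[paste0(pre, "ln2b")]] + lb$db
      dXc1 <- dXc + lb$dX
    }
    # attention sublayer backward
    dBranch <- dX1 * sc$dp1row
    dPermBranch <- dropoutBackward(dBranch[sc$perm, , drop = FALSE], sc$blkdrop)
    ab <- attentionBackward(dPermBranch, sc$att)
    for (w in c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo"))
      G[[paste0(pre, w)]] <- ab[[paste0("d", w)]]
    dLn1out <- matrix(0, nrow(ab$dX), ncol(ab$dX))
    dLn1out[sc$perm, ] <- ab$dX
    lb <- lnBackward(dLn1out, sc$ln1)
    G[[paste0(pre, "ln1g")]] <- lb$dg
    G[[paste0(pre, "ln1b")]] <- lb$db
    dX <- dX1 + lb$dX
    if (cls) {
      dcA <- dXc1 * sc$dp1
      dcA <- dropoutBackward(dcA, sc$cDrop)
      G[[paste0(pre, "Wo")]] <- G[[paste0(pre, "Wo")]] + t(sc$cV) %*% dcA
      G[[paste0(pre, "bo")]] <- G[[paste0(pre, "bo")]] + colSums(dcA)
      dcV <- dcA %*% t(P[[paste0(pre, "Wo")]])
      c_ln1_out <- sweep(sweep(sc$c_ln1$xhat, 2, P[[paste0(pre, "ln1g")]], "*"),
                         2, P[[paste0(pre, "ln1b")]], "+")
      G[[paste0(pre, "Wv")]] <- G[[paste0(pre, "Wv")]] + t(c_ln1_out) %*% dcV
      G[[paste0(pre, "bv")]] <- G[[paste0(pre, "bv")]] + colSums(dcV)
      lb <- lnBackward(dcV %*% t(P[[paste0(pre, "Wv")]]), sc$c_ln1)
      G[[paste0(pre, "ln1g")]] <- G[[paste0(pre, "ln1g")]] + lb$dg
      G[[paste0(pre, "ln1b")]] <- G[[paste0(pre, "ln1b")]] + lb$db
      dXc <- dXc1 + lb$dX
    }
    # undo stage-entry padding
    if (!is.null(sc$padRowsB)) dX <- dX[sc$padRowsB, , drop = FALSE]
  }
  bk <- denseBackward(dX, caches$emb$cache)
  G$embedW <- bk$dW
  G$embedb <- bk$db
  if (cls) G$cls <- colSums(dXc)
  dX0 <- bk$dX
  n0 <- L$n0
  G$epos <- array(0, dim(P$epos))
  dInput <- if (inputGrad) vector("list", B) else NULL
  for (i in seq_len(B)) {
    dtok <- dX0[(i - 1L) * n0 + seq_len(n0), , drop = FALSE]
    dmap <- patchUnpartition(dtok, c(L$T, L$T, L$Cin), L$p)
    G$epos <- G$epos + dmap
    if (inputGrad) dInput[[i]] <- dmap
  }
  list(grads = G, dInput = dInput)
}

#' Encoder forward pass on a fused feature map
#'
#' Runs position embedding, patch partition, linear embedding, the encoder
#' blocks and patch merging in evaluation mode and returns the final
#' flattened token sequence (the head input).
#'
#' @param model a [WinShiftModel-class].
#' @param map fused array (targetSpatial, targetSpatial, fusedChannels).
#' @return the readout feature vector for the map.
#' @export
encoderForward <- function(model, map) {
  fw <- modelForward(model, list(map), training = FALSE)
  as.vector(fw$caches$FEAT[1, ])
}

#' Predict class probabilities and labels
#'
#' Evaluation-mode forward pass (dropout and drop-path disabled); two calls
#' on the same input are bit-identical. Probability rows sum to one.
#'
#' @param object a [WinShiftModel-class].
#' @param newdata an [ImageSet-class] of processed 224 x 224 x 3 images, or
#'   a list of fused feature maps.
#' @param ... unused.
#' @return list with `probabilities` (n x K matrix) and `labels` (factor).
#' @export
setMethod("predict", "WinShiftModel", function(object, newdata, ...) {
  fused <- if (is(newdata, "ImageSet")) {
    lapply(newdata@images, fuseFeatures, ensemble = object@ensemble)
  } else newdata
  probs <- matrix(0, length(fused), object@nClasses)
  bs <- 32L
  for (at in seq(1L, length(fused), by = bs)) {
    idx <- at:min(at + bs - 1L, length(fused))
    fw <- modelForward(object, fused[idx], training = FALSE)
    probs[idx, ] <- fw$probs
  }
  colnames(probs) <- object@classes
  labs <- factor(object@classes[max.col(probs, ties.method = "first")],
                 levels = object@classes)
  list(probabilities = probs, labels = labs)
})
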