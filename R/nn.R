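# Forward/backward numerical kernels. Every forward returns the output plus
# a cache; the matching backward consumes the upstream gradient and the
# cache and returns gradients for inputs and parameters. Verified against
# finite differences in the test suite.

LN_EPS <- 1e-5

lnForward <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  Y <- sweep(sweep(xhat, 2, g, "*"), 2, b, "+")
  list(out = Y, cache = list(xhat = xhat, inv = inv, g = g))
}

lnBackward <- function(dY, cache) {
  xhat <- cache$xhat; inv <- cache$inv
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- sweep(dY, 2, cache$g, "*")
  dX <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = dg, db = db)
}

denseForward <- function(X, W, b) {
  list(out = sweep(X %*% W, 2, b, "+"), cache = list(X = X, W = W))
}

denseBackward <- function(dY, cache) {
  list(dX = dY %*% t(cache$W), dW = t(cache$X) %*% dY, db = colSums(dY))
}

geluForward <- function(X) {
  P <- stats::pnorm(X)
  list(out = X * P, cache = list(X = X, P = P))
}

geluBackward <- function(dY, cache) {
  dY * (cache$P + cache$X * stats::dnorm(cache$X))
}

reluForward <- function(X) list(out = pmax(X, 0), cache = X > 0)
reluBackward <- function(dY, cache) dY * cache

# inverted dropout; identity when not training or rate 0
dropoutForward <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(out = X, cache = NULL))
  keep <- matrix(stats::runif(length(X)) >= rate, nrow(X), ncol(X)) / (1 - rate)
  list(out = X * keep, cache = keep)
}

dropoutBackward <- function(dY, cache) if (is.null(cache)) dY else dY * cache

# per-sample stochastic depth: rows of each sample share one keep mask
dropPathMask <- function(B, rate, training) {
  if (!training || rate <= 0) return(rep(1, B))
  (stats::runif(B) >= rate) / (1 - rate)
}

# ---------------------------------------------------------------------------
# Windowed multi-head attention over a pre-permuted (G windows x W rows)
# token matrix. masks: list of W x W matrices indexed by window-within-image.
# ---------------------------------------------------------------------------

attentionForward <- function(Xw, heads, Wq, bq, Wk, bk, Wv, bv, Wo, bo,
                             masks, winPerImage, attnDrop, training) {
  C <- ncol(Xw); n <- nrow(Xw)
  W <- nrow(masks[[1]])
  G <- n %/% W
  dh <- C %/% heads
  Q <- sweep(Xw %*% Wq, 2, bq, "+")
  K <- sweep(Xw %*% Wk, 2, bk, "+")
  V <- sweep(Xw %*% Wv, 2, bv, "+")
  O <- matrix(0, n, C)
  Acache <- vector("list", G * heads)
  Dcache <- vector("list", G * heads)
  for (g in seq_len(G)) {
    rows <- (g - 1L) * W + seq_len(W)
    mask <- masks[[(g - 1L) %% winPerImage + 1L]]
    for (h in seq_len(heads)) {
      cols <- (h - 1L) * dh + seq_len(dh)
      S <- Q[rows, cols, drop = FALSE] %*% t(K[rows, cols, drop = FALSE]) /
        sqrt(dh) + mask
      A <- rowSoftmax(S)
      dr <- dropoutForward(A, attnDrop, training)
      Acache[[(g - 1L) * heads + h]] <- A
      Dcache[(g - 1L) * heads + h] <- list(dr$cache)
      O[rows, cols] <- dr$out %*% V[rows, cols, drop = FALSE]
    }
  }
  out <- sweep(O %*% Wo, 2, bo, "+")
  list(out = out,
       cache = list(Xw = Xw, Q = Q, K = K, V = V, O = O, A = Acache,
                    D = Dcache, heads = heads, dh = dh, W = W, G = G,
                    Wq = Wq, Wk = Wk, Wv = Wv, Wo = Wo))
}

attentionBackward <- function(dOut, cache) {
  with(cache, {
    dWo <- t(O) %*% dOut
    dbo <- colSums(dOut)
    dO <- dOut %*% t(Wo)
    dQ <- matrix(0, nrow(Xw), ncol(Xw))
    dK <- dQ; dV <- dQ
    for (g in seq_len(G)) {
      rows <- (g - 1L) * W + seq_len(W)
      for (h in seq_len(heads)) {
        cols <- (h - 1L) * dh + seq_len(dh)
        i <- (g - 1L) * heads + h
        Ag <- A[[i]]; keep <- D[[i]]
        Ad <- if (is.null(keep)) Ag else Ag * keep
        dOg <- dO[rows, cols, drop = FALSE]
        dAd <- dOg %*% t(V[rows, cols, drop = FALSE])
        dV[rows, cols] <- dV[rows, cols] + t(Ad) %*% dOg
        dA <- if (is.null(keep)) dAd else dAd * keep
        dS <- Ag * (dA - rowSums(Ag * dA))
        dS <- dS / sqrt(dh)
        dQ[rows, cols] <- dQ[rows, cols] +
          dS %*% K[rows, cols, drop = FALSE]
        dK[rows, cols] <- dK[rows, cols] +
          t(dS) %*% Q[rows, cols, drop = FALSE]
      }
    }
    dXw <- dQ %*% t(Wq) + dK %*% t(Wk) + dV %*% t(Wv)
    list(dX = dXw,
         dWq = t(Xw) %*% dQ, dbq = colSums(dQ),
         dWk = t(Xw) %*% dK, dbk = colSums(dK),
         dWv = t(Xw) %*% dV, dbv = colSums(dV),
         dWo = dWo, dbo = dbo)
  })
}

# softmax + categorical cross-entropy; labels are 1-based class indices
softmaxCrossEntropy <- function(logits, y) {
  P <- rowSoftmax(logits)
  n <- nrow(P)
  eps <- 1e-12
  loss <- -mean(log(P[cbind(seq_len(n), y)] + eps))
  dlogits <- P
  dlogits[cbind(seq_len(n), y)] <- dlogits[cbind(seq_len(n), y)] - 1
  list(loss = loss, probs = P, dlogits = dlogits / n)
}
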