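test_that("position embedding adds per-position values and preserves shape", {
  m <- array(runif(4 * 4 * 3), c(4, 4, 3))
  e <- array(runif(4 * 4 * 3), c(4, 4, 3))
  expect_equal(addPositionEmbedding(m, array(0, dim(m))), m)
  expect_equal(addPositionEmbedding(array(0, dim(e)), e), e)
  expect_equal(dim(addPositionEmbedding(m, e)), dim(m))
  expect_error(addPositionEmbedding(m, array(0, c(3, 3, 3))), "mismatch")
})

test_that("patch partition produces the documented token geometry and round-trips", {
  m <- array(seq_len(2 * 2 * 3), c(2, 2, 3))
  tok <- patchPartition(m, 2)
  expect_equal(dim(tok), c(1, 12))
  # pixels row-major within the patch, channels fastest
  expect_equal(as.vector(tok),
               c(m[1, 1, ], m[1, 2, ], m[2, 1, ], m[2, 2, ]))
  m2 <- array(rnorm(4 * 4 * 5), c(4, 4, 5))
  tok2 <- patchPartition(m2, 2)
  expect_equal(dim(tok2), c(4, 20))
  expect_equal(patchUnpartition(tok2), m2)
})

test_that("the published fused map partitions into 36 tokens of 22,016 features", {
  fused <- array(rnorm(12 * 12 * 5504), c(12, 12, 5504))
  tok <- patchPartition(fused, 2)
  expect_equal(dim(tok), c(36, 22016))
  E <- matrix(rnorm(22016 * 96, 0, 0.01), 22016, 96)
  emb <- linearEmbed(tok, E)
  expect_equal(dim(emb), c(36, 96))
})

test_that("linear embedding honors identity and selection properties", {
  tok <- matrix(rnorm(6 * 8), 6, 8)
  expect_equal(linearEmbed(tok, diag(8)), tok)
  e3 <- matrix(0, 8, 1); e3[3, 1] <- 1
  expect_equal(as.vector(linearEmbed(tok, e3)), tok[, 3])
  expect_error(linearEmbed(tok, diag(5)), "match")
})

test_that("window partition and its reverse are exact inverses", {
  g <- randomGrid(6, 6, 3)
  wins <- windowPartition(g, 2)
  expect_length(wins, 9)
  expect_true(all(vapply(wins, nrow, integer(1)) == 4))
  expect_equal(windowReverse(wins, 6, 6, 2), g)
  # window side equal to the grid side puts everything in one window
  wins1 <- windowPartition(g, 6)
  expect_length(wins1, 1)
  expect_equal(nrow(wins1[[1]]), 36)
})

test_that("cyclic shift rolls with wrap-around and inverts exactly", {
  g <- randomGrid(6, 6, 2)
  expect_identical(cyclicShift(g, 0), g)
  sh <- cyclicShift(g, 1)
  # token at (1, 1) moves to (6, 6) under a (-1, -1) roll
  expect_equal(sh[6, 6, ], g[1, 1, ])
  expect_equal(sh[1, 1, ], g[2, 2, ])
  expect_equal(cyclicShift(sh, 1, inverse = TRUE), g)
})

test_that("shift masks block exactly the cross-region pairs", {
  masks <- buildShiftMask(6, 6, 2, 1)
  # interior windows see one contiguous region: all-zero mask
  expect_true(all(masks[[1]] == 0))
  expect_true(all(masks[[2]] == 0))
  # 4 x 4 grid, M = 2, s = 1: bottom-right window mixes 4 regions, so only
  # the diagonal survives (brute-force region-id oracle)
  m4 <- buildShiftMask(4, 4, 2, 1)
  br <- m4[[4]]
  expect_equal(sum(br == 0), 4)
  expect_true(all(diag(br) == 0))
  expect_true(all(br[br != 0] == -1e9))
  # blocking pattern is symmetric; s = 0 gives all-zero masks
  expect_true(all(vapply(m4, function(m) isTRUE(all.equal(m, t(m))), logical(1))))
  expect_true(all(buildShiftMask(4, 4, 2, 0)[[1]] == 0))
})

test_that("masked attention equals attention computed per contiguous region", {
  # one shifted window containing two pre-shift regions
  C <- 4L
  p <- randomAttnParams(C, seed = 2)
  cfg <- swinBlockConfig(window = 2L, shift = 1L, heads = 1L, embedDim = C,
                         mlpNodes = 4L)
  g <- randomGrid(2, 2, C, seed = 3)
  out <- windowedAttention(g, cfg, p)
  # with Hg = Wg = M = 2 and s = 1 every token is its own region, so
  # attention reduces to per-token (softmax over itself = 1)
  X <- winshift:::gridToSeq(g)
  V <- sweep(X %*% p$Wv, 2, p$bv, "+")
  expected <- sweep(V %*% p$Wo, 2, p$bo, "+")
  expect_equal(winshift:::gridToSeq(out), expected, tolerance = 1e-8)
})

test_that("single-token windows and uniform scores reduce to closed forms", {
  C <- 4L
  X <- matrix(rnorm(C), 1, C)
  id <- diag(C); z <- numeric(C)
  # softmax over a single key is 1: output is the value projection
  out <- windowAttention(list(X), 1L, Wq = id, Wk = id, Wv = id, Wo = id)
  expect_equal(out[[1]], X)
  # all-equal scores average the values
  Xw <- matrix(rnorm(4 * C), 4, C)
  out2 <- windowAttention(list(Xw), 1L, Wq = matrix(0, C, C),
                          Wk = matrix(0, C, C), Wv = id, Wo = id)
  expect_equal(out2[[1]], matrix(colMeans(Xw), 4, C, byrow = TRUE),
               tolerance = 1e-10)
})

test_that("permuting windows permutes attention outputs identically", {
  C <- 6L
  p <- randomAttnParams(C, seed = 5)
  wins <- lapply(1:4, function(i) matrix(rnorm(4 * C), 4, C))
  out <- windowAttention(wins, 2L, p$Wq, p$Wk, p$Wv, p$Wo)
  perm <- c(3, 1, 4, 2)
  outPerm <- windowAttention(wins[perm], 2L, p$Wq, p$Wk, p$Wv, p$Wo)
  expect_equal(outPerm, out[perm])
})

test_that("a zero-weight block is the identity and blocks preserve shape", {
  cfg <- swinBlockConfig(window = 2L, shift = 0L, heads = 4L, embedDim = 96L,
                         mlpNodes = 24L, dropoutMlp = 0, dropoutAttn = 0,
                         dropoutBlock = 0, dropPath = 0)
  g <- randomGrid(6, 6, 96, seed = 1)
  zeroP <- initSwinBlockParams(cfg, zero = TRUE)
  expect_equal(swinBlock(g, cfg, zeroP), g, tolerance = 1e-10)
  out <- swinBlock(g, cfg)
  expect_equal(dim(out), c(6, 6, 96))
})

test_that("constant grids are invariant to the shift choice", {
  cfgA <- smallBlockConfig(window = 2L, shift = 0L)
  cfgB <- smallBlockConfig(window = 2L, shift = 1L)
  g <- array(0.7, c(4, 4, 16))
  p <- initSwinBlockParams(cfgA, seed = 11)
  expect_equal(swinBlock(g, cfgA, p), swinBlock(g, cfgB, p), tolerance = 1e-8)
})

test_that("patch merging halves the grid and doubles the channels", {
  g <- randomGrid(6, 6, 96, seed = 2)
  W <- matrix(rnorm(384 * 192, 0, 0.05), 384, 192)
  out <- patchMerging(g, W)
  expect_equal(dim(out), c(3, 3, 192))
  # degenerate 1 x 1 grid passes through
  g1 <- randomGrid(1, 1, 8)
  expect_identical(patchMerging(g1, matrix(0, 32, 16)), g1)
  # averaging reduction on block-constant grids reproduces the constants
  C <- 2L
  gg <- array(0, c(4, 4, C))
  vals <- matrix(rnorm(4 * C), 4, C)  # one constant vector per 2x2 block
  for (br in 1:2) for (bc in 1:2) for (k in seq_len(C))
    gg[2 * br - 1:0, 2 * bc - 1:0, k] <- vals[(br - 1) * 2 + bc, k]
  Wavg <- matrix(0, 4 * C, 2 * C)
  for (k in seq_len(C)) for (q in 1:4) {
    Wavg[(q - 1) * C + k, k] <- 0.25       # first C outputs: block mean
    Wavg[(q - 1) * C + k, C + k] <- 0.25   # duplicated in the second half
  }
  out2 <- patchMerging(gg, Wavg)
  for (b in 1:4)
    expect_equal(out2[(b - 1) %/% 2 + 1, (b - 1) %% 2 + 1, ],
                 rep(vals[b, ], 2), tolerance = 1e-12)
})

test_that("the default encoder reproduces the published dimension chain", {
  m <- buildModel(ensembleA(), swinBlockConfig(), headConfig(), nClasses = 3L,
                  seed = 1)
  L <- m@layout
  expect_equal(L$Cin, 5504L)       # fused channels
  expect_equal(L$n0, 36L)          # token count after partition
  expect_equal(L$d0, 22016L)       # raw token dimension
  expect_equal(L$D, 96L)           # embedded dimension
  # grid chain 6x6x96 -> merge 3x3x192 -> pad 4x4 -> merge 2x2x384
  expect_equal(c(L$stages[[1]]$Hp, L$stages[[1]]$Wp, L$stages[[1]]$C),
               c(6L, 6L, 96L))
  expect_equal(c(L$stages[[2]]$Hg, L$stages[[2]]$Wg), c(3L, 3L))
  expect_equal(c(L$stages[[2]]$Hp, L$stages[[2]]$Wp), c(4L, 4L))
  expect_equal(c(L$finalN, L$finalC), c(4L, 384L))
  expect_equal(L$flatDim, 1536L)
  fused <- array(rnorm(12 * 12 * 5504, 0, 0.1), c(12, 12, 5504))
  expect_length(encoderForward(m, fused), 1536L)
})

test_that("zero-weight blocks reduce the encoder to its residual/merge skeleton", {
  m <- smallModel(seed = 5)
  # zero the attention/MLP weights of both blocks: each block becomes the
  # identity (pure residual path), so the encoder output is just the two
  # patch merges of the embedded tokens
  for (nm in names(m@params))
    if (grepl("^b[0-9]+\\.(W[qkvo]|b[qkvo]|mlp)", nm)) m@params[[nm]][] <- 0
  fused <- randomFused(m, 1)[[1]]
  out <- encoderForward(m, fused)
  emb <- linearEmbed(patchPartition(fused + m@params$epos, 2),
                     m@params$embedW, m@params$embedb)
  g <- winshift:::seqToGrid(emb, 4, 4)
  g <- patchMerging(g, m@params$`b1.mergeW`, m@params$`b1.mergeb`)
  g <- patchMerging(g, m@params$`b2.mergeW`, m@params$`b2.mergeb`)
  expect_equal(out, as.vector(winshift:::gridToSeq(g)[1, ]), tolerance = 1e-10)
})

test_that("doubling the input doubles the pre-normalization embedding stream", {
  m <- smallModel(seed = 6)
  m@params$epos[] <- 0
  fused <- randomFused(m, 1)[[1]]
  t1 <- linearEmbed(patchPartition(fused, 2), m@params$embedW)
  t2 <- linearEmbed(patchPartition(fused * 2, 2), m@params$embedW)
  expect_equal(t2, t1 * 2, tolerance = 1e-12)
})

test_that("attention complexity formulas evaluate exactly and scale as stated", {
  expect_equal(complexityMsa(6, 6, 96), 1575936)
  expect_equal(complexityMsa(1, 1, 1), 6)
  expect_equal(complexityWmsa(6, 6, 96, 2), 1354752)
  # h = w = M makes windowed and global attention coincide
  for (M in c(2, 4, 7))
    expect_equal(complexityWmsa(M, M, 32, M), complexityMsa(M, M, 32))
  expect_error(complexityWmsa(2, 2, 8, 4), "M must not")
})
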