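
test_that("confusion counts are exact, transpose under argument swap", {
  truev <- c(1, 1, 2, 3, 3, 3)
  predv <- c(1, 2, 2, 3, 3, 1)
  cm <- confusion(truev, predv, classes = c("a", "b", "c"))
  expect_equal(sum(cm@counts), 6)
  expect_equal(cm@counts[1, ], c(1L, 1L, 0L))
  expect_equal(cm@counts[3, ], c(1L, 0L, 2L))
  cmT <- confusion(predv, truev, classes = c("a", "b", "c"))
  expect_equal(cmT@counts, t(cm@counts))
  # perfect predictions give a diagonal matrix
  cmP <- confusion(truev, truev, classes = c("a", "b", "c"))
  expect_true(all(cmP@counts[row(cmP@counts) != col(cmP@counts)] == 0))
  expect_error(confusion(c(1, 4), c(1, 1), classes = c("a", "b")),
               "out of range")
})

test_that("the published held-out confusion reproduces the printed metrics", {
  cm <- paperConfusion()
  expect_equal(sum(cm@counts), 307L)
  off <- cm@counts[row(cm@counts) != col(cm@counts)]
  expect_equal(sort(off), c(rep(0L, 4), 1L, 1L))
  rep <- classificationReport(cm)
  men <- rep$perClass[rep$perClass$class == "meningioma", ]
  expect_equal(men$precision, 142 / 143, tolerance = 1e-12)
  expect_equal(men$sensitivity, 142 / 143, tolerance = 1e-12)
  expect_equal(round(men$f1, 4), 0.9930)
  gli <- rep$perClass[rep$perClass$class == "glioma", ]
  expect_equal(round(gli$f1, 4), 0.9859)
  expect_equal(gli$f1, 140 / 142, tolerance = 1e-12)
  pit <- rep$perClass[rep$perClass$class == "pituitary", ]
  expect_equal(pit$precision, 1); expect_equal(pit$f1, 1)
  expect_equal(rep$accuracy, 305 / 307, tolerance = 1e-12)
  expect_equal(round(100 * rep$accuracy, 2), 99.35)  # 99.34 as printed is truncated
})

test_that("metrics agree with a brute-force per-sample counting oracle", {
  withr::with_seed(13, {
    for (rep_i in 1:5) {
      K <- sample(2:5, 1)
      n <- 100
      truev <- sample(K, n, replace = TRUE)
      predv <- sample(K, n, replace = TRUE)
      cm <- confusion(truev, predv, classes = as.character(seq_len(K)))
      rp <- classificationReport(cm)
      for (k in seq_len(K)) {
        tp <- sum(truev == k & predv == k)
        fp <- sum(truev != k & predv == k)
        fn <- sum(truev == k & predv != k)
        tn <- sum(truev != k & predv != k)
        expect_equal(tp + tn + fp + fn, n)
        row <- rp$perClass[k, ]
        expect_equal(row$precision, if (tp + fp == 0) 0 else tp / (tp + fp))
        expect_equal(row$sensitivity, if (tp + fn == 0) 0 else tp / (tp + fn))
        expect_equal(row$f1, if (2 * tp + fp + fn == 0) 0 else
          2 * tp / (2 * tp + fp + fn))
        expect_equal(row$accuracyOvR, (tp + tn) / n)
      }
      expect_equal(rp$accuracy, mean(truev == predv))
    }
  })
})

test_that("one-vs-rest accuracy equals overall accuracy on one-error-per-class matrices", {
  # balanced cyclic single-error matrix: each class loses one to the next
  K <- 3; nPer <- 10
  cm <- diag(rep(nPer - 1L, K))
  for (k in seq_len(K)) cm[k, k %% K + 1] <- 1L
  obj <- new("ConfusionMatrix", counts = cm, classes = letters[1:K])
  rp <- classificationReport(obj)
  micro <- with(perClassCounts(obj), sum(TP) / (sum(TP) + sum(FP)))
  expect_equal(rp$accuracy, micro)
})

test_that("a never-predicted class reports precision 0 with a warning", {
  cm <- confusion(c(1, 1, 2, 2), c(1, 1, 1, 1), classes = c("a", "b"))
  expect_warning(rp <- classificationReport(cm), "never predicted")
  expect_equal(rp$perClass$precision[2], 0)
})

test_that("ROC endpoints behave as the theory says", {
  # perfectly separated scores
  truev <- c(1, 1, 2, 2)
  probs <- rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.2, 0.8), c(0.1, 0.9))
  r <- rocAuc(truev, probs, classes = c("a", "b"))
  expect_equal(unname(r$auc), c(1, 1))
  # label-independent scores hover at 0.5 for large n
  withr::with_seed(5, {
    n <- 4000
    truev <- sample(2, n, replace = TRUE)
    p1 <- runif(n)
    probs <- cbind(p1, 1 - p1)
    r2 <- rocAuc(truev, probs, classes = c("a", "b"))
    expect_equal(unname(r2$auc[1]), 0.5, tolerance = 0.05)
  })
})

test_that("AUC equals the Mann-Whitney pair-counting statistic", {
  # 4 hand-listed samples; exhaustive pair counting oracle
  truev <- c(1, 2, 1, 2)
  score1 <- c(0.7, 0.6, 0.4, 0.2)   # class-1 scores
  probs <- cbind(score1, 1 - score1)
  pos <- which(truev == 1); neg <- which(truev == 2)
  pairs <- expand.grid(p = pos, n = neg)
  u <- sum(score1[pairs$p] > score1[pairs$n]) +
    0.5 * sum(score1[pairs$p] == score1[pairs$n])
  oracle <- u / (length(pos) * length(neg))
  r <- rocAuc(truev, probs, classes = c("a", "b"))
  expect_equal(unname(r$auc[1]), oracle)
  # invariance under strictly monotone transforms of the scores
  probs2 <- cbind(plogis(5 * score1), 1 - plogis(5 * score1))
  r2 <- rocAuc(truev, probs2 / rowSums(probs2), classes = c("a", "b"))
  expect_equal(unname(r2$auc[1]), oracle)
})

test_that("AUC matches an independent ROC implementation on random data", {
  skip_if_not_installed("pROC")
  withr::with_seed(8, {
    n <- 60
    truev <- sample(2, n, replace = TRUE)
    s <- runif(n)
    probs <- cbind(s, 1 - s)
    r <- rocAuc(truev, probs, classes = c("a", "b"))
    ref <- suppressMessages(pROC::auc(pROC::roc(truev == 1, s)))
    expect_equal(unname(r$auc[1]), as.numeric(ref), tolerance = 1e-10)
  })
})

test_that("confusion counts match an independent implementation", {
  skip_if_not_installed("caret")
  withr::with_seed(9, {
    truev <- factor(sample(letters[1:3], 80, replace = TRUE))
    predv <- factor(sample(letters[1:3], 80, replace = TRUE),
                    levels = levels(truev))
    cm <- confusion(truev, predv)
    ref <- caret::confusionMatrix(predv, truev)
    # caret tables are predicted x true
    expect_equal(unname(cm@counts), unname(t(as.matrix(ref$table))))
  })
})

test_that("a single-class truth yields a missing AUC for the degenerate class", {
  probs <- cbind(c(0.6, 0.7), c(0.4, 0.3))
  r <- rocAuc(c(1, 1), probs, classes = c("a", "b"))
  expect_true(is.na(r$auc[1]) && is.na(r$auc[2]))
})

test_that("Grad-CAM is bounded, zero on dead gradients, and localizes the blob", {
  ds <- generateSyntheticDataset(syntheticSpec(nPerClass = 12, noiseSd = 0,
                                               seed = 17))
  proc <- preprocessImageSet(ds, crop = FALSE)
  m <- smallModel(classes = levels(labels(ds)))
  m <- trainModel(m, proc, proc,
                  opt = optimizerConfig(epochs = 6L, batchSize = 8L),
                  seed = 4)
  i <- 30L  # a large-blob image
  img <- images(proc)[[i]]
  g <- gradCam(m, img, classIndex = as.integer(labels(proc)[i]))
  expect_true(all(g$heatmap >= 0 & g$heatmap <= 1))
  expect_equal(dim(g$heatmap), c(224, 224))
  # peak of the raw map lies inside the blob's bounding box (known geometry)
  meta <- imageMeta(ds)[i, ]
  peak <- which(g$raw == max(g$raw), arr.ind = TRUE)[1, ]
  cell <- 224 / nrow(g$raw)
  peakRow <- (peak[1] - 0.5) * cell; peakCol <- (peak[2] - 0.5) * cell
  expect_lte(abs(peakRow - meta$centerRow), meta$radiusRow + cell)
  expect_lte(abs(peakCol - meta$centerCol), meta$radiusCol + cell)
  # all-zero input has no dynamic range: the map must be all zero
  gz <- gradCam(m, array(0, c(224, 224, 3)), classIndex = 1L)
  expect_true(all(gz$heatmap == 0))
})
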