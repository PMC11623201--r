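# End-to-end training: Adam with per-element gradient clipping, categorical
# cross-entropy, reduce-on-plateau learning rate, early stopping with
# best-validation weight restore.

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamStep <- function(params, grads, state, lr, clip,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (clip > 0) g <- pmin(pmax(g, -clip), clip)
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

evaluateLossAcc <- function(model, fused, y, batchSize = 32L) {
  n <- length(fused)
  loss <- 0; correct <- 0
  for (at in seq(1L, n, by = batchSize)) {
    idx <- at:min(at + batchSize - 1L, n)
    fw <- modelForward(model, fused[idx], y = y[idx], training = FALSE)
    loss <- loss + fw$loss * length(idx)
    correct <- correct + sum(max.col(fw$probs, ties.method = "first") == y[idx])
  }
  c(loss = loss / n, acc = correct / n)
}

#' Train the model end-to-end
#'
#' Backbones stay frozen: their feature maps are computed once and cached;
#' only encoder and head parameters receive gradients. Each epoch runs
#' shuffled minibatches of Adam with per-element gradient clipping, then
#' evaluates validation loss/accuracy in evaluation mode. The learning rate
#' is multiplied by `plateauFactor` when validation loss fails to improve
#' by more than `plateauEpsilon` for `plateauPatience` consecutive epochs,
#' and training stops early after `earlyStopPatience` epochs without
#' improvement, restoring the best-validation weights. A non-finite loss
#' aborts with a diagnostic. Deterministic under `seed`.
#'
#' @param model a [WinShiftModel-class].
#' @param trainSet,valSet [ImageSet-class] objects of processed images, or
#'   lists with elements `fused` (list of fused maps) and `y` (integer
#'   class indices).
#' @param opt an [optimizerConfig()].
#' @param sched a [scheduleConfig()].
#' @param seed RNG seed governing shuffling, dropout and drop-path.
#' @param augment optional [augmentationSpec()]; when supplied, training
#'   images are re-augmented (and re-extracted) each epoch. Only the
#'   training split is ever augmented.
#' @param verbose print one line per epoch.
#' @return the trained [WinShiftModel-class]; per-epoch metrics are in
#'   [trainingHistory()].
#' @export
trainModel <- function(model, trainSet, valSet, opt = optimizerConfig(),
                       sched = scheduleConfig(), seed = 1L, augment = NULL,
                       verbose = FALSE) {
  prep <- function(s) {
    if (is(s, "ImageSet")) {
      stopIf(length(s) == 0, "empty split")
      list(images = s@images,
           fused = lapply(s@images, fuseFeatures, ensemble = model@ensemble),
           y = as.integer(factor(as.character(labels(s)),
                                 levels = model@classes)))
    } else s
  }
  tr <- prep(trainSet)
  va <- prep(valSet)
  stopIf(anyNA(tr$y) || anyNA(va$y),
         "labels outside the model's class set")
  P <- model@params
  st <- adamInit(P)
  lr <- opt$learningRate
  hist <- data.frame()
  best <- list(loss = Inf, params = P, epoch = 0L)
  plateauWait <- 0L; stopWait <- 0L
  nTr <- length(tr$fused)
  withSeed(seed, {
    for (epoch in seq_len(opt$epochs)) {
      ord <- sample(nTr)
      fusedEpoch <- if (!is.null(augment) && !is.null(tr$images)) {
        lapply(tr$images, function(im)
          fuseFeatures(augmentImage(im, augment), model@ensemble))
      } else tr$fused
      trLoss <- 0; trCorrect <- 0
      for (at in seq(1L, nTr, by = opt$batchSize)) {
        idx <- ord[at:min(at + opt$batchSize - 1L, nTr)]
        model@params <- P
        fw <- modelForward(model, fusedEpoch[idx], y = tr$y[idx],
                           training = TRUE)
        if (!is.finite(fw$loss))
          stop(sprintf("divergent loss (%g) at epoch %d; reduce the learning rate",
                       fw$loss, epoch), call. = FALSE)
        bw <- modelBackward(model, fw$caches, fw$dlogits)
        upd <- adamStep(P, bw$grads, st, lr, opt$clipValue)
        P <- upd$params; st <- upd$state
        trLoss <- trLoss + fw$loss * length(idx)
        trCorrect <- trCorrect +
          sum(max.col(fw$probs, ties.method = "first") == tr$y[idx])
      }
      model@params <- P
      vm <- evaluateLossAcc(model, va$fused, va$y)
      hist <- rbind(hist, data.frame(
        epoch = epoch, trainLoss = trLoss / nTr, trainAcc = trCorrect / nTr,
        valLoss = vm["loss"], valAcc = vm["acc"], lr = lr,
        row.names = NULL))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f acc %.3f | val loss %.4f acc %.3f | lr %.2e",
                        epoch, trLoss / nTr, trCorrect / nTr,
                        vm["loss"], vm["acc"], lr))
      improved <- vm["loss"] < best$loss - sched$plateauEpsilon
      if (improved) {
        best <- list(loss = vm["loss"], params = P, epoch = epoch)
        plateauWait <- 0L; stopWait <- 0L
      } else {
        plateauWait <- plateauWait + 1L
        stopWait <- stopWait + 1L
        if (plateauWait >= sched$plateauPatience) {
          lr <- lr * sched$plateauFactor
          plateauWait <- 0L
        }
        if (stopWait >= sched$earlyStopPatience) break
      }
    }
  })
  model@params <- best$params
  model@history <- hist
  model
}

#' Cross-entropy of an untrained balanced K-class model is about log(K)
#'
#' Convenience used in diagnostics: evaluation-mode loss on a labelled set.
#' @param model a [WinShiftModel-class].
#' @param set an [ImageSet-class] or prepared list (see [trainModel()]).
#' @return named vector with `loss` and `acc`.
#' @export
evaluateModel <- function(model, set) {
  if (is(set, "ImageSet")) {
    fused <- lapply(set@images, fuseFeatures, ensemble = model@ensemble)
    y <- as.integer(factor(as.character(labels(set)), levels = model@classes))
  } else { fused <- set$fused; y <- set$y }
  evaluateLossAcc(model, fused, y)
}
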