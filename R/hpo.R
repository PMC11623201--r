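# Bayesian hyperparameter optimization: a Tree-structured Parzen Estimator
# (TPE) over the encoder/head hyperparameters, plus the published tuned
# configuration.

#' Hyperparameter search space
#'
#' Continuous dropout/drop-path dimensions on [0, 1) and categorical
#' choices for heads, embedding dimension and MLP width. The ranges bracket
#' the published optimum (every candidate embedding dimension is divisible
#' by every candidate head count).
#'
#' @param dims optional named list overriding the default dimensions; each
#'   entry is `list(type = "uniform", low =, high =)` or
#'   `list(type = "choice", values =)`.
#' @return a list of class "searchSpace".
#' @export
searchSpace <- function(dims = NULL) {
  if (is.null(dims)) {
    u <- function(lo, hi) list(type = "uniform", low = lo, high = hi)
    dims <- list(
      dropoutMlp   = u(0, 1), dropoutAttn = u(0, 1),
      dropoutBlock = u(0, 1), dropPath    = u(0, 1),
      heads    = list(type = "choice", values = c(2L, 4L, 8L)),
      embedDim = list(type = "choice", values = c(48L, 96L, 192L)),
      mlpNodes = list(type = "choice", values = c(24L, 48L, 96L)))
  }
  ed <- dims$embedDim; hd <- dims$heads
  if (!is.null(ed) && !is.null(hd) && ed$type == "choice" && hd$type == "choice")
    stopIf(!all(outer(ed$values, hd$values, "%%") == 0),
           "every embedDim must be divisible by every head count")
  structure(dims, class = "searchSpace")
}

sampleRandom <- function(space) {
  lapply(unclass(space), function(d)
    if (d$type == "uniform") stats::runif(1, d$low, d$high)
    else sample(d$values, 1))
}

# TPE proposal for one dimension given good/bad observed values
tpeProposeDim <- function(d, goodVals, badVals, nCandidates = 24L) {
  if (d$type == "choice") {
    score <- function(vals) {
      cnt <- table(factor(vals, levels = as.character(d$values)))
      (as.numeric(cnt) + 1) / (length(vals) + length(d$values))
    }
    ratio <- score(goodVals) / score(badVals)
    d$values[which.max(ratio)]
  } else {
    bw <- function(x) max(stats::sd(x), (d$high - d$low) / 20, 1e-3)
    bg <- bw(goodVals); bb <- bw(badVals)
    dens <- function(x, centers, h)
      rowMeans(outer(x, centers, function(a, b) stats::dnorm(a, b, h))) +
        1e-12
    cand <- pmin(pmax(goodVals[sample.int(length(goodVals), nCandidates,
                                          replace = TRUE)] +
                        stats::rnorm(nCandidates, 0, bg),
                      d$low), d$high - 1e-9)
    cand[which.max(dens(cand, goodVals, bg) / dens(cand, badVals, bb))]
  }
}

#' Run a TPE hyperparameter study
#'
#' Maximizes `objectiveFn(params)` (e.g. validation accuracy of a
#' scaled-down training run). The first `nWarmup` trials are random; later
#' trials split completed trials at the top `gamma` quantile into good/bad
#' sets and propose, per dimension, the candidate maximizing the
#' good/bad density ratio (Gaussian kernels for continuous dimensions,
#' smoothed frequencies for categorical ones). Reproducible under `seed`;
#' a trial whose objective errors is recorded as failed.
#'
#' @param space a [searchSpace()].
#' @param nTrials total trial budget (>= 1).
#' @param objectiveFn function(named list of sampled values) -> numeric.
#' @param seed study seed.
#' @param nWarmup random warmup trials before TPE kicks in.
#' @param gamma top quantile treated as "good".
#' @return list of class "studyResult": `trials` data.frame (sampled values,
#'   objective, state) and `best` (the best complete trial as a list).
#' @export
runStudy <- function(space, nTrials, objectiveFn, seed = 1L,
                     nWarmup = 10L, gamma = 0.25) {
  stopIf(nTrials < 1, "nTrials must be >= 1")
  dims <- unclass(space)
  rows <- vector("list", nTrials)
  withSeed(seed, {
    for (t in seq_len(nTrials)) {
      done <- do.call(rbind, rows)
      complete <- if (!is.null(done)) done[done$state == "complete", , drop = FALSE]
                  else NULL
      params <- if (t <= nWarmup || is.null(complete) || nrow(complete) < 4) {
        sampleRandom(space)
      } else {
        nGood <- max(2L, ceiling(gamma * nrow(complete)))
        ordc <- order(complete$objective, decreasing = TRUE)
        good <- complete[ordc[seq_len(nGood)], , drop = FALSE]
        bad <- complete[ordc[-seq_len(nGood)], , drop = FALSE]
        if (nrow(bad) < 2) sampleRandom(space)
        else stats::setNames(lapply(names(dims), function(nm)
          tpeProposeDim(dims[[nm]], good[[nm]], bad[[nm]])), names(dims))
      }
      obj <- tryCatch(objectiveFn(params), error = function(e) e)
      if (inherits(obj, "error")) {
        rows[[t]] <- data.frame(trial = t, as.data.frame(params),
                                objective = NA_real_, state = "failed",
                                message = conditionMessage(obj))
      } else {
        rows[[t]] <- data.frame(trial = t, as.data.frame(params),
                                objective = as.numeric(obj),
                                state = "complete", message = "")
      }
    }
  })
  trials <- do.call(rbind, rows)
  complete <- trials[trials$state == "complete", , drop = FALSE]
  if (nrow(complete) == 0)
    stop(paste0("all trials failed:\n",
                paste(trials$message, collapse = "\n")), call. = FALSE)
  bi <- complete$trial[which.max(complete$objective)]
  best <- as.list(trials[trials$trial == bi, setdiff(names(trials),
                                                     c("state", "message"))])
  structure(list(trials = trials, best = best), class = "studyResult")
}

#' @export
print.studyResult <- function(x, ...) {
  cat(sprintf("TPE study: %d trials (%d complete), best objective %.4f (trial %d)\n",
              nrow(x$trials), sum(x$trials$state == "complete"),
              x$best$objective, x$best$trial))
  invisible(x)
}

#' The published tuned hyperparameter configuration
#'
#' The best values found by the original Bayesian optimization: dropout
#' after each MLP layer 0.2995, dropout after windowed attention 0.7605,
#' dropout at the end of each attention block 0.5855, drop-path 0.4789,
#' 4 attention heads, embedding dimension 96, 24 MLP nodes; together with
#' the published head (256 units / dropout 0.5, 96 units / dropout 0.1).
#'
#' @param window window side (published patch and window size are both 2).
#' @return list with `block` (a [SwinBlockConfig-class]) and `head` (a
#'   [headConfig()]).
#' @export
tunedHyperparameters <- function(window = 2L) {
  list(block = swinBlockConfig(window = window, shift = 0L, heads = 4L,
                               embedDim = 96L, mlpNodes = 24L,
                               dropoutMlp = 0.2995, dropoutAttn = 0.7605,
                               dropoutBlock = 0.5855, dropPath = 0.4789),
       head = headConfig(256L, 96L, 0.5, 0.1))
}
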