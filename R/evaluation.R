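# Evaluation stack: confusion matrix with one-vs-rest counts, the standard
# ACC/PRE/SEN/F1 metrics, multiclass ROC/AUC by trapezoidal integration,
# and Grad-CAM explanation maps.

#' Build a confusion matrix
#'
#' @param true,pred equal-length label vectors (factors, characters, or
#'   1-based integer class indices).
#' @param classes class labels in matrix order; inferred from factor levels
#'   when omitted.
#' @return a [ConfusionMatrix-class]: counts[i, j] = #(true = i, pred = j).
#' @export
confusion <- function(true, pred, classes = NULL) {
  stopIf(length(true) != length(pred), "label vectors differ in length")
  if (is.null(classes))
    classes <- if (is.factor(true)) levels(true)
               else sort(unique(c(as.character(true), as.character(pred))))
  if (is.numeric(true)) {
    K <- length(classes)
    stopIf(any(true < 1 | true > K | pred < 1 | pred > K),
           "integer labels out of range")
    true <- classes[true]; pred <- classes[pred]
  }
  true <- factor(as.character(true), levels = classes)
  pred <- factor(as.character(pred), levels = classes)
  stopIf(anyNA(true) || anyNA(pred), "labels outside the class set")
  counts <- unclass(table(true, pred))
  dimnames(counts) <- NULL
  new("ConfusionMatrix", counts = matrix(as.integer(counts), nrow(counts)),
      classes = classes)
}

#' One-vs-rest TP/TN/FP/FN counts per class
#' @param cm a [ConfusionMatrix-class].
#' @return data.frame with one row per class; for every class
#'   TP + TN + FP + FN equals the total sample count.
#' @export
perClassCounts <- function(cm) {
  m <- cm@counts
  total <- sum(m)
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  tn <- total - tp - fp - fn
  data.frame(class = cm@classes, TP = tp, TN = tn, FP = fp, FN = fn,
             support = rowSums(m))
}

#' Classification report from a confusion matrix
#'
#' Per class (one-vs-rest): precision TP/(TP+FP), sensitivity (recall)
#' TP/(TP+FN), F1 = 2TP/(2TP+FP+FN), and one-vs-rest accuracy
#' (TP+TN)/total. Overall accuracy is trace/total. A class never predicted
#' (TP+FP = 0) reports precision 0 with a warning.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return list with `perClass` (data.frame: class, precision, sensitivity,
#'   f1, accuracyOvR, support) and `accuracy` (overall, in [0, 1]).
#' @export
classificationReport <- function(cm) {
  stopIf(sum(cm@counts) == 0, "empty confusion matrix")
  pc <- perClassCounts(cm)
  denomP <- pc$TP + pc$FP
  if (any(denomP == 0))
    warning("class(es) never predicted; precision reported as 0: ",
            paste(pc$class[denomP == 0], collapse = ", "))
  precision <- ifelse(denomP == 0, 0, pc$TP / denomP)
  sensitivity <- ifelse(pc$TP + pc$FN == 0, 0, pc$TP / (pc$TP + pc$FN))
  f1 <- ifelse(2 * pc$TP + pc$FP + pc$FN == 0, 0,
               2 * pc$TP / (2 * pc$TP + pc$FP + pc$FN))
  accOvR <- (pc$TP + pc$TN) / sum(cm@counts)
  list(perClass = data.frame(class = pc$class, precision = precision,
                             sensitivity = sensitivity, f1 = f1,
                             accuracyOvR = accOvR, support = pc$support),
       accuracy = sum(diag(cm@counts)) / sum(cm@counts))
}

# one-vs-rest ROC curve for one score vector; thresholds swept over the
# sorted unique scores, trapezoidal AUC
rocBinary <- function(isPos, score) {
  nP <- sum(isPos); nN <- sum(!isPos)
  if (nP == 0 || nN == 0)
    return(list(fpr = NA_real_, tpr = NA_real_, auc = NA_real_))
  th <- sort(unique(score), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(score >= t & isPos) / nP, numeric(1))
  fpr <- vapply(th, function(t) sum(score >= t & !isPos) / nN, numeric(1))
  fpr <- c(0, fpr, 1); tpr <- c(0, tpr, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Multiclass one-vs-rest ROC curves and AUC
#'
#' One curve per class, using that class's predicted probability as the
#' score; AUC by trapezoidal integration over all score thresholds. A class
#' absent from (or covering all of) the truth gets an NA AUC.
#'
#' @param true labels (factor/character/1-based integer).
#' @param probs n x K matrix of class probabilities (rows sum to ~1).
#' @param classes class labels in column order; default from `probs`
#'   colnames or factor levels.
#' @return list of class "rocResult": per-class list with `fpr`, `tpr`,
#'   `auc`, plus `auc` (named vector).
#' @export
rocAuc <- function(true, probs, classes = NULL) {
  stopIf(any(abs(rowSums(probs) - 1) > 1e-6),
         "probability rows must sum to 1")
  if (is.null(classes))
    classes <- if (!is.null(colnames(probs))) colnames(probs)
               else if (is.factor(true)) levels(true)
               else as.character(sort(unique(true)))
  lab <- if (is.numeric(true)) classes[true] else as.character(true)
  curves <- lapply(seq_along(classes), function(k)
    rocBinary(lab == classes[k], probs[, k]))
  names(curves) <- classes
  structure(list(curves = curves,
                 auc = vapply(curves, function(x) x$auc, numeric(1))),
            class = "rocResult")
}

#' @export
print.rocResult <- function(x, ...) {
  cat("One-vs-rest ROC; AUC per class:\n")
  print(round(x$auc, 4))
  invisible(x)
}

#' Grad-CAM explanation map
#'
#' Gradient-weighted class activation mapping at the fused feature map (the
#' target layer between the frozen ensemble and the encoder): channel
#' weights are the spatial means of the class logit's gradient, the map is
#' ReLU(sum_k alpha_k A_k), min-max normalized and bilinearly upsampled to
#' the input size. If every pooled gradient is non-positive the map is all
#' zero, as is a map with no dynamic range.
#'
#' @param model a [WinShiftModel-class].
#' @param image processed 224 x 224 x 3 array (or a fused feature map).
#' @param classIndex 1-based target class; default the predicted class.
#' @param size output side of the upsampled heatmap.
#' @return list of class "gradCamMap": `heatmap` (size x size in [0, 1]),
#'   `raw` (the target-layer-resolution map), `classIndex`.
#' @export
gradCam <- function(model, image, classIndex = NULL, size = 224L) {
  L <- model@layout
  fused <- if (length(dim(image)) == 3 && all(dim(image) == c(L$T, L$T, L$Cin)))
    image else fuseFeatures(image, model@ensemble)
  fw <- modelForward(model, list(fused), training = FALSE)
  if (is.null(classIndex))
    classIndex <- which.max(fw$probs[1, ])
  seedGrad <- matrix(0, 1, model@nClasses)
  seedGrad[1, classIndex] <- 1
  bw <- modelBackward(model, fw$caches, seedGrad, inputGrad = TRUE)
  dmap <- bw$dInput[[1]]
  alpha <- apply(dmap, 3, mean)
  if (all(alpha <= 0)) {
    heat <- matrix(0, L$T, L$T)
  } else {
    heat <- matrix(0, L$T, L$T)
    for (k in seq_along(alpha)) heat <- heat + alpha[k] * fused[, , k]
    heat <- pmax(heat, 0)
    rngv <- range(heat)
    heat <- if (diff(rngv) <= 0) heat * 0 else (heat - rngv[1]) / diff(rngv)
  }
  up <- upsampleBilinear(heat, size, size)
  up <- pmin(pmax(up, 0), 1)
  structure(list(heatmap = up, raw = heat, classIndex = classIndex),
            class = "gradCamMap")
}
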