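## Detection and classification metrics: confusion counts, greedy IoU
## matching, all-point average precision, accuracy/recall/precision/F, and
## ROC/AUC by threshold sweep.

#' Confusion counts
#'
#' @param tp,fp,fn,tn non-negative integer counts.
#' @return Named integer vector of class `ConfusionCounts`.
#' @export
confusionCounts <- function(tp = 0L, fp = 0L, fn = 0L, tn = 0L) {
  v <- c(tp = as.integer(tp), fp = as.integer(fp),
         fn = as.integer(fn), tn = as.integer(tn))
  if (any(v < 0L)) stop("confusion counts must be non-negative")
  structure(v, class = "ConfusionCounts")
}

#' Match predicted boxes to ground truth at an IoU threshold
#'
#' PASCAL-style greedy matching: predictions are visited in descending score
#' order; each claims the unmatched truth box of highest IoU, and counts as
#' a true positive when that IoU reaches the threshold. Each truth box
#' matches at most one prediction; unmatched truths are false negatives.
#'
#' @param predicted detections data.frame (boxes + `score`).
#' @param truth n x 4 corner matrix of ground-truth boxes (may be empty).
#' @param iouThreshold IoU threshold in (0, 1], default 0.5.
#' @return List: `counts` ([confusionCounts()], tn = 0), `matches`
#'   data.frame (`pred`, `truth`, `iou`) and logical `tpFlags` in descending
#'   score order.
#' @export
matchDetections <- function(predicted, truth, iouThreshold = 0.5) {
  if (iouThreshold <= 0 || iouThreshold > 1)
    stop("iouThreshold must lie in (0, 1]")
  truth <- if (length(truth)) asBoxMatrix(truth) else
    matrix(numeric(0), 0, 4)
  nP <- nrow(predicted); nT <- nrow(truth)
  ord <- if (nP) order(-predicted$score) else integer(0)
  usedT <- logical(nT)
  tpFlags <- logical(nP)
  matches <- list()
  pb <- if (nP) detBoxes(predicted) else matrix(numeric(0), 0, 4)
  for (j in seq_along(ord)) {
    i <- ord[j]
    if (nT == 0L) next
    ious <- overlapRatio(pb[rep(i, nT), , drop = FALSE], truth)
    ious[usedT] <- -1
    k <- which.max(ious)
    if (length(k) && ious[k] >= iouThreshold) {
      usedT[k] <- TRUE
      tpFlags[j] <- TRUE
      matches[[length(matches) + 1L]] <-
        data.frame(pred = i, truth = k, iou = ious[k])
    }
  }
  matches <- if (length(matches)) do.call(rbind, matches) else
    data.frame(pred = integer(0), truth = integer(0), iou = numeric(0))
  counts <- confusionCounts(tp = sum(tpFlags), fp = nP - sum(tpFlags),
                            fn = nT - sum(usedT), tn = 0L)
  list(counts = counts, matches = matches, tpFlags = tpFlags)
}

#' Average precision of scored detections
#'
#' All-point interpolated area under the precision-recall curve: predictions
#' are swept in descending score order under the greedy IoU matching of
#' [matchDetections()], and AP is the sum over recall increments of the
#' interpolated (running-maximum-to-the-right) precision.
#'
#' @param predicted detections data.frame with `score`.
#' @param truth n x 4 corner matrix of ground-truth boxes; must be
#'   non-empty (AP is undefined without truths).
#' @param iouThreshold IoU threshold (default 0.5).
#' @return AP in `[0, 1]`.
#' @export
averagePrecision <- function(predicted, truth, iouThreshold = 0.5) {
  truth <- asBoxMatrix(truth)
  if (nrow(truth) == 0L) stop("average precision is undefined with no truths")
  if (nrow(predicted) == 0L) return(0)
  m <- matchDetections(predicted, truth, iouThreshold)
  tp <- cumsum(m$tpFlags)
  fp <- cumsum(!m$tpFlags)
  recall <- tp / nrow(truth)
  precision <- tp / (tp + fp)
  precEnv <- rev(cummax(rev(precision)))
  dr <- diff(c(0, recall))
  sum(dr * precEnv)
}

#' F-measure from precision and recall
#'
#' The harmonic mean `2PR/(P+R)`; the standard summary column of detection
#' tables, also usable directly on printed precision/recall values.
#'
#' @param precision,recall values in `[0, 1]`, not both zero.
#' @return The F-measure.
#' @examples
#' fMeasure(0.703, 0.956) # ~0.810
#' @export
fMeasure <- function(precision, recall) {
  if (precision + recall == 0) stop("P + R must be positive")
  2 * precision * recall / (precision + recall)
}

#' Accuracy, recall, precision and F-measure from confusion counts
#'
#' `accuracy = (tp+tn)/total`, `recall = tp/(tp+fn)`,
#' `precision = tp/(tp+fp)`, `F = 2PR/(P+R)`. A metric whose denominator is
#' zero is reported as `NaN` with a warning, never silently as 0; zero total
#' is an error.
#'
#' @param counts a [confusionCounts()] (or named vector tp/fp/fn/tn).
#' @return List with `accuracy`, `recall`, `precision`, `f_measure`.
#' @examples
#' prfMetrics(confusionCounts(tp = 3, fp = 1, fn = 1, tn = 5))
#' @export
prfMetrics <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  fn <- counts[["fn"]]; tn <- counts[["tn"]]
  total <- tp + fp + fn + tn
  if (total == 0L) stop("no evaluated items")
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); reported as NaN", what))
      return(NaN)
    }
    num / den
  }
  accuracy <- (tp + tn) / total
  recall <- safe(tp, tp + fn, "recall")
  precision <- safe(tp, tp + fp, "precision")
  f <- if (is.nan(recall) || is.nan(precision)) {
    warning("F-measure undefined; reported as NaN")
    NaN
  } else if (precision + recall == 0) {
    warning("F-measure undefined (P + R = 0); reported as NaN")
    NaN
  } else fMeasure(precision, recall)
  list(accuracy = accuracy, recall = recall, precision = precision,
       f_measure = f)
}

#' ROC curve and AUC of sequence scores
#'
#' Sweeps a decision threshold over the distinct scores and records
#' (false positive rate, true positive rate) at each; AUC is the
#' trapezoid-rule area. Scissors (or 1) is the positive class. Requires
#' both classes present.
#'
#' @param scores numeric scores (higher = more scissors-like).
#' @param labels 0/1 vector or character tool-class labels.
#' @return List: `roc` data.frame (`threshold`, `fpr`, `tpr`) and `auc`.
#' @export
rocCurveAuc <- function(scores, labels) {
  y <- if (is.character(labels)) labelToBinary(labels) else as.integer(labels)
  if (length(unique(y)) < 2L)
    stop("ROC requires both classes among the labels")
  nPos <- sum(y == 1L); nNeg <- sum(y == 0L)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(th) {
    pred <- scores >= th
    c(fpr = sum(pred & y == 0L) / nNeg, tpr = sum(pred & y == 1L) / nPos)
  }, numeric(2)))
  roc <- data.frame(threshold = thr, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
  auc <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
  list(roc = roc, auc = auc)
}

#' Target-hand selection metrics against annotated truth
#'
#' A frame counts as a true positive when a hand was selected and its box
#' matches the annotated operating hand at the IoU threshold; a selection
#' matching no truth is a false positive; a frame with an annotated
#' operating hand but no selection is a false negative; a frame with
#' neither is a true negative.
#'
#' @param selectedBoxes n x 4 matrix of selected hand boxes, rows of `NA`
#'   where no hand was selected.
#' @param truthBoxes n x 4 matrix of annotated operating-hand boxes, rows of
#'   `NA` where no operating hand exists.
#' @param iouThreshold IoU threshold (default 0.5).
#' @return List with `counts` and the [prfMetrics()] values.
#' @export
selectionMetrics <- function(selectedBoxes, truthBoxes, iouThreshold = 0.5) {
  selectedBoxes <- asBoxMatrix(selectedBoxes)
  truthBoxes <- asBoxMatrix(truthBoxes)
  if (nrow(selectedBoxes) != nrow(truthBoxes))
    stop("selected and truth boxes must align frame by frame")
  selOk <- !is.na(selectedBoxes[, 1])
  truOk <- !is.na(truthBoxes[, 1])
  both <- selOk & truOk
  iou <- rep(0, nrow(selectedBoxes))
  if (any(both))
    iou[both] <- overlapRatio(selectedBoxes[both, , drop = FALSE],
                              truthBoxes[both, , drop = FALSE])
  counts <- confusionCounts(
    tp = sum(both & iou >= iouThreshold),
    fp = sum(selOk & !(both & iou >= iouThreshold)),
    fn = sum(truOk & !selOk),
    tn = sum(!selOk & !truOk))
  c(list(counts = counts), prfMetrics(counts))
}
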