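## Phase-3 classifier: per-frame features -> LSTM aggregation ->
## per-timestep sigmoid probabilities -> fused sequence label.
## Scissors is the positive class (coded 1); needle holders are coded 0.

POSITIVE_CLASS <- "scissors"
NEGATIVE_CLASS <- "needle_holders"

labelToBinary <- function(labels) as.integer(labels == POSITIVE_CLASS)

#' Recurrent aggregation of a feature sequence
#'
#' Runs the single-layer LSTM (tanh cell activation, hidden size equal to
#' the number of columns of `params$Wh` / 4) over one feature sequence. The
#' aggregation is causal: row t of the output depends only on rows 1..t of
#' the input.
#'
#' @param psi `T x featureDim` matrix of per-frame features.
#' @param params list with `Wx` (`featureDim x 4H`), `Wh` (`H x 4H`), `b`
#'   (`4H`), gate blocks ordered input, forget, cell, output.
#' @return `T x H` matrix of aggregated features psi-hat.
#' @export
aggregateSequence <- function(psi, params) {
  psiSeq <- lapply(seq_len(nrow(psi)), function(t) psi[t, , drop = FALSE])
  fwd <- lstmForward(psiSeq, params)
  do.call(rbind, fwd$h)
}

#' Per-timestep label probabilities
#'
#' Applies the MLP head (one ReLU hidden layer, single sigmoid output unit)
#' independently to every aggregated feature vector.
#'
#' @param psiHat `T x H` matrix of aggregated features.
#' @param head list with `W1`, `b1`, `W2`, `b2`.
#' @return Numeric vector of T probabilities in (0, 1).
#' @export
predictTimesteps <- function(psiHat, head) {
  headForward(psiHat, head)$p
}

#' Fuse per-timestep probabilities into a sequence decision
#'
#' The classifier emits one probability per timestep; a single sequence
#' score is obtained by mean (default), last-step, or max fusion, and the
#' label is the positive class (scissors) when the fused score is >= 0.5.
#'
#' @param p numeric vector of per-timestep probabilities.
#' @param fusion `"mean"`, `"last"`, or `"max"`.
#' @return List with `pFinal` and `label`.
#' @examples
#' sequenceLabel(c(0.2, 0.8)) # mean 0.5 -> scissors under the >= convention
#' @export
sequenceLabel <- function(p, fusion = c("mean", "last", "max")) {
  fusion <- match.arg(fusion)
  if (length(p) < 1L) stop("need at least one timestep probability")
  pFinal <- switch(fusion, mean = mean(p), last = p[length(p)], max = max(p))
  list(pFinal = pFinal,
       label = if (pFinal >= 0.5) POSITIVE_CLASS else NEGATIVE_CLASS)
}

#' Inverse-frequency class weights
#'
#' For class counts `n_c` over K classes with total N, the weight of class c
#' is `N / (K * n_c)`: rarer classes weigh more, and the count-weighted mean
#' of the weights is 1, so the overall loss scale is unchanged. With the
#' sequence counts 756 scissors / 2894 needle holders this gives weights
#' 2.414 and 0.631.
#'
#' @param counts named positive integer vector of per-class counts.
#' @return Named numeric weights.
#' @examples
#' computeClassWeights(c(scissors = 756, needle_holders = 2894))
#' @export
computeClassWeights <- function(counts) {
  if (any(counts <= 0)) stop("all class counts must be positive")
  N <- sum(counts); K <- length(counts)
  w <- N / (K * counts)
  setNames(as.numeric(w), names(counts))
}

#' Class-weighted binary cross-entropy of a probability sequence
#'
#' `loss = w_y * mean_t(-(y log p_t + (1-y) log(1-p_t)))` with probabilities
#' clipped to `[eps, 1-eps]` for numerical stability. Reduces to plain
#' binary cross-entropy when both weights are 1 and scales linearly in the
#' weight of the true class.
#'
#' @param p numeric vector of per-timestep probabilities.
#' @param y true label: 0/1, or a tool-class name (scissors = 1).
#' @param classWeights length-2 numeric `c(w0, w1)` or named by class.
#' @param eps clipping constant (default 1e-7).
#' @return Non-negative scalar loss.
#' @examples
#' weightedCrossEntropy(rep(0.5, 10), 1) # log(2)
#' @export
weightedCrossEntropy <- function(p, y, classWeights = c(1, 1), eps = 1e-7) {
  if (is.character(y)) y <- labelToBinary(y)
  if (!y %in% c(0L, 1L)) stop("y must be 0/1 or a tool-class name")
  w <- classWeightFor(classWeights, y)
  pc <- pmin(pmax(p, eps), 1 - eps)
  w * mean(-(y * log(pc) + (1 - y) * log(1 - pc)))
}

classWeightFor <- function(classWeights, y) {
  if (!is.null(names(classWeights)) &&
      all(c(NEGATIVE_CLASS, POSITIVE_CLASS) %in% names(classWeights))) {
    unname(classWeights[if (y == 1L) POSITIVE_CLASS else NEGATIVE_CLASS])
  } else classWeights[y + 1L]
}

resolveClassWeights <- function(config, labels) {
  if (length(config@classWeights)) {
    w <- config@classWeights
    if (is.null(names(w))) names(w) <- c(NEGATIVE_CLASS, POSITIVE_CLASS)
    return(w)
  }
  counts <- table(factor(labels, levels = c(NEGATIVE_CLASS, POSITIVE_CLASS)))
  computeClassWeights(setNames(as.integer(counts), names(counts)))
}

standardizeStats <- function(descriptors) {
  all <- do.call(rbind, descriptors)
  center <- colMeans(all)
  scale <- pmax(apply(all, 2L, sd), 1e-6)
  list(center = center, scale = scale)
}

applyStandardize <- function(m, center, scale) {
  sweep(sweep(m, 2L, center, "-"), 2L, scale, "/")
}

## Assemble a [B, T, D] array from standardized fragments.
fragmentArray <- function(descriptors, idx, offsets, tFrames, center, scale) {
  B <- length(idx)
  D <- ncol(descriptors[[1]])
  arr <- array(0, c(B, tFrames, D))
  for (j in seq_len(B)) {
    i <- idx[j]; off <- offsets[j]
    arr[j, , ] <- applyStandardize(
      descriptors[[i]][(off + 1L):(off + tFrames), , drop = FALSE],
      center, scale)
  }
  arr
}

#' Train the sequential motion classifier
#'
#' Trains the linear feature projection, LSTM aggregator and MLP head
#' end-to-end with Adam on class-weighted per-timestep binary cross-entropy.
#' Each epoch shuffles the clips and, for clips longer than T, samples one
#' random T-frame fragment; dropout is applied to the projected features
#' (the LSTM inputs). Everything stochastic — weight init, shuffling,
#' fragment offsets, dropout — is governed by `config@seed`.
#'
#' @param set a [clipFeatureSet()] with at least two clips per class.
#' @param config a [classifierConfig()].
#' @return A [MotionClassifier-class] with per-epoch loss history.
#' @export
trainMotionClassifier <- function(set, config = classifierConfig()) {
  trainCore(set, config, recurrent = TRUE)
}

#' Train the per-frame appearance baseline
#'
#' The "only hand" baseline: the same feature extractor and MLP head,
#' without the recurrent aggregator, trained on single crops (every frame of
#' every training clip becomes one sample labelled with its clip's class).
#' When the two classes differ only in motion, this baseline has no signal
#' to learn and stays near the 0.5 chance rate.
#'
#' @param set a [clipFeatureSet()].
#' @param config a [classifierConfig()]; `tFrames` is treated as 1.
#' @param frameBatch minibatch size in frames (default 64).
#' @return A [MotionClassifier-class] with `recurrent = FALSE`.
#' @export
trainPerFrameBaseline <- function(set, config = classifierConfig(),
                                  frameBatch = 64L) {
  trainCore(set, config, recurrent = FALSE, frameBatch = as.integer(frameBatch))
}

trainCore <- function(set, config, recurrent, frameBatch = 64L) {
  labels <- set$labels
  if (length(unique(labels)) < 2L)
    stop("training requires both tool classes to be present")
  y <- labelToBinary(labels)
  cw <- resolveClassWeights(config, labels)
  st <- standardizeStats(set$descriptors)
  D <- set$descriptorDim
  set.seed(config@seed)
  params <- nnInitParams(D, config@featureDim, config@recurrentHidden,
                         config@headHidden, recurrent)
  state <- adamInit(params)
  lossHistory <- numeric(0)
  Tn <- config@tFrames

  if (recurrent) {
    lens <- vapply(set$descriptors, nrow, integer(1))
    if (any(lens < Tn))
      stop("every clip must provide at least tFrames frames")
    for (ep in seq_len(config@epochs)) {
      ord <- sample.int(length(labels))
      epochLoss <- 0; seen <- 0L
      for (start in seq.int(1L, length(ord), by = config@batchSize)) {
        idx <- ord[start:min(start + config@batchSize - 1L, length(ord))]
        B <- length(idx)
        offsets <- vapply(idx, function(i) {
          hi <- lens[i] - Tn
          if (hi == 0L) 0L else sample.int(hi + 1L, 1L) - 1L
        }, integer(1))
        arr <- fragmentArray(set$descriptors, idx, offsets, Tn,
                             st$center, st$scale)
        mask <- NULL
        if (config@dropout > 0)
          mask <- matrix(rbinom(B * Tn * config@featureDim, 1L,
                                1 - config@dropout),
                         B * Tn, config@featureDim) / (1 - config@dropout)
        fwd <- nnForwardSeq(arr, params, mask)
        wB <- vapply(y[idx], function(yy) classWeightFor(cw, yy), numeric(1))
        loss <- mean(vapply(seq_len(B), function(b)
          weightedCrossEntropy(fwd$P[b, ], y[idx[b]], cw), numeric(1)))
        dLogit <- (fwd$P - matrix(y[idx], B, Tn)) * (wB / (B * Tn))
        grads <- nnBackwardSeq(fwd, params, dLogit, mask)
        upd <- adamStep(params, grads, state, config@learningRate)
        params <- upd$params; state <- upd$state
        epochLoss <- epochLoss + loss * B; seen <- seen + B
      }
      lossHistory <- c(lossHistory, epochLoss / seen)
    }
  } else {
    X <- do.call(rbind, lapply(seq_along(set$descriptors), function(i)
      applyStandardize(set$descriptors[[i]], st$center, st$scale)))
    yF <- rep(y, vapply(set$descriptors, nrow, integer(1)))
    wF <- vapply(yF, function(yy) classWeightFor(cw, yy), numeric(1))
    n <- length(yF)
    for (ep in seq_len(config@epochs)) {
      ord <- sample.int(n)
      epochLoss <- 0; seen <- 0L
      for (start in seq.int(1L, n, by = frameBatch)) {
        idx <- ord[start:min(start + frameBatch - 1L, n)]
        B <- length(idx)
        Xb <- X[idx, , drop = FALSE]
        mask <- NULL
        if (config@dropout > 0)
          mask <- matrix(rbinom(B * config@featureDim, 1L,
                                1 - config@dropout),
                         B, config@featureDim) / (1 - config@dropout)
        fwd <- nnForwardFrame(Xb, params, mask)
        pc <- pmin(pmax(fwd$p, 1e-7), 1 - 1e-7)
        loss <- mean(wF[idx] *
                       -(yF[idx] * log(pc) + (1 - yF[idx]) * log(1 - pc)))
        dLogit <- wF[idx] * (fwd$p - yF[idx]) / B
        grads <- nnBackwardFrame(fwd, params, dLogit, mask)
        upd <- adamStep(params, grads, state, config@learningRate)
        params <- upd$params; state <- upd$state
        epochLoss <- epochLoss + loss * B; seen <- seen + B
      }
      lossHistory <- c(lossHistory, epochLoss / seen)
    }
  }
  new("MotionClassifier", config = config, params = params,
      featureCenter = st$center, featureScale = st$scale,
      classWeights = cw, lossHistory = lossHistory, recurrent = recurrent)
}

#' Classify clip windows with a trained model
#'
#' Runs the full forward pass (projection, LSTM, head) on every clip of a
#' feature set and fuses the per-timestep probabilities by the model's
#' fusion rule. Sequences of any length are accepted; the LSTM simply runs
#' for the given number of steps.
#'
#' @param model a trained [MotionClassifier-class] (recurrent).
#' @param set a [clipFeatureSet()].
#' @return A data.frame with `p_final`, `label`, `truth`; the per-timestep
#'   probability vectors are attached as the `"probs"` attribute (list).
#' @export
classifyClips <- function(model, set) {
  if (!model@recurrent)
    stop("model is a per-frame baseline; use predictFrames()")
  probs <- lapply(set$descriptors, function(d) {
    ds <- applyStandardize(d, model@featureCenter, model@featureScale)
    psi <- sweep(ds %*% model@params$Wp, 2L, model@params$bp, "+")
    psiHat <- aggregateSequence(psi, model@params)
    predictTimesteps(psiHat, model@params)
  })
  fused <- lapply(probs, sequenceLabel, fusion = model@config@fusion)
  out <- data.frame(
    p_final = vapply(fused, `[[`, numeric(1), "pFinal"),
    label = vapply(fused, `[[`, character(1), "label"),
    truth = set$labels)
  attr(out, "probs") <- probs
  out
}

#' Per-frame predictions of the baseline model
#'
#' @param model a [MotionClassifier-class] trained by
#'   [trainPerFrameBaseline()].
#' @param set a [clipFeatureSet()]; every frame of every clip is scored.
#' @return A data.frame with one row per frame: `p`, `label`, `truth`,
#'   `clip`.
#' @export
predictFrames <- function(model, set) {
  if (model@recurrent)
    stop("model is a sequential classifier; use classifyClips()")
  if (!length(set$descriptors)) stop("empty test set")
  rows <- lapply(seq_along(set$descriptors), function(i) {
    ds <- applyStandardize(set$descriptors[[i]], model@featureCenter,
                           model@featureScale)
    p <- nnForwardFrame(ds, model@params)$p
    data.frame(p = p,
               label = ifelse(p >= 0.5, POSITIVE_CLASS, NEGATIVE_CLASS),
               truth = set$labels[i], clip = i)
  })
  do.call(rbind, rows)
}

#' Classification metrics of sequence predictions
#'
#' Builds the confusion counts of predicted vs. true labels (scissors
#' positive) and derives accuracy, recall, precision and F-measure.
#'
#' @param predicted,truth character vectors of tool-class labels.
#' @return List with `counts` and the four metrics.
#' @export
classificationMetrics <- function(predicted, truth) {
  yp <- labelToBinary(predicted); yt <- labelToBinary(truth)
  counts <- confusionCounts(tp = sum(yp == 1 & yt == 1),
                            fp = sum(yp == 1 & yt == 0),
                            fn = sum(yp == 0 & yt == 1),
                            tn = sum(yp == 0 & yt == 0))
  c(list(counts = counts), prfMetrics(counts))
}
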