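#' @import methods
#' @importFrom stats rnorm runif rpois rbinom sd setNames
NULL

TOOL_CLASSES <- c("needle_holders", "scissors")
MOTION_PROGRAMS <- c("oscillate", "rotate", "static")
DETECTION_CATEGORIES <- c("hand", "tool")

#' Detector noise model
#'
#' Parameters of the synthetic detector's corruption of ground-truth boxes:
#' i.i.d. Gaussian jitter on each box corner, independent per-box misses,
#' Poisson-distributed spurious low-score boxes, and Gaussian noise on the
#' detection scores. With all four parameters at zero the oracle detector
#' reproduces the ground truth exactly with score 1.
#'
#' @slot boxJitterSigma standard deviation (pixels) of corner jitter.
#' @slot missRate probability in `[0,1]` that a true box is dropped.
#' @slot spuriousRate expected number of false boxes injected per frame.
#' @slot scoreNoiseSigma standard deviation of the score perturbation.
#' @exportClass DetectorNoise
setClass("DetectorNoise",
  representation(
    boxJitterSigma = "numeric",
    missRate = "numeric",
    spuriousRate = "numeric",
    scoreNoiseSigma = "numeric"
  ),
  prototype(boxJitterSigma = 0, missRate = 0, spuriousRate = 0,
            scoreNoiseSigma = 0)
)

setValidity("DetectorNoise", function(object) {
  v <- c(object@boxJitterSigma, object@missRate, object@spuriousRate,
         object@scoreNoiseSigma)
  if (any(!is.finite(v)) || any(v < 0))
    return("all noise parameters must be finite and non-negative")
  if (object@missRate > 1)
    return("missRate must lie in [0, 1]")
  TRUE
})

#' Construct a detector noise model
#'
#' @param boxJitterSigma corner jitter s.d. in pixels (default 0).
#' @param missRate per-box miss probability (default 0).
#' @param spuriousRate expected spurious boxes per frame (default 0).
#' @param scoreNoiseSigma score noise s.d. (default 0).
#' @return A [DetectorNoise-class] object.
#' @examples
#' detectorNoise(boxJitterSigma = 2, missRate = 0.1)
#' @export
detectorNoise <- function(boxJitterSigma = 0, missRate = 0,
                          spuriousRate = 0, scoreNoiseSigma = 0) {
  new("DetectorNoise", boxJitterSigma = boxJitterSigma, missRate = missRate,
      spuriousRate = spuriousRate, scoreNoiseSigma = scoreNoiseSigma)
}

#' Synthetic egocentric scene specification
#'
#' Fully determines one synthetic scene: an egocentric-like view of a target
#' hand operating a tool, plus independently moving distractor hands. The two
#' tool classes are rendered with identical sprites; they differ only in the
#' motion program driving the hand-tool pair, so per-frame appearance carries
#' no class information.
#'
#' @slot nFrames number of frames (>= 1).
#' @slot fps frames per second (default 25).
#' @slot frameWidth,frameHeight frame size in pixels (default 480 x 270,
#'   the 16:9 aspect of full-HD footage scaled down).
#' @slot toolClass `"scissors"` or `"needle_holders"`.
#' @slot motionProgram `"oscillate"` (small-amplitude linear oscillation of
#'   the rigid hand-tool pair, period ~12 frames), `"rotate"` (hand sweeps a
#'   circle about the fixed tool tip, period ~40 frames, emulating the
#'   suturing wrist rotation), or `"static"` (no motion; test fixture).
#' @slot nDistractors number of distractor hands, 0-3.
#' @slot noise a [DetectorNoise-class] model for the oracle detector.
#' @slot seed integer seed; rendering and trajectories are deterministic
#'   given the seed.
#' @exportClass SceneSpec
setClass("SceneSpec",
  representation(
    nFrames = "integer",
    fps = "numeric",
    frameWidth = "integer",
    frameHeight = "integer",
    toolClass = "character",
    motionProgram = "character",
    nDistractors = "integer",
    noise = "DetectorNoise",
    seed = "integer"
  )
)

setValidity("SceneSpec", function(object) {
  if (object@nFrames < 1L) return("nFrames must be >= 1")
  if (!object@toolClass %in% TOOL_CLASSES)
    return(sprintf("toolClass must be one of: %s",
                   paste(TOOL_CLASSES, collapse = ", ")))
  if (!object@motionProgram %in% MOTION_PROGRAMS)
    return(sprintf("motionProgram must be one of: %s",
                   paste(MOTION_PROGRAMS, collapse = ", ")))
  if (object@nDistractors < 0L || object@nDistractors > 3L)
    return("nDistractors must be between 0 and 3")
  if (object@frameWidth < 64L || object@frameHeight < 64L)
    return("frame must be at least 64 x 64 pixels")
  if (object@fps <= 0) return("fps must be positive")
  TRUE
})

#' Construct a scene specification
#'
#' The default motion program follows the tool class: scissors oscillate
#' (cutting strokes), needle holders rotate (suturing wrist sweep).
#'
#' @param nFrames number of frames.
#' @param toolClass `"scissors"` or `"needle_holders"`.
#' @param motionProgram motion program; defaults to the class-typical one.
#' @param nDistractors distractor hands (0-3, default 2).
#' @param noise a [DetectorNoise-class] object (default: noise-free).
#' @param seed integer seed.
#' @param fps frames per second (default 25).
#' @param frameWidth,frameHeight frame size (default 480 x 270).
#' @return A [SceneSpec-class] object.
#' @examples
#' sceneSpec(nFrames = 60, toolClass = "scissors", seed = 1)
#' @export
sceneSpec <- function(nFrames, toolClass = c("scissors", "needle_holders"),
                      motionProgram = NULL, nDistractors = 2L,
                      noise = detectorNoise(), seed = 1L, fps = 25,
                      frameWidth = 480L, frameHeight = 270L) {
  toolClass <- match.arg(toolClass)
  if (is.null(motionProgram))
    motionProgram <- if (toolClass == "scissors") "oscillate" else "rotate"
  new("SceneSpec", nFrames = as.integer(nFrames), fps = fps,
      frameWidth = as.integer(frameWidth),
      frameHeight = as.integer(frameHeight),
      toolClass = toolClass, motionProgram = motionProgram,
      nDistractors = as.integer(nDistractors), noise = noise,
      seed = as.integer(seed))
}

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(
    "SceneSpec: %d frames @ %g fps, %dx%d px\n  tool class: %s (motion: %s), %d distractor hand(s), seed %d\n",
    object@nFrames, object@fps, object@frameWidth, object@frameHeight,
    object@toolClass, object@motionProgram, object@nDistractors,
    object@seed))
})

#' Fixed-length window of target-hand crops
#'
#' The classifier's sample unit: `T` consecutive cropped-and-resized images
#' of the target hand, all 252 x 252 x 3, with gapless frame indices and one
#' tool-class label.
#'
#' @slot images list of `T` arrays, each 252 x 252 x 3 in `[0,1]`.
#' @slot frameIndices integer vector of `T` consecutive frame indices.
#' @slot label `"scissors"`, `"needle_holders"`, or `"unknown"`.
#' @exportClass ClipWindow
setClass("ClipWindow",
  representation(
    images = "list",
    frameIndices = "integer",
    label = "character"
  )
)

setValidity("ClipWindow", function(object) {
  Tn <- length(object@images)
  if (Tn < 1L) return("a ClipWindow must contain at least one image")
  if (length(object@frameIndices) != Tn)
    return("frameIndices length must equal the number of images")
  if (Tn > 1L && any(diff(object@frameIndices) != 1L))
    return("frameIndices must be consecutive (gapless)")
  dims <- vapply(object@images, function(x) paste(dim(x), collapse = "x"),
                 character(1))
  if (any(dims != "252x252x3"))
    return("every image must be 252x252x3")
  if (!object@label %in% c(TOOL_CLASSES, "unknown"))
    return("label must be a tool class or 'unknown'")
  TRUE
})

#' Number of frames in a clip window
#' @param x a [ClipWindow-class].
#' @return Integer window length `T`.
#' @export
clipLength <- function(x) length(x@images)

setMethod("show", "ClipWindow", function(object) {
  cat(sprintf("ClipWindow: T=%d frames [%d..%d], label=%s\n",
              clipLength(object), object@frameIndices[1],
              object@frameIndices[length(object@frameIndices)],
              object@label))
})

#' Motion classifier configuration
#'
#' Hyperparameters of the sequential tool classifier. Defaults follow the
#' training protocol the model was designed around: windows of T = 50 frames
#' (2 s at 25 fps), 128-d per-frame features, a 128-unit single-layer LSTM
#' with tanh activation, dropout 0.5 on the LSTM/head inputs, Adam at
#' learning rate 1e-3, batch size 5, 15 epochs.
#'
#' @slot tFrames window length T.
#' @slot featureDim per-frame visual feature dimension (128).
#' @slot recurrentHidden LSTM hidden size (128).
#' @slot headHidden MLP head hidden width.
#' @slot dropout dropout probability on LSTM input features.
#' @slot learningRate Adam learning rate.
#' @slot batchSize sequences per minibatch.
#' @slot epochs training epochs.
#' @slot classWeights named per-class positive weights; empty means
#'   inverse-frequency weights computed from the training counts.
#' @slot fusion how per-timestep probabilities fuse into one score:
#'   `"mean"`, `"last"`, or `"max"`.
#' @slot extractor feature extractor backend: `"smallcnn"` (fixed oriented
#'   conv bank + grid pooling + trained linear projection) or `"pool"`
#'   (grid pooling + trained linear projection).
#' @slot seed integer seed governing weight init, shuffling, dropout and
#'   fragment sampling.
#' @exportClass ClassifierConfig
setClass("ClassifierConfig",
  representation(
    tFrames = "integer",
    featureDim = "integer",
    recurrentHidden = "integer",
    headHidden = "integer",
    dropout = "numeric",
    learningRate = "numeric",
    batchSize = "integer",
    epochs = "integer",
    classWeights = "numeric",
    fusion = "character",
    extractor = "character",
    seed = "integer"
  )
)

setValidity("ClassifierConfig", function(object) {
  if (object@tFrames < 1L) return("tFrames must be >= 1")
  if (object@dropout < 0 || object@dropout >= 1)
    return("dropout must lie in [0, 1)")
  if (object@learningRate <= 0) return("learningRate must be positive")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@epochs < 0L) return("epochs must be >= 0")
  if (length(object@classWeights) &&
      (any(object@classWeights <= 0) || any(!is.finite(object@classWeights))))
    return("classWeights must be positive and finite")
  if (!object@fusion %in% c("mean", "last", "max"))
    return("fusion must be one of mean, last, max")
  if (!object@extractor %in% c("smallcnn", "pool"))
    return("extractor must be 'smallcnn' or 'pool'")
  TRUE
})

#' Construct a classifier configuration
#'
#' @param tFrames window length T (default 50).
#' @param featureDim per-frame feature dimension (default 128).
#' @param recurrentHidden LSTM hidden units (default 128).
#' @param headHidden MLP hidden width (default 64).
#' @param dropout dropout probability (default 0.5).
#' @param learningRate Adam learning rate (default 1e-3).
#' @param batchSize minibatch size (default 5).
#' @param epochs training epochs (default 15).
#' @param classWeights named numeric class weights, or empty for
#'   inverse-frequency weights from training counts.
#' @param fusion probability fusion rule (default `"mean"`).
#' @param extractor extractor backend (default `"smallcnn"`).
#' @param seed integer seed (default 1).
#' @return A [ClassifierConfig-class] object.
#' @examples
#' classifierConfig(tFrames = 25, seed = 7)
#' @export
classifierConfig <- function(tFrames = 50L, featureDim = 128L,
                             recurrentHidden = 128L, headHidden = 64L,
                             dropout = 0.5, learningRate = 1e-3,
                             batchSize = 5L, epochs = 15L,
                             classWeights = numeric(0), fusion = "mean",
                             extractor = "smallcnn", seed = 1L) {
  new("ClassifierConfig", tFrames = as.integer(tFrames),
      featureDim = as.integer(featureDim),
      recurrentHidden = as.integer(recurrentHidden),
      headHidden = as.integer(headHidden), dropout = dropout,
      learningRate = learningRate, batchSize = as.integer(batchSize),
      epochs = as.integer(epochs), classWeights = classWeights,
      fusion = fusion, extractor = extractor, seed = as.integer(seed))
}

setMethod("show", "ClassifierConfig", function(object) {
  cat(sprintf(
    "ClassifierConfig: T=%d, features %d-d, LSTM %d, head %d\n  dropout %.2f, Adam lr %.1e, batch %d, %d epochs, fusion '%s', extractor '%s', seed %d\n",
    object@tFrames, object@featureDim, object@recurrentHidden,
    object@headHidden, object@dropout, object@learningRate,
    object@batchSize, object@epochs, object@fusion, object@extractor,
    object@seed))
})

#' Trained motion classifier
#'
#' A fitted sequential tool classifier: the jointly trained linear feature
#' projection, LSTM recurrent aggregator and sigmoid MLP head, together with
#' the configuration, class weights, feature standardization statistics and
#' per-epoch training loss history. Scissors is the positive class (coded 1).
#'
#' @slot config the [ClassifierConfig-class] used for training.
#' @slot params named list of weight matrices and bias vectors.
#' @slot featureCenter,featureScale standardization of the raw descriptors.
#' @slot classWeights the per-class loss weights actually used.
#' @slot lossHistory numeric vector, mean weighted cross-entropy per epoch.
#' @slot recurrent logical; `FALSE` for the per-frame baseline (no LSTM).
#' @exportClass MotionClassifier
setClass("MotionClassifier",
  representation(
    config = "ClassifierConfig",
    params = "list",
    featureCenter = "numeric",
    featureScale = "numeric",
    classWeights = "numeric",
    lossHistory = "numeric",
    recurrent = "logical"
  )
)

setMethod("show", "MotionClassifier", function(object) {
  kind <- if (object@recurrent) "sequential (LSTM)" else "per-frame baseline"
  cat(sprintf(
    "MotionClassifier [%s]: T=%d, %d epochs trained\n  class weights: %s\n  final training loss: %s\n",
    kind, object@config@tFrames, length(object@lossHistory),
    paste(sprintf("%s=%.4g", names(object@classWeights),
                  object@classWeights), collapse = ", "),
    if (length(object@lossHistory))
      sprintf("%.4f", object@lossHistory[length(object@lossHistory)])
    else "(untrained)"))
})
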