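## Phase 1 -> 2 -> 3 wiring: oracle (or external) detections, per-frame
## target-hand selection, track/run assembly, window cutting, classifier
## training and evaluation, with selection metrics audited against the
## scene ground truth along the way.

#' Run selection and feature extraction over one scene
#'
#' Runs the oracle detector, selects the target hand for the highest-scored
#' tool of every frame, audits the selection against the ground-truth
#' operating hand, and computes the per-frame descriptor of every selected
#' hand crop (render, crop, resize 252x252, descriptor).
#'
#' @param truth a `SceneTruth` from [makeScene()].
#' @param extractor a [featureExtractor()].
#' @param noise detector noise (default: the scene's own model).
#' @param pad crop padding fraction (default 0).
#' @param detections optional externally supplied detections data.frame
#'   (e.g. read with [readDetectionsJson()]); replaces the oracle detector.
#' @return List: `track` (selected frames + boxes), `runs` (from
#'   [findRuns()]), `descriptors` (one matrix row per track entry),
#'   `selection` ([selectionMetrics()] vs. truth), `label`.
#' @export
processScene <- function(truth, extractor, noise = truth$spec@noise,
                         pad = 0, detections = NULL) {
  spec <- truth$spec
  dets <- if (is.null(detections)) oracleDetect(truth, noise) else detections
  n <- spec@nFrames
  selBox <- matrix(NA_real_, n, 4)
  byFrame <- split(dets, dets$frame_index)
  for (fd in byFrame) {
    fi <- fd$frame_index[1]
    hands <- fd[fd$category == "hand", , drop = FALSE]
    tools <- fd[fd$category == "tool", , drop = FALSE]
    if (nrow(tools) == 0L) next
    tool <- tools[which.max(tools$score), , drop = FALSE]
    sel <- selectTargetHand(hands, tool)
    if (!is.na(sel$selected_hand_index))
      selBox[fi + 1L, ] <- detBoxes(hands)[sel$selected_hand_index, ]
  }
  selection <- selectionMetrics(selBox, truth$handBox)
  selected <- which(!is.na(selBox[, 1]))
  track <- data.frame(frame_index = selected - 1L,
                      x_min = selBox[selected, 1], y_min = selBox[selected, 2],
                      x_max = selBox[selected, 3], y_max = selBox[selected, 4])
  runs <- findRuns(track)
  render <- sceneFrameRenderer(truth)
  descriptors <- matrix(0, nrow(track), extractor$descriptorDim)
  for (r in seq_len(nrow(track))) {
    box <- as.numeric(track[r, -1])
    if (pad > 0) {
      m <- pad * max(box[3] - box[1], box[4] - box[2])
      box <- c(box[1] - m, box[2] - m, box[3] + m, box[4] + m)
    }
    crop <- resizeCrop(render(track$frame_index[r], box = box))
    descriptors[r, ] <- extractor$descriptor(crop)
  }
  list(track = track, runs = runs, descriptors = descriptors,
       selection = selection, label = spec@toolClass)
}

#' Pipeline run configuration
#'
#' Bundles every knob of a pipeline run; together with the seed it fully
#' determines the result. Defaults are the desk-scale study conditions: 400
#' scenes of 55 frames each (one T = 50 window per scene, so all 400 clips
#' come from distinct backgrounds and geometries, emulating clip diversity
#' across surgeries), two distractor hands, noise-free detections, and a
#' 75/25 scene-level split (300 training / 100 held-out test windows). For
#' window-length sweeps up to T = 100 raise `framesPerScene` to at least
#' `max(tValues)`.
#'
#' @param nScenes number of scenes (classes alternate scene by scene).
#' @param framesPerScene frames per scene.
#' @param tFrames window length T.
#' @param stride window-cutting stride (train and test).
#' @param testFraction fraction of scenes held out (split by scene, never by
#'   window, so no frame leaks across the split).
#' @param nDistractors distractor hands per scene.
#' @param noise a [detectorNoise()].
#' @param extractor extractor backend name.
#' @param epochs,batchSize,learningRate,dropout,fusion classifier settings
#'   (see [classifierConfig()]).
#' @param baseline also train/evaluate the per-frame baseline.
#' @param pad crop padding fraction.
#' @param seed master seed.
#' @param outDir optional output directory for JSON/CSV reports.
#' @return A validated `RunConfig` list.
#' @export
runConfig <- function(nScenes = 400L, framesPerScene = 55L, tFrames = 50L,
                      stride = 25L, testFraction = 0.25, nDistractors = 2L,
                      noise = detectorNoise(), extractor = "smallcnn",
                      epochs = 15L, batchSize = 5L, learningRate = 1e-3,
                      dropout = 0.5, fusion = "mean", baseline = TRUE,
                      pad = 0, seed = 1L, outDir = NULL) {
  cfg <- list(nScenes = as.integer(nScenes),
              framesPerScene = as.integer(framesPerScene),
              tFrames = as.integer(tFrames), stride = as.integer(stride),
              testFraction = testFraction,
              nDistractors = as.integer(nDistractors), noise = noise,
              extractor = extractor, epochs = as.integer(epochs),
              batchSize = as.integer(batchSize),
              learningRate = learningRate, dropout = dropout,
              fusion = fusion, baseline = isTRUE(baseline), pad = pad,
              seed = as.integer(seed), outDir = outDir)
  validateRunConfig(cfg)
  structure(cfg, class = "RunConfig")
}

validateRunConfig <- function(cfg) {
  checks <- list(
    nScenes = cfg$nScenes >= 4L,
    framesPerScene = cfg$framesPerScene >= 1L,
    tFrames = cfg$tFrames >= 1L,
    stride = cfg$stride >= 1L,
    testFraction = cfg$testFraction > 0 && cfg$testFraction < 1,
    nDistractors = cfg$nDistractors >= 0L && cfg$nDistractors <= 3L,
    extractor = cfg$extractor %in% c("smallcnn", "pool"),
    epochs = cfg$epochs >= 0L,
    fusion = cfg$fusion %in% c("mean", "last", "max"))
  bad <- names(checks)[!vapply(checks, isTRUE, logical(1))]
  if (length(bad))
    stop(sprintf("invalid RunConfig field(s): %s", paste(bad, collapse = ", ")))
  invisible(TRUE)
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return `readRunConfig` returns a `RunConfig`; `writeRunConfig` invisibly
#'   returns `path`.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  noise <- do.call(detectorNoise, as.list(y$noise %||% list()))
  y$noise <- NULL
  known <- names(formals(runConfig))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop(sprintf("unknown RunConfig field(s): %s",
                 paste(unknown, collapse = ", ")))
  do.call(runConfig, c(y, list(noise = noise)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname readRunConfig
#' @param cfg a `RunConfig`.
#' @export
writeRunConfig <- function(cfg, path) {
  y <- unclass(cfg)
  y$noise <- list(boxJitterSigma = cfg$noise@boxJitterSigma,
                  missRate = cfg$noise@missRate,
                  spuriousRate = cfg$noise@spuriousRate,
                  scoreNoiseSigma = cfg$noise@scoreNoiseSigma)
  y <- y[!vapply(y, is.null, logical(1))]
  yaml::write_yaml(y, path)
  invisible(path)
}

sceneSpecsForRun <- function(cfg) {
  lapply(seq_len(cfg$nScenes), function(i) {
    cls <- if (i %% 2L == 1L) "scissors" else "needle_holders"
    sceneSpec(nFrames = cfg$framesPerScene, toolClass = cls,
              nDistractors = cfg$nDistractors, noise = cfg$noise,
              seed = cfg$seed * 1000L + i)
  })
}

#' Assemble selection runs and descriptors for a whole scene set
#'
#' Simulates every scene of the run configuration, pushes each through
#' detection, selection and feature extraction, and pools the resulting
#' selection-run descriptor matrices into train and test
#' [clipFeatureSet()]s (split by scene).
#'
#' @param cfg a [runConfig()].
#' @param extractor optional pre-built [featureExtractor()].
#' @param progress print per-scene progress (default FALSE).
#' @return List: `train`, `test` (run-level feature sets), `selection`
#'   (pooled counts + metrics), `nTestScenes`.
#' @export
assembleRunData <- function(cfg, extractor = NULL, progress = FALSE) {
  specs <- sceneSpecsForRun(cfg)
  if (is.null(extractor))
    extractor <- featureExtractor(cfg$extractor, seed = cfg$seed)
  nTest <- max(2L, as.integer(round(cfg$nScenes * cfg$testFraction)))
  testIdx <- seq.int(cfg$nScenes - nTest + 1L, cfg$nScenes)
  descr <- list(); labs <- character(0); isTest <- logical(0)
  counts <- confusionCounts()
  for (i in seq_along(specs)) {
    truth <- makeScene(specs[[i]])
    ps <- processScene(truth, extractor, pad = cfg$pad)
    counts <- confusionCounts(
      tp = counts[["tp"]] + ps$selection$counts[["tp"]],
      fp = counts[["fp"]] + ps$selection$counts[["fp"]],
      fn = counts[["fn"]] + ps$selection$counts[["fn"]],
      tn = counts[["tn"]] + ps$selection$counts[["tn"]])
    for (r in seq_len(nrow(ps$runs))) {
      descr[[length(descr) + 1L]] <-
        ps$descriptors[ps$runs$start_row[r]:ps$runs$end_row[r], ,
                       drop = FALSE]
      labs <- c(labs, ps$label)
      isTest <- c(isTest, i %in% testIdx)
    }
    if (progress && i %% 10L == 0L)
      message(sprintf("  scene %d/%d", i, length(specs)))
  }
  selection <- c(list(counts = counts), prfMetrics(counts))
  list(train = clipFeatureSet(descr[!isTest], labs[!isTest], extractor),
       test = clipFeatureSet(descr[isTest], labs[isTest], extractor),
       selection = selection, nTestScenes = nTest)
}

#' Run the full three-phase pipeline on synthetic scenes
#'
#' Simulate -> detect -> select -> assemble windows -> train -> classify ->
#' evaluate. Reports selection metrics, sequential-classifier metrics (with
#' ROC/AUC), and optionally the per-frame appearance baseline, writing
#' JSON/CSV reports when `cfg$outDir` is set.
#'
#' @param cfg a [runConfig()].
#' @param progress print progress messages (default FALSE).
#' @return List: `selection`, `classification`, `roc`, `auc`, `baseline`
#'   (`NULL` unless requested), `predictions`, `lossHistory`, `config`.
#' @export
runPipeline <- function(cfg = runConfig(), progress = FALSE) {
  validateRunConfig(cfg)
  data <- assembleRunData(cfg, progress = progress)
  trainW <- windowFeatureSet(data$train, cfg$tFrames, cfg$stride)
  testW <- windowFeatureSet(data$test, cfg$tFrames, cfg$stride)
  if (!length(testW$labels) || !length(trainW$labels))
    warning(sprintf(
      "no windows of T=%d frames could be cut (longest runs are shorter); nothing to classify",
      cfg$tFrames))
  ccfg <- classifierConfig(tFrames = cfg$tFrames, epochs = cfg$epochs,
                           batchSize = cfg$batchSize,
                           learningRate = cfg$learningRate,
                           dropout = cfg$dropout, fusion = cfg$fusion,
                           extractor = cfg$extractor, seed = cfg$seed)
  result <- list(selection = data$selection, config = cfg,
                 nTrainWindows = length(trainW$labels),
                 nTestWindows = length(testW$labels))
  if (length(trainW$labels) && length(testW$labels)) {
    if (progress) message("training sequential classifier...")
    model <- trainMotionClassifier(trainW, ccfg)
    preds <- classifyClips(model, testW)
    result$classification <- classificationMetrics(preds$label, preds$truth)
    roc <- rocCurveAuc(preds$p_final, preds$truth)
    result$roc <- roc$roc
    result$auc <- roc$auc
    result$predictions <- preds
    result$lossHistory <- model@lossHistory
    result$model <- model
    if (cfg$baseline) {
      if (progress) message("training per-frame baseline...")
      bmodel <- trainPerFrameBaseline(data$train, ccfg)
      bpred <- predictFrames(bmodel, data$test)
      result$baseline <- classificationMetrics(bpred$label, bpred$truth)
      result$baselineModel <- bmodel
    }
  }
  if (!is.null(cfg$outDir)) writePipelineReport(result, cfg$outDir)
  result
}

writePipelineReport <- function(result, outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  rep <- list(
    selection = result$selection[c("accuracy", "recall", "precision",
                                   "f_measure")],
    classification = if (!is.null(result$classification))
      result$classification[c("accuracy", "recall", "precision",
                              "f_measure")],
    auc = result$auc,
    baseline = if (!is.null(result$baseline))
      result$baseline[c("accuracy", "recall", "precision", "f_measure")],
    n_train_windows = result$nTrainWindows,
    n_test_windows = result$nTestWindows,
    loss_history = result$lossHistory,
    seed = result$config$seed)
  jsonlite::write_json(rep, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = 10, null = "null")
  if (!is.null(result$roc))
    utils::write.csv(result$roc, file.path(outDir, "roc.csv"),
                     row.names = FALSE)
  invisible(outDir)
}

#' Window-length sweep
#'
#' Re-windows, re-trains and re-evaluates the pipeline for each window
#' length T, sharing one simulation/selection/feature pass across all T.
#' Duplicate T values are deduplicated with a warning.
#'
#' @param cfg a [runConfig()]; `framesPerScene` must be at least `max(tValues)`.
#' @param tValues window lengths to compare (default 25, 50, 100).
#' @param progress print progress (default FALSE).
#' @return A data.frame with one row per T: `t_frames`, `n_train`, `n_test`,
#'   `accuracy`, `recall`, `precision`, `f_measure`, `auc`.
#' @export
sweepWindowLength <- function(cfg = runConfig(), tValues = c(25L, 50L, 100L),
                              progress = FALSE) {
  validateRunConfig(cfg)
  if (anyDuplicated(tValues)) {
    warning("duplicate T values removed from sweep")
    tValues <- unique(tValues)
  }
  data <- assembleRunData(cfg, progress = progress)
  rows <- lapply(as.integer(tValues), function(Tn) {
    trainW <- windowFeatureSet(data$train, Tn, cfg$stride)
    testW <- windowFeatureSet(data$test, Tn, min(cfg$stride, Tn))
    ccfg <- classifierConfig(tFrames = Tn, epochs = cfg$epochs,
                             batchSize = cfg$batchSize,
                             learningRate = cfg$learningRate,
                             dropout = cfg$dropout, fusion = cfg$fusion,
                             extractor = cfg$extractor, seed = cfg$seed)
    if (progress) message(sprintf("sweep: T=%d (%d train / %d test windows)",
                                  Tn, length(trainW$labels),
                                  length(testW$labels)))
    model <- trainMotionClassifier(trainW, ccfg)
    preds <- classifyClips(model, testW)
    m <- classificationMetrics(preds$label, preds$truth)
    auc <- rocCurveAuc(preds$p_final, preds$truth)$auc
    data.frame(t_frames = Tn, n_train = length(trainW$labels),
               n_test = length(testW$labels), accuracy = m$accuracy,
               recall = m$recall, precision = m$precision,
               f_measure = m$f_measure, auc = auc)
  })
  do.call(rbind, rows)
}

#' Simulate scenes to disk
#'
#' Renders each scene of a run configuration into
#' `<outDir>/scene_%03d/frame_%06d.png` with COCO ground-truth annotations
#' (`annotations.json`) and appends one line per scene to a clip-label
#' manifest (`manifest.jsonl`).
#'
#' @param cfg a [runConfig()] (or path to its YAML).
#' @param outDir output directory.
#' @param nScenes how many of the configured scenes to write (default all;
#'   rendering to PNG is the slow path, intended for small scene sets).
#' @return Invisibly, the vector of scene directories.
#' @export
cmdSimulate <- function(cfg, outDir, nScenes = cfg$nScenes) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  validateRunConfig(cfg)
  specs <- sceneSpecsForRun(cfg)[seq_len(nScenes)]
  manifest <- file.path(outDir, "manifest.jsonl")
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  if (file.exists(manifest)) file.remove(manifest)
  dirs <- vapply(seq_along(specs), function(i) {
    d <- file.path(outDir, sprintf("scene_%03d", i))
    truth <- makeScene(specs[[i]])
    renderFrames(truth, d)
    writeCocoAnnotations(truth, file.path(d, "annotations.json"),
                         video = sprintf("scene_%03d", i))
    appendClipManifest(manifest, sprintf("scene_%03d", i),
                       specs[[i]]@toolClass, 0L, specs[[i]]@nFrames)
    d
  }, character(1))
  invisible(dirs)
}

#' Accuracy of a uniform-random classifier on balanced labels
#'
#' The chance rate of the binary task: random uniform scores thresholded at
#' 0.5 against balanced random labels. Converges to 0.5; used as the
#' reference band for the per-frame appearance baseline.
#'
#' @param n number of simulated sequences (default 10000).
#' @param seed integer seed.
#' @return Empirical accuracy.
#' @export
randomClassifierAccuracy <- function(n = 10000L, seed = 1L) {
  set.seed(seed)
  labels <- rep(c(0L, 1L), length.out = n)[sample.int(n)]
  preds <- as.integer(runif(n) >= 0.5)
  mean(preds == labels)
}
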