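test_that("scene specs validate their fields", {
  expect_error(sceneSpec(nFrames = 0, toolClass = "scissors"), "nFrames")
  expect_error(sceneSpec(nFrames = 5, toolClass = "scissors",
                         nDistractors = 4), "nDistractors")
  expect_error(detectorNoise(missRate = 1.5), "missRate")
  expect_error(detectorNoise(boxJitterSigma = -1), "non-negative")
  # default motion program follows the tool class
  expect_identical(sceneSpec(10, "scissors")@motionProgram, "oscillate")
  expect_identical(sceneSpec(10, "needle_holders")@motionProgram, "rotate")
})

test_that("trajectories are deterministic given the seed", {
  s1 <- makeScene(sceneSpec(40, "needle_holders", seed = 77))
  s2 <- makeScene(sceneSpec(40, "needle_holders", seed = 77))
  expect_identical(s1$handBox, s2$handBox)
  expect_identical(s1$toolBox, s2$toolBox)
  expect_identical(s1$backgroundSmall, s2$backgroundSmall)
  s3 <- makeScene(sceneSpec(40, "needle_holders", seed = 78))
  expect_false(identical(s1$handBox, s3$handBox))
})

test_that("oscillation has zero net displacement over full periods", {
  truth <- makeScene(sceneSpec(49, "scissors", seed = 5))  # 4 periods of 12
  c0 <- truth$handCenter[1, ]
  for (k in 1:4)
    expect_equal(truth$handCenter[1 + 12 * k, ], c0, tolerance = 1e-9)
  # the hand-tool pair is rigid: tip offset from center is constant
  offs <- truth$toolTip - truth$handCenter
  expect_lt(max(abs(sweep(offs, 2, offs[1, ]))), 1e-9)
})

test_that("rotation keeps the hand at fixed radius about the tool tip", {
  truth <- makeScene(sceneSpec(80, "needle_holders", seed = 9))
  rad <- sqrt(rowSums((truth$handCenter - truth$toolTip)^2))
  expect_lt(max(abs(rad - rad[1])), 1)  # fixed radius within 1 px
  # the tip (anchor) itself never moves
  expect_lt(max(abs(sweep(truth$toolTip, 2, truth$toolTip[1, ]))), 1e-9)
  # one full cycle: the hand returns to its start after the period
  expect_equal(truth$handCenter[41, ], truth$handCenter[1, ],
               tolerance = 1e-9)
})

test_that("hand and tool boxes always overlap (selection is well-posed)", {
  for (seed in 1:5) {
    for (cls in c("scissors", "needle_holders")) {
      truth <- makeScene(sceneSpec(55, cls, seed = seed))
      iou <- overlapRatio(truth$handBox, truth$toolBox)
      expect_true(all(iou > 0))
    }
  }
})

test_that("distractor hands never overlap the tool box meaningfully", {
  for (seed in 11:16) {
    truth <- makeScene(sceneSpec(55, "needle_holders", nDistractors = 3,
                                 seed = seed))
    for (db in truth$distractorBoxes)
      expect_true(all(overlapRatio(db, truth$toolBox) <= 0.05))
  }
})

test_that("the adversarial mode does place distractors near the action", {
  near <- makeScene(sceneSpec(30, "needle_holders", nDistractors = 2,
                              seed = 3), adversarial = TRUE)
  d <- sapply(near$distractorCenters, function(dc)
    min(sqrt(rowSums(sweep(dc, 2, near$toolTip[1, ])^2))))
  expect_true(all(d < 130))
})

test_that("region rendering equals cropping the full frame render", {
  truth <- makeScene(sceneSpec(12, "needle_holders", seed = 42))
  render <- sceneFrameRenderer(truth)
  for (i in c(0L, 5L, 11L)) {
    full <- render(i)
    box <- truth$handBox[i + 1, ]
    expect_identical(render(i, box = box), cropRegion(full, box))
  }
  expect_error(render(12L), "out of range")
})

test_that("per-frame appearance is indistinguishable between classes", {
  # mean crop intensity per frame, 100 frames per class, distinct scenes;
  # identical sprites + class-independent backgrounds => same distribution
  stat <- function(cls, seeds) {
    unlist(lapply(seeds, function(s) {
      truth <- makeScene(sceneSpec(20, cls, seed = s))
      render <- sceneFrameRenderer(truth)
      vapply(0:19, function(i)
        mean(render(i, box = truth$handBox[i + 1, ])), numeric(1))
    }))
  }
  a <- stat("scissors", 201:205)
  b <- stat("needle_holders", 301:305)
  expect_gt(suppressWarnings(stats::ks.test(a, b)$p.value), 0.01)
})

test_that("the noise-free oracle detector reproduces the truth exactly", {
  truth <- makeScene(sceneSpec(25, "scissors", nDistractors = 2, seed = 8))
  dets <- oracleDetect(truth)
  expect_true(all(dets$score == 1))
  expect_identical(nrow(dets), 25L * 4L)  # target + 2 distractors + tool
  tools <- dets[dets$category == "tool", ]
  expect_equal(unname(detBoxes <- as.matrix(
    tools[order(tools$frame_index), c("x_min", "y_min", "x_max", "y_max")])),
    unname(truth$toolBox))
})

test_that("misses thin detections at the configured rate", {
  truth <- makeScene(sceneSpec(500, "scissors", nDistractors = 1, seed = 4))
  all1 <- oracleDetect(truth, detectorNoise(missRate = 1), seed = 10)
  expect_true(is.null(all1) || nrow(all1) == 0L)
  some <- oracleDetect(truth, detectorNoise(missRate = 0.1), seed = 10)
  kept <- nrow(some) / (500 * 3)
  expect_gt(kept, 0.87); expect_lt(kept, 0.93)
})

test_that("jitter perturbs boxes and spurious boxes carry low scores", {
  truth <- makeScene(sceneSpec(60, "scissors", nDistractors = 0, seed = 6))
  noisy <- oracleDetect(truth, detectorNoise(boxJitterSigma = 2,
                                             spuriousRate = 0.5,
                                             scoreNoiseSigma = 0.05),
                        seed = 11)
  hands <- noisy[noisy$category == "hand", ]
  realHands <- hands[hands$score > 0.5, ]
  expect_gt(mean(abs(realHands$x_min - truth$handBox[
    realHands$frame_index + 1, 1])), 0.5)
  spurious <- noisy[noisy$score <= 0.3, ]
  expect_gt(nrow(spurious), 5)
  # boxes remain valid after jitter
  expect_true(all(noisy$x_max > noisy$x_min & noisy$y_max > noisy$y_min))
})

test_that("COCO annotations round-trip losslessly and keep category ids", {
  d <- withr::local_tempdir()
  truth <- makeScene(sceneSpec(10, "needle_holders", nDistractors = 1,
                               seed = 12))
  f <- file.path(d, "ann.json")
  writeCocoAnnotations(truth, f, video = "sceneA")
  back <- readCocoAnnotations(f)
  expect_identical(nrow(back$images), 10L)
  expect_identical(back$categories$name, c("hand", "tool"))
  expect_identical(back$categories$id, c(1L, 2L))
  ann <- back$annotations
  expect_true(all(c("id", "image_id", "category_id", "area", "iscrowd",
                    "x_min", "y_min", "x_max", "y_max") %in% names(ann)))
  target <- ann[ann$category_id == 1L & ann$target, ]
  target <- target[order(target$image_id), ]
  expect_equal(unname(as.matrix(target[, c("x_min", "y_min", "x_max",
                                           "y_max")])),
               unname(truth$handBox), tolerance = 1e-6)
  tools <- ann[ann$category_id == 2L, ]
  expect_equal(unname(as.matrix(tools[order(tools$image_id),
                                      c("x_min", "y_min", "x_max",
                                        "y_max")])),
               unname(truth$toolBox), tolerance = 1e-6)
  # same scene written twice is byte-identical (full determinism)
  f2 <- file.path(d, "ann2.json")
  writeCocoAnnotations(makeScene(sceneSpec(10, "needle_holders",
                                           nDistractors = 1, seed = 12)),
                       f2, video = "sceneA")
  expect_identical(readLines(f), readLines(f2))
})

test_that("detections JSON round-trips through the exchange format", {
  d <- withr::local_tempdir()
  truth <- makeScene(sceneSpec(6, "scissors", seed = 14))
  dets <- oracleDetect(truth, detectorNoise(boxJitterSigma = 1), seed = 2)
  f <- file.path(d, "dets.json")
  writeDetectionsJson(dets, f)
  back <- readDetectionsJson(f)
  expect_equal(back$frame_index, dets$frame_index)
  expect_identical(back$category, dets$category)
  expect_equal(detBoxes <- as.matrix(back[, 4:7]),
               as.matrix(dets[, 4:7]), tolerance = 1e-6)
})

test_that("rendered frame files are written and read back faithfully", {
  d <- withr::local_tempdir()
  truth <- makeScene(sceneSpec(3, "scissors", seed = 15))
  paths <- renderFrames(truth, file.path(d, "frames"))
  expect_length(paths, 3)
  expect_true(all(file.exists(paths)))
  reader <- frameReader(file.path(d, "frames"))
  img <- reader(1)
  direct <- sceneFrameRenderer(truth)(1)
  expect_identical(dim(img), dim(direct))
  expect_lt(max(abs(img - direct)), 1 / 255)  # 8-bit PNG quantization
})

test_that("a static scene renders identical consecutive frames", {
  truth <- makeScene(sceneSpec(4, "scissors", motionProgram = "static",
                               seed = 16))
  render <- sceneFrameRenderer(truth)
  f0 <- render(0)
  for (i in 1:3) expect_identical(render(i), f0)
})
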