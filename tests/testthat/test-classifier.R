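test_that("inverse-frequency class weights are count-normalized", {
  w <- computeClassWeights(c(scissors = 756, needle_holders = 2894))
  expect_equal(unname(w["scissors"]), 3650 / 1512, tolerance = 1e-12)
  expect_equal(unname(w["needle_holders"]), 3650 / 5788, tolerance = 1e-12)
  expect_equal(round(unname(w), 4), c(2.414, 0.6306))
  expect_equal(unname(computeClassWeights(c(a = 10, b = 10))), c(1, 1))
  expect_equal(unname(computeClassWeights(c(a = 1, b = 3))), c(2, 2 / 3))
  # count-weighted mean of the weights is 1 for any counts
  set.seed(5)
  cnt <- sample(1:500, 4)
  w4 <- computeClassWeights(setNames(cnt, letters[1:4]))
  expect_equal(sum(w4 * cnt) / sum(cnt), 1)
  expect_error(computeClassWeights(c(a = 0, b = 5)), "positive")
})

test_that("weighted cross-entropy has its closed-form values", {
  expect_lt(weightedCrossEntropy(rep(1, 5), 1), 1e-6)
  expect_equal(weightedCrossEntropy(rep(0.5, 7), 1), log(2))
  expect_equal(weightedCrossEntropy(c(0.2, 0.4), 0, classWeights = c(2, 1)),
               2 * mean(c(-log(0.8), -log(0.6))))
  expect_equal(round(weightedCrossEntropy(c(0.2, 0.4), 0,
                                          classWeights = c(2, 1)), 4),
               0.734)
})

test_that("weighted cross-entropy reduces to plain BCE and scales linearly", {
  set.seed(13)
  p <- runif(20, 0.01, 0.99)
  plainBce <- mean(-log(p))  # independent direct evaluation, y = 1
  expect_equal(weightedCrossEntropy(p, 1, c(1, 1)), plainBce)
  for (w in c(0.5, 2, 7))
    expect_equal(weightedCrossEntropy(p, 1, c(1, w)), w * plainBce)
  # doubling every class weight doubles the loss at fixed probabilities
  expect_equal(weightedCrossEntropy(p, 0, c(4, 6)),
               2 * weightedCrossEntropy(p, 0, c(2, 3)))
  # class-name labels map scissors to the positive class
  expect_equal(weightedCrossEntropy(p, "scissors",
                                    c(needle_holders = 1, scissors = 3)),
               3 * plainBce)
})

test_that("zero-weight LSTM aggregation is identically zero", {
  Fd <- 6L; H <- 4L
  params <- list(Wx = matrix(0, Fd, 4 * H), Wh = matrix(0, H, 4 * H),
                 b = numeric(4 * H))
  psi <- matrix(rnorm(10 * Fd), 10, Fd)
  out <- aggregateSequence(psi, params)
  expect_identical(dim(out), c(10L, H))
  expect_true(all(out == 0))
})

test_that("aggregation is causal: truncation preserves the prefix", {
  set.seed(17)
  Fd <- 6L; H <- 5L
  params <- list(Wx = matrix(rnorm(Fd * 4 * H, sd = 0.3), Fd, 4 * H),
                 Wh = matrix(rnorm(H * 4 * H, sd = 0.3), H, 4 * H),
                 b = rnorm(4 * H, sd = 0.1))
  psi <- matrix(rnorm(12 * Fd), 12, Fd)
  full <- aggregateSequence(psi, params)
  for (k in c(1L, 5L, 11L)) {
    trunc <- aggregateSequence(psi[seq_len(k), , drop = FALSE], params)
    expect_equal(trunc, full[seq_len(k), , drop = FALSE], tolerance = 1e-12)
  }
  # altering later frames leaves earlier aggregated features unchanged
  psi2 <- psi; psi2[9:12, ] <- rnorm(4 * Fd)
  full2 <- aggregateSequence(psi2, params)
  expect_equal(full2[1:8, ], full[1:8, ], tolerance = 1e-12)
})

test_that("one LSTM step matches the hand-rolled cell equations", {
  set.seed(19)
  Fd <- 4L; H <- 3L
  params <- list(Wx = matrix(rnorm(Fd * 4 * H), Fd, 4 * H),
                 Wh = matrix(rnorm(H * 4 * H), H, 4 * H),
                 b = rnorm(4 * H))
  x <- rnorm(Fd)
  out <- aggregateSequence(matrix(x, 1, Fd), params)
  # independent single-step recurrence from the standard cell equations
  sig <- function(z) 1 / (1 + exp(-z))
  z <- as.numeric(x %*% params$Wx) + params$b   # h_0 = 0
  i <- sig(z[1:H]); f <- sig(z[(H + 1):(2 * H)])
  g <- tanh(z[(2 * H + 1):(3 * H)]); o <- sig(z[(3 * H + 1):(4 * H)])
  cc <- f * 0 + i * g
  expect_equal(as.numeric(out), o * tanh(cc), tolerance = 1e-12)
})

test_that("head probabilities follow the affine-ReLU-affine-sigmoid form", {
  H <- 4L; M <- 3L
  zero <- list(W1 = matrix(0, H, M), b1 = numeric(M),
               W2 = matrix(0, M, 1), b2 = 0)
  psiHat <- matrix(rnorm(6 * H), 6, H)
  expect_equal(predictTimesteps(psiHat, zero), rep(0.5, 6))
  set.seed(23)
  head <- list(W1 = matrix(rnorm(H * M), H, M), b1 = rnorm(M),
               W2 = matrix(rnorm(M), M, 1), b2 = 0.3)
  p <- predictTimesteps(psiHat, head)
  expect_true(all(p > 0 & p < 1))
  # independent forward-pass oracle, row by row
  for (t in 1:6) {
    a1 <- as.numeric(psiHat[t, ] %*% head$W1) + head$b1
    oracle <- 1 / (1 + exp(-(sum(pmax(a1, 0) * head$W2) + head$b2)))
    expect_equal(p[t], oracle, tolerance = 1e-12)
  }
  # raising the output bias strictly raises every probability
  headUp <- head; headUp$b2 <- head$b2 + 0.5
  expect_true(all(predictTimesteps(psiHat, headUp) > p))
})

test_that("sequence fusion rules and the decision threshold behave", {
  expect_equal(sequenceLabel(rep(0.9, 10))$pFinal, 0.9)
  half <- sequenceLabel(c(0.2, 0.8))
  expect_equal(half$pFinal, 0.5)
  expect_identical(half$label, "scissors")  # >= 0.5 convention
  set.seed(29)
  p <- runif(33)
  expect_equal(sequenceLabel(p)$pFinal, sum(p) / length(p))
  expect_equal(sequenceLabel(p, "last")$pFinal, p[33])
  expect_equal(sequenceLabel(p, "max")$pFinal, max(p))
  expect_identical(sequenceLabel(c(0.1, 0.2))$label, "needle_holders")
})

test_that("backpropagation matches finite differences", {
  set.seed(31)
  B <- 2L; Tn <- 3L; D <- 5L; Fd <- 4L; H <- 3L; M <- 3L
  params <- toolmotion:::nnInitParams(D, Fd, H, M, TRUE)
  descr <- array(rnorm(B * Tn * D), c(B, Tn, D))
  y <- c(0, 1); w <- c(1.5, 0.8)
  lossFn <- function(pp) {
    fwd <- toolmotion:::nnForwardSeq(descr, pp)
    mean(vapply(1:B, function(b)
      w[b] * mean(-(y[b] * log(fwd$P[b, ]) +
                      (1 - y[b]) * log(1 - fwd$P[b, ]))), numeric(1)))
  }
  fwd <- toolmotion:::nnForwardSeq(descr, params)
  grads <- toolmotion:::nnBackwardSeq(
    fwd, params, (fwd$P - matrix(y, B, Tn)) * (w / (B * Tn)))
  eps <- 1e-6
  for (k in names(grads)) {
    for (i in seq_len(min(length(grads[[k]]), 6L))) {
      up <- params; up[[k]][i] <- up[[k]][i] + eps
      dn <- params; dn[[k]][i] <- dn[[k]][i] - eps
      fd <- (lossFn(up) - lossFn(dn)) / (2 * eps)
      expect_equal(grads[[k]][i], fd, tolerance = 1e-4)
    }
  }
})

test_that("training on separable motion signatures reduces the loss", {
  set12 <- gaussianMotionSet(nPerClass = 6, len = 20, dim = 10)
  cfg <- classifierConfig(tFrames = 15, featureDim = 16,
                          recurrentHidden = 12, headHidden = 8,
                          epochs = 15, batchSize = 4, seed = 7)
  model <- trainMotionClassifier(set12, cfg)
  expect_length(model@lossHistory, 15)
  expect_lt(model@lossHistory[15], model@lossHistory[1])
  preds <- classifyClips(model, set12)
  expect_identical(nrow(preds), 12L)
  expect_true(all(preds$p_final >= 0 & preds$p_final <= 1))
})

test_that("zero training epochs return the seeded initialization", {
  set12 <- gaussianMotionSet()
  cfg <- classifierConfig(tFrames = 15, featureDim = 16,
                          recurrentHidden = 12, headHidden = 8,
                          epochs = 0, seed = 7)
  model <- trainMotionClassifier(set12, cfg)
  expect_length(model@lossHistory, 0)
  set.seed(7)
  init <- toolmotion:::nnInitParams(10L, 16L, 12L, 8L, TRUE)
  expect_equal(model@params, init)
})

test_that("a single-class training set is rejected", {
  s <- gaussianMotionSet(nPerClass = 4)
  s$labels <- rep("scissors", length(s$labels))
  expect_error(trainMotionClassifier(s, classifierConfig(tFrames = 15)),
               "both tool classes")
  expect_error(trainPerFrameBaseline(s, classifierConfig(tFrames = 15)),
               "both tool classes")
})

test_that("trained predictions are causal in the input frames", {
  set12 <- gaussianMotionSet()
  cfg <- classifierConfig(tFrames = 15, featureDim = 16,
                          recurrentHidden = 12, headHidden = 8,
                          epochs = 5, batchSize = 4, seed = 11)
  model <- trainMotionClassifier(set12, cfg)
  d <- set12$descriptors[[1]]
  probsOf <- function(d) {
    ds <- toolmotion:::applyStandardize(d, model@featureCenter,
                                        model@featureScale)
    psi <- sweep(ds %*% model@params$Wp, 2L, model@params$bp, "+")
    predictTimesteps(aggregateSequence(psi, model@params), model@params)
  }
  p1 <- probsOf(d)
  d2 <- d; d2[11:20, ] <- d2[11:20, ] + 5
  p2 <- probsOf(d2)
  expect_equal(p2[1:10], p1[1:10], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(p2[11:20], p1[11:20])))
})

test_that("per-frame features have the contracted shape and determinism", {
  ex <- featureExtractor("flatproj", seed = 5)
  clip <- tinyClip(4)
  psi <- extractFeatures(clip, ex)
  expect_identical(dim(psi), c(4L, 128L))
  expect_identical(psi, extractFeatures(clip, ex))
  # two pixel-identical frames give identical features
  imgs <- list(clip@images[[2]], clip@images[[2]])
  psi2 <- extractFeatures(imgs, ex)
  expect_identical(psi2[1, ], psi2[2, ])
  # flatten + fixed projection equals the matrix-multiply oracle per frame
  d <- clipDescriptors(clip, ex)
  oracle <- d %*% ex$projection$W +
    matrix(ex$projection$b, 4, 128, byrow = TRUE)
  expect_equal(psi, oracle, tolerance = 1e-12)
  # smallcnn satisfies the same contract at its own descriptor size
  ex2 <- featureExtractor("smallcnn", seed = 5)
  expect_identical(dim(extractFeatures(clip, ex2)), c(4L, 128L))
  expect_identical(ncol(clipDescriptors(clip, ex2)), 635L)
})

test_that("an empty test set is rejected by the baseline predictor", {
  set12 <- gaussianMotionSet()
  cfg <- classifierConfig(tFrames = 15, featureDim = 16,
                          recurrentHidden = 12, headHidden = 8,
                          epochs = 1, seed = 3)
  bl <- trainPerFrameBaseline(set12, cfg)
  empty <- set12; empty$descriptors <- list(); empty$labels <- character(0)
  expect_error(predictFrames(bl, empty), "empty")
  expect_error(classifyClips(bl, set12), "baseline")
})
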