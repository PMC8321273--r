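test_that("detection matching classifies TP/FP/FN at the IoU threshold", {
  truth <- matrix(c(0, 0, 10, 10), 1, 4)
  hit <- detections(0, "tool", c(0, 0, 10, 6))   # IoU 0.6
  m <- matchDetections(hit, truth, 0.5)
  expect_identical(unclass(m$counts)[1:3], c(tp = 1L, fp = 0L, fn = 0L))
  miss <- detections(0, "tool", c(0, 0, 10, 4))  # IoU 0.4
  m2 <- matchDetections(miss, truth, 0.5)
  expect_identical(unclass(m2$counts)[1:3], c(tp = 0L, fp = 1L, fn = 1L))
  expect_error(matchDetections(hit, truth, 0), "iouThreshold")
})

test_that("matching agrees with an independent greedy oracle", {
  set.seed(91)
  for (rep in 1:40) {
    nP <- sample(1:6, 1); nT <- sample(1:4, 1)
    pred <- detections(0, "tool",
                       do.call(rbind, lapply(seq_len(nP), function(i)
                         randomIntBox(30, 20))),
                       score = runif(nP))
    truth <- do.call(rbind, lapply(seq_len(nT), function(i)
      randomIntBox(30, 20)))
    m <- matchDetections(pred, truth, 0.5)
    o <- greedyMatchOracle(pred, truth, 0.5)
    expect_identical(unclass(m$counts)[1:3],
                     c(tp = unname(o["tp"]), fp = unname(o["fp"]),
                       fn = unname(o["fn"])))
  }
})

test_that("average precision reproduces hand-built PR curves", {
  truth <- matrix(c(0, 0, 10, 10), 1, 4)
  perfect <- detections(0, "tool", c(0, 0, 10, 10), score = 0.9)
  expect_equal(averagePrecision(perfect, truth), 1)
  # high-score FP then low-score TP: precision at recall 1 is 1/2
  mixed <- detections(0, "tool",
                      rbind(c(50, 50, 60, 60), c(0, 0, 10, 10)),
                      score = c(0.9, 0.4))
  expect_equal(averagePrecision(mixed, truth), 0.5)
  allFp <- detections(0, "tool", rbind(c(50, 50, 60, 60), c(70, 70, 90, 90)),
                      score = c(0.8, 0.6))
  expect_equal(averagePrecision(allFp, truth), 0)
  expect_error(averagePrecision(perfect, matrix(numeric(0), 0, 4)),
               "undefined")
})

test_that("AP is invariant under strictly monotone score transforms", {
  set.seed(101)
  nP <- 12L; nT <- 5L
  pred <- detections(0, "tool",
                     do.call(rbind, lapply(seq_len(nP), function(i)
                       randomIntBox(40, 25))), score = runif(nP))
  truth <- do.call(rbind, lapply(seq_len(nT), function(i)
    randomIntBox(40, 25)))
  ap <- averagePrecision(pred, truth)
  squashed <- pred; squashed$score <- plogis(3 * pred$score - 1)
  expect_equal(averagePrecision(squashed, truth), ap)
})

test_that("accuracy, recall, precision and F have their closed forms", {
  perfect <- prfMetrics(confusionCounts(tp = 1, tn = 1))
  expect_equal(unlist(perfect), c(accuracy = 1, recall = 1, precision = 1,
                                  f_measure = 1))
  m <- prfMetrics(confusionCounts(tp = 3, fp = 1, fn = 2, tn = 4))
  expect_equal(m$accuracy, 7 / 10)
  expect_equal(m$recall, 3 / 5)
  expect_equal(m$precision, 3 / 4)
  expect_equal(m$f_measure, 2 * (3 / 4) * (3 / 5) / (3 / 4 + 3 / 5))
  expect_error(prfMetrics(confusionCounts()), "no evaluated")
})

test_that("the harmonic F reproduces printed two-decimal-input tables", {
  # 25-frame row: P 0.703, R 0.956 -> printed F 0.810
  expect_equal(round(fMeasure(0.703, 0.956), 3), 0.810)
  # 100-frame row: P 0.500, R 0.903 -> printed F 0.644
  expect_equal(round(fMeasure(0.500, 0.903), 3), 0.644)
  # P 0.981, R 0.810 -> harmonic mean 0.8873 (printed as 0.888 from
  # unrounded inputs upstream)
  expect_equal(round(fMeasure(0.981, 0.810), 4), 0.8873)
})

test_that("F lies between min(P,R) and their arithmetic mean", {
  set.seed(111)
  for (i in 1:100) {
    p <- runif(1, 0.01, 1); r <- runif(1, 0.01, 1)
    f <- fMeasure(p, r)
    expect_gte(f + 1e-12, min(p, r))
    expect_lte(f, (p + r) / 2 + 1e-12)
  }
})

test_that("undefined metrics surface as NaN with a warning, never as 0", {
  w <- capture_warnings(m <- prfMetrics(confusionCounts(tn = 5)))
  expect_true(any(grepl("recall", w)))
  expect_true(any(grepl("precision", w)))
  expect_true(is.nan(m$recall))
  expect_true(is.nan(m$precision))
  expect_true(is.nan(m$f_measure))
  expect_equal(m$accuracy, 1)
})

test_that("ROC/AUC handles separation, symmetry and chance", {
  sep <- rocCurveAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(sep$auc, 1)
  rev <- rocCurveAuc(1 - c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(rev$auc, 0)
  set.seed(121)
  scores <- runif(1000); labels <- rbinom(1000, 1, 0.5)
  chance <- rocCurveAuc(scores, labels)
  expect_gt(chance$auc, 0.45); expect_lt(chance$auc, 0.55)
  # reversing scores maps AUC -> 1 - AUC
  expect_equal(rocCurveAuc(-scores, labels)$auc, 1 - chance$auc,
               tolerance = 1e-12)
  expect_error(rocCurveAuc(scores, rep(1, 1000)), "both classes")
})

test_that("AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(131)
  scores <- c(rnorm(60, 0.6, 0.3), rnorm(40, 0.3, 0.3))
  labels <- c(rep(1, 60), rep(0, 40))
  ours <- rocCurveAuc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("selection metrics follow the matched-at-IoU definition", {
  sel <- rbind(c(0, 0, 10, 10),      # exact match -> tp
               c(0, 0, 10, 4),       # IoU 0.4 with truth -> fp
               c(NA, NA, NA, NA),    # truth present, none selected -> fn
               c(NA, NA, NA, NA))    # no truth, none selected -> tn
  tru <- rbind(c(0, 0, 10, 10), c(0, 0, 10, 10), c(0, 0, 10, 10),
               c(NA, NA, NA, NA))
  sm <- selectionMetrics(sel, tru)
  expect_identical(unclass(sm$counts)[1:4],
                   c(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  expect_equal(sm$accuracy, 0.5)
})
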