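# Shared fixtures and independent oracles, all built in code.

# Lattice pixel-counting oracle for box geometry: for integer-corner boxes
# under the half-open convention, a box covers the integer pixels
# x in [x_min, x_max), y in [y_min, y_max). Areas and IoU are computed by
# explicit pixel-set enumeration, independently of the closed-form code.
latticePixels <- function(b) {
  xs <- seq.int(b[1], b[3] - 1L)
  ys <- seq.int(b[2], b[4] - 1L)
  as.vector(outer(xs, ys, function(x, y) x * 100000L + y))
}

latticeIoU <- function(a, b) {
  pa <- latticePixels(a); pb <- latticePixels(b)
  inter <- length(intersect(pa, pb))
  inter / (length(pa) + length(pb) - inter)
}

randomIntBox <- function(maxCoord = 60L, maxSide = 30L) {
  x0 <- sample.int(maxCoord, 1L) - 1L
  y0 <- sample.int(maxCoord, 1L) - 1L
  c(x0, y0, x0 + sample.int(maxSide, 1L), y0 + sample.int(maxSide, 1L))
}

# Constant-valued test frame (width x height x 3).
flatFrame <- function(w = 100L, h = 100L, value = 0.5) {
  array(value, c(w, h, 3L))
}

# A tiny deterministic clip of n constant frames with distinct values.
tinyClip <- function(n = 3L, label = "scissors") {
  imgs <- lapply(seq_len(n), function(i) array(i / (n + 1), c(252L, 252L, 3L)))
  new("ClipWindow", images = imgs, frameIndices = seq_len(n) - 1L,
      label = label)
}

# Separable synthetic feature-sequence set: two "motion signatures" in
# descriptor space (slow vs fast sinusoidal drift), same marginal scale.
gaussianMotionSet <- function(nPerClass = 6L, len = 20L, dim = 10L,
                              seed = 99L) {
  set.seed(seed)
  mk <- function(freq) {
    base <- matrix(rnorm(dim), nrow = 1)
    t(sapply(seq_len(len), function(t)
      base + sin(2 * pi * freq * t / len) * seq_len(dim) / dim +
        rnorm(dim, sd = 0.05)))
  }
  descr <- c(lapply(seq_len(nPerClass), function(i) mk(1)),
             lapply(seq_len(nPerClass), function(i) mk(4)))
  labels <- rep(c("needle_holders", "scissors"), each = nPerClass)
  ex <- list(type = "test", descriptorDim = dim)
  clipFeatureSet(descr, labels, ex)
}

# Independent greedy matcher re-implemented from the matching rule, used to
# cross-check matchDetections on random inputs.
greedyMatchOracle <- function(pred, truth, thr) {
  ord <- order(-pred$score)
  used <- rep(FALSE, nrow(truth))
  tp <- 0L
  for (i in ord) {
    if (!nrow(truth)) break
    best <- -1; bestK <- 0L
    for (k in seq_len(nrow(truth))) {
      if (used[k]) next
      iou <- overlapRatio(as.numeric(pred[i, c("x_min", "y_min", "x_max",
                                               "y_max")]),
                          truth[k, ])
      if (iou > best) { best <- iou; bestK <- k }
    }
    if (bestK > 0L && best >= thr) { used[bestK] <- TRUE; tp <- tp + 1L }
  }
  c(tp = tp, fp = nrow(pred) - tp, fn = nrow(truth) - sum(used))
}
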