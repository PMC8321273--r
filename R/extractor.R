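## Per-frame visual feature extraction. A backend turns one 252x252x3 crop
## into a raw descriptor vector; the 128-d feature psi_t is a linear
## projection of that descriptor. The projection is the learnable stage of
## the extractor and is trained jointly with the LSTM and head; the
## descriptor stage (pooling + fixed oriented convolution bank) is fixed and
## seeded, so features are cacheable and deterministic.

blockMeanMat <- function(n, block) {
  k <- n %/% block
  m <- matrix(0, n, k)
  for (j in seq_len(k)) m[((j - 1L) * block + 1L):(j * block), j] <- 1 / block
  m
}

## Fixed 3x3 filter bank: 4 oriented edges, 1 center-surround, 3 seeded
## random filters (zero-mean, unit-norm).
convBank <- function(seed) {
  ed <- function(m) m / sqrt(sum(m^2))
  bank <- list(
    ed(matrix(c(-1, -1, -1, 0, 0, 0, 1, 1, 1), 3, 3)),            # horiz
    ed(matrix(c(-1, 0, 1, -1, 0, 1, -1, 0, 1), 3, 3)),            # vert
    ed(matrix(c(-1, -1, 0, -1, 0, 1, 0, 1, 1), 3, 3)),            # diag
    ed(matrix(c(0, -1, -1, 1, 0, -1, 1, 1, 0), 3, 3)),            # anti-diag
    ed(matrix(c(-1, -1, -1, -1, 8, -1, -1, -1, -1), 3, 3))        # center
  )
  set.seed(seed)
  for (i in 1:3) {
    w <- matrix(rnorm(9), 3, 3); w <- w - mean(w)
    bank[[5L + i]] <- ed(w)
  }
  bank
}

conv3x3same <- function(M, w) {
  n1 <- nrow(M); n2 <- ncol(M)
  Mp <- matrix(0, n1 + 2L, n2 + 2L)
  Mp[2:(n1 + 1L), 2:(n2 + 1L)] <- M
  out <- matrix(0, n1, n2)
  for (a in 1:3) for (b in 1:3)
    if (w[a, b] != 0)
      out <- out + w[a, b] * Mp[a:(a + n1 - 1L), b:(b + n2 - 1L)]
  out
}

#' Create a per-frame feature extractor
#'
#' Backends (all seeded, all deterministic given their seed):
#' \describe{
#'   \item{`smallcnn`}{4x4 average-pool of the 252x252 crop to 63x63, a
#'     fixed bank of eight oriented/center-surround 3x3 filters with ReLU on
#'     the grayscale plane pooled to a 7x7 spatial grid, plus the three color
#'     planes pooled to a 9x9 grid. Spatial grid pooling (rather than global
#'     pooling) retains the coarse layout of the crop, which is where the
#'     tool's position and orientation — the motion signal — live.
#'     Descriptor length 635.}
#'   \item{`pool`}{color planes pooled to a 9x9 grid only (descriptor 243);
#'     a cheaper purely photometric-spatial backend.}
#'   \item{`flatproj`}{7x7 grid flatten of the three planes (147); intended
#'     for oracle tests of the projection contract.}
#' }
#' Each extractor carries a fixed seeded Glorot projection used when
#' features are requested standalone; during training the model owns (and
#' learns) its projection instead.
#'
#' @param type backend name.
#' @param seed integer seed for the random filters and the fixed projection.
#' @param featureDim projected feature dimension (default 128).
#' @return A `FeatureExtractor` list: `type`, `descriptorDim`, `featureDim`,
#'   `descriptor(img)`, and fixed `projection` (`W`, `b`).
#' @export
featureExtractor <- function(type = c("smallcnn", "pool", "flatproj"),
                             seed = 1L, featureDim = 128L) {
  type <- match.arg(type)
  P4 <- blockMeanMat(252L, 4L)
  P9 <- blockMeanMat(63L, 9L)   # 63 -> 7 grid
  P7 <- blockMeanMat(63L, 7L)   # 63 -> 9 grid
  P36 <- blockMeanMat(252L, 36L) # 252 -> 7 grid (flatproj)
  bank <- if (type == "smallcnn") convBank(seed) else NULL
  descriptor <- switch(type,
    smallcnn = function(img) {
      ds <- vapply(1:3, function(ch) crossprod(P4, img[, , ch]) %*% P4,
                   matrix(0, 63, 63))
      gray <- (ds[, , 1] + ds[, , 2] + ds[, , 3]) / 3
      convPooled <- unlist(lapply(bank, function(w)
        as.vector(crossprod(P9, pmax(conv3x3same(gray, w), 0)) %*% P9)))
      colorPooled <- as.vector(vapply(1:3, function(ch)
        crossprod(P7, ds[, , ch]) %*% P7, matrix(0, 9, 9)))
      c(convPooled, colorPooled)
    },
    pool = function(img) {
      ds <- vapply(1:3, function(ch) crossprod(P4, img[, , ch]) %*% P4,
                   matrix(0, 63, 63))
      as.vector(vapply(1:3, function(ch)
        crossprod(P7, ds[, , ch]) %*% P7, matrix(0, 9, 9)))
    },
    flatproj = function(img) {
      as.vector(vapply(1:3, function(ch)
        crossprod(P36, img[, , ch]) %*% P36, matrix(0, 7, 7)))
    })
  descriptorDim <- switch(type, smallcnn = 8L * 49L + 3L * 81L,
                          pool = 3L * 81L, flatproj = 3L * 49L)
  set.seed(seed + 101L)
  proj <- list(W = glorot(descriptorDim, featureDim), b = numeric(featureDim))
  structure(list(type = type, seed = as.integer(seed),
                 descriptorDim = descriptorDim,
                 featureDim = as.integer(featureDim),
                 descriptor = descriptor, projection = proj),
            class = "FeatureExtractor")
}

#' @export
print.FeatureExtractor <- function(x, ...) {
  cat(sprintf("FeatureExtractor '%s': descriptor %d-d -> features %d-d (seed %d)\n",
              x$type, x$descriptorDim, x$featureDim, x$seed))
  invisible(x)
}

#' Raw descriptors of a clip
#'
#' Applies the extractor's fixed descriptor stage to every image of a clip.
#'
#' @param clip a [ClipWindow-class] or a list of 252x252x3 arrays.
#' @param extractor a [featureExtractor()].
#' @return A `T x descriptorDim` matrix.
#' @export
clipDescriptors <- function(clip, extractor) {
  imgs <- if (is(clip, "ClipWindow")) clip@images else clip
  t(vapply(imgs, extractor$descriptor, numeric(extractor$descriptorDim)))
}

#' Per-frame visual features of a clip
#'
#' The per-frame feature psi_t: the extractor's descriptor projected to
#' `featureDim` dimensions. With `projection = NULL` the extractor's own
#' fixed seeded projection is used, making standalone feature extraction
#' fully deterministic; a trained model supplies its learned projection
#' instead.
#'
#' @param clip a [ClipWindow-class] or list of 252x252x3 arrays.
#' @param extractor a [featureExtractor()].
#' @param projection optional list `(W, b)` overriding the fixed projection.
#' @return A `T x featureDim` matrix of features, one row per frame.
#' @export
extractFeatures <- function(clip, extractor, projection = NULL) {
  if (is.null(projection)) projection <- extractor$projection
  D <- clipDescriptors(clip, extractor)
  if (ncol(D) != nrow(projection$W))
    stop(sprintf("descriptor dimension %d does not match projection input %d",
                 ncol(D), nrow(projection$W)))
  sweep(D %*% projection$W, 2L, projection$b, "+")
}

#' Bundle per-clip descriptors and labels for training
#'
#' The trainer and evaluator consume feature sets rather than raw images so
#' that the fixed descriptor stage is computed once per frame. Descriptor
#' matrices may be longer than the window length T; the trainer then samples
#' a random T-frame fragment per epoch.
#'
#' @param descriptors list of `L_i x D` matrices (one per clip/run).
#' @param labels character vector of tool-class labels, one per clip.
#' @param extractor the [featureExtractor()] that produced the descriptors.
#' @return A `ClipFeatureSet` list.
#' @export
clipFeatureSet <- function(descriptors, labels, extractor) {
  if (length(descriptors) != length(labels))
    stop("one label per descriptor matrix required")
  if (!all(labels %in% TOOL_CLASSES))
    stop("labels must be tool classes")
  D <- unique(vapply(descriptors, ncol, integer(1)))
  if (length(D) != 1L) stop("descriptor dimension differs between clips")
  structure(list(descriptors = descriptors, labels = as.character(labels),
                 descriptorDim = D, extractorType = extractor$type),
            class = "ClipFeatureSet")
}

#' @export
print.ClipFeatureSet <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("ClipFeatureSet: %d clips (%s), descriptor %d-d [%s]\n",
              length(x$labels),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              x$descriptorDim, x$extractorType))
  invisible(x)
}

#' Cut a feature set into fixed-length windows
#'
#' Slices every descriptor matrix into windows of `tFrames` rows at the
#' given stride (clips shorter than `tFrames` are dropped), propagating
#' labels. Used to turn whole selection runs into classifier samples.
#'
#' @param set a [clipFeatureSet()].
#' @param tFrames window length T.
#' @param stride offset between windows (default `tFrames`).
#' @return A new `ClipFeatureSet` of exact-T windows; `$source` maps each
#'   window to its originating clip index.
#' @export
windowFeatureSet <- function(set, tFrames, stride = tFrames) {
  out <- list(); labs <- character(0); src <- integer(0)
  for (i in seq_along(set$descriptors)) {
    L <- nrow(set$descriptors[[i]])
    if (L < tFrames) next
    for (off in seq.int(0L, L - tFrames, by = stride)) {
      out[[length(out) + 1L]] <-
        set$descriptors[[i]][(off + 1L):(off + tFrames), , drop = FALSE]
      labs <- c(labs, set$labels[i])
      src <- c(src, i)
    }
  }
  res <- structure(list(descriptors = out, labels = labs,
                        descriptorDim = set$descriptorDim,
                        extractorType = set$extractorType, source = src),
                   class = "ClipFeatureSet")
  res
}
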