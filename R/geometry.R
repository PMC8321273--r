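## Box convention: 0-based, half-open, continuous real coordinates
## [x_min, x_max) x [y_min, y_max). Images are EBImage-style arrays
## (width, height, channel) with values in [0, 1]; pixel (x, y) in box
## coordinates lives at array index [x + 1, y + 1].

#' Construct and validate a bounding box
#'
#' Boxes are axis-aligned, 0-based, half-open
#' (`[x_min, x_max) x [y_min, y_max)`), with real-valued pixel coordinates.
#' Degenerate (zero width/height) or negative-coordinate boxes are rejected.
#'
#' @param xMin,yMin,xMax,yMax box corners in pixels.
#' @return Named numeric vector `c(x_min, y_min, x_max, y_max)`.
#' @examples
#' makeBox(0, 0, 10, 10)
#' @export
makeBox <- function(xMin, yMin, xMax, yMax) {
  b <- c(x_min = as.numeric(xMin), y_min = as.numeric(yMin),
         x_max = as.numeric(xMax), y_max = as.numeric(yMax))
  if (any(!is.finite(b))) stop("box coordinates must be finite")
  if (any(b < 0)) stop("box coordinates must be >= 0")
  if (b["x_max"] <= b["x_min"] || b["y_max"] <= b["y_min"])
    stop("degenerate box: require x_min < x_max and y_min < y_max")
  b
}

asBoxMatrix <- function(b) {
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  if (ncol(b) != 4) stop("boxes must have 4 coordinates")
  colnames(b) <- c("x_min", "y_min", "x_max", "y_max")
  b
}

#' Box area
#'
#' @param b a box (length-4 vector) or an n x 4 matrix of boxes.
#' @return Area(s) in square pixels. Under the half-open convention this
#'   equals the number of integer lattice pixels covered when corners are
#'   integers.
#' @examples
#' boxArea(makeBox(2, 3, 4, 9)) # 12
#' @export
boxArea <- function(b) {
  b <- asBoxMatrix(b)
  unname((b[, 3] - b[, 1]) * (b[, 4] - b[, 2]))
}

#' Overlap ratio (intersection over union) of two boxes
#'
#' The selection statistic: area of intersection divided by area of union.
#' Symmetric, in `[0, 1]`, 0 for disjoint boxes and 1 exactly when the boxes
#' coincide. Arguments vectorize rowwise (n x 4 matrices, recycled to a
#' common number of rows).
#'
#' @param a,b boxes as length-4 vectors or n x 4 matrices.
#' @return Numeric vector of IoU values.
#' @examples
#' overlapRatio(makeBox(0, 0, 10, 10), makeBox(5, 0, 15, 10)) # 1/3
#' @export
overlapRatio <- function(a, b) {
  a <- asBoxMatrix(a); b <- asBoxMatrix(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L && n > 1L) a <- a[rep(1L, n), , drop = FALSE]
  if (nrow(b) == 1L && n > 1L) b <- b[rep(1L, n), , drop = FALSE]
  iw <- pmax(0, pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1]))
  ih <- pmax(0, pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]))
  inter <- iw * ih
  uni <- boxArea(a) + boxArea(b) - inter
  unname(inter / uni)
}

#' Crop a box region out of a frame
#'
#' Extracts the sub-image covered by `box`, optionally expanded on every side
#' by `pad * max(boxWidth, boxHeight)` pixels, snapped outward to the integer
#' pixel grid and clamped to the frame bounds. A box lying entirely outside
#' the frame signals an inconsistent detection and is an error.
#'
#' @param frame array `(width, height, channel)` with values in `[0,1]`.
#' @param box a length-4 box.
#' @param pad non-negative padding fraction (default 0: crop exactly the
#'   box; the tool tip may lie outside the hand box, so padding is exposed).
#' @return The cropped array, never empty.
#' @examples
#' f <- array(runif(100 * 100 * 3), c(100, 100, 3))
#' dim(cropRegion(f, makeBox(0, 0, 10, 10))) # 10 10 3
#' @export
cropRegion <- function(frame, box, pad = 0) {
  if (length(dim(frame)) != 3L) stop("frame must be a (width,height,channel) array")
  if (pad < 0) stop("pad must be >= 0")
  b <- asBoxMatrix(box)[1L, ]
  W <- dim(frame)[1]; H <- dim(frame)[2]
  m <- pad * max(b[3] - b[1], b[4] - b[2])
  x0 <- b[1] - m; x1 <- b[3] + m
  y0 <- b[2] - m; y1 <- b[4] + m
  if (x0 >= W || y0 >= H || x1 <= 0 || y1 <= 0)
    stop("inconsistent detection: box lies entirely outside the frame")
  xi <- max(1L, floor(x0) + 1L):min(W, ceiling(x1))
  yi <- max(1L, floor(y0) + 1L):min(H, ceiling(y1))
  frame[xi, yi, , drop = FALSE]
}

#' Resize an image to the classifier input size
#'
#' Direct bilinear resize to 252 x 252 (no aspect-ratio preservation, no
#' letterboxing), the fixed input size of the per-frame feature extractor.
#'
#' @param img array `(width, height, channel)`.
#' @param size output side length (default 252).
#' @return A `size x size x channels` array.
#' @export
resizeCrop <- function(img, size = 252L) {
  if (length(dim(img)) != 3L || any(dim(img)[1:2] < 1L))
    stop("img must be a non-empty (width,height,channel) array")
  if (all(dim(img)[1:2] == size)) return(img)
  out <- EBImage::resize(img, w = size, h = size, filter = "bilinear")
  unclass(out)
}

#' Convert between corner boxes and COCO bbox convention
#'
#' COCO annotations store `[x, y, width, height]`; internally boxes are
#' corner-form `[x_min, y_min, x_max, y_max]` (0-based, half-open). The two
#' conversions are exact inverses.
#'
#' @param b corner box(es), length-4 vector or n x 4 matrix.
#' @return For `boxToCoco`, an n x 4 matrix `[x, y, w, h]`; for `cocoToBox`,
#'   an n x 4 corner matrix.
#' @examples
#' boxToCoco(makeBox(2, 3, 10, 8)) # x=2 y=3 w=8 h=5
#' @export
boxToCoco <- function(b) {
  b <- asBoxMatrix(b)
  out <- cbind(x = b[, 1], y = b[, 2],
               w = b[, 3] - b[, 1], h = b[, 4] - b[, 2])
  unname(out)
}

#' @rdname boxToCoco
#' @param xywh COCO-form box(es) `[x, y, w, h]`.
#' @export
cocoToBox <- function(xywh) {
  m <- if (is.null(dim(xywh))) matrix(xywh, nrow = 1) else as.matrix(xywh)
  out <- cbind(x_min = m[, 1], y_min = m[, 2],
               x_max = m[, 1] + m[, 3], y_max = m[, 2] + m[, 4])
  out
}
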