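## Synthetic egocentric scenes. One target hand (textured ellipse sprite)
## operates an elongated tool sprite; distractor hands drift independently
## far from the tool. The two tool classes use IDENTICAL sprites and
## placement statistics — class information exists only in the trajectory:
##   oscillate (scissors): the rigid hand+tool pair translates sinusoidally
##     along a random axis, amplitude ~12 px, period ~12 frames (cutting
##     strokes);
##   rotate (needle holders): the hand sweeps a circle of radius 48 px about
##     the fixed tool tip, period ~40 frames (suturing wrist rotation).
## Both periods fit inside one 50-frame window (2 s at 25 fps).

HAND_HALF_X <- 28; HAND_HALF_Y <- 22
TOOL_REACH <- 48           # hand-center-to-tool-tip distance, both classes
TOOL_HALFWIDTH <- 3.5
OSC_AMPLITUDE <- 12; OSC_PERIOD <- 12
ROT_PERIOD <- 40
HAND_COLOR <- c(0.78, 0.62, 0.55)
TOOL_COLOR <- c(0.22, 0.24, 0.28)

#' Generate the ground-truth trajectories of a synthetic scene
#'
#' Deterministic given `spec@seed`: draws the anchor position, motion phase
#' and axis, distractor placements and the background texture, then rolls
#' the motion program forward for `nFrames` frames. Distractor hands are
#' placed at least 140 px from the tool anchor so their boxes never overlap
#' the tool (selection ground truth is unambiguous); `adversarial = TRUE`
#' drops that guarantee and parks them near the action for stress testing.
#'
#' @param spec a [sceneSpec()].
#' @param adversarial place distractors close to the tool (default FALSE).
#' @return A `SceneTruth` list: `spec`, per-frame `handBox`, `toolBox`
#'   (n x 4 corner matrices), `handCenter`, `toolTip` (n x 2), `toolAngle`
#'   (radians), `distractorBoxes`/`distractorCenters` (lists), and the
#'   low-resolution background texture used by the renderer.
#' @export
makeScene <- function(spec, adversarial = FALSE) {
  stopifnot(is(spec, "SceneSpec"))
  W <- spec@frameWidth; H <- spec@frameHeight
  n <- spec@nFrames
  set.seed(spec@seed)
  margin <- TOOL_REACH + HAND_HALF_X + OSC_AMPLITUDE + 6
  anchor <- c(runif(1, margin, W - margin), runif(1, margin * 0.72, H - margin * 0.72))
  theta0 <- runif(1, 0, 2 * pi)
  t <- seq_len(n) - 1
  if (spec@motionProgram == "oscillate") {
    axis <- runif(1, 0, 2 * pi)
    disp <- OSC_AMPLITUDE * sin(2 * pi * t / OSC_PERIOD)
    center <- cbind(anchor[1] + disp * cos(axis), anchor[2] + disp * sin(axis))
    toolAngle <- rep(theta0, n)
    tip <- center + TOOL_REACH * cbind(cos(toolAngle), sin(toolAngle))
  } else if (spec@motionProgram == "rotate") {
    theta <- theta0 + 2 * pi * t / ROT_PERIOD
    center <- cbind(anchor[1] + TOOL_REACH * cos(theta),
                    anchor[2] + TOOL_REACH * sin(theta))
    tip <- matrix(anchor, n, 2, byrow = TRUE)
    toolAngle <- atan2(tip[, 2] - center[, 2], tip[, 1] - center[, 1])
  } else { # static
    center <- matrix(anchor, n, 2, byrow = TRUE)
    toolAngle <- rep(theta0, n)
    tip <- center + TOOL_REACH * cbind(cos(toolAngle), sin(toolAngle))
  }
  handBox <- cbind(center[, 1] - HAND_HALF_X, center[, 2] - HAND_HALF_Y,
                   center[, 1] + HAND_HALF_X, center[, 2] + HAND_HALF_Y)
  toolBox <- cbind(pmin(center[, 1], tip[, 1]) - TOOL_HALFWIDTH,
                   pmin(center[, 2], tip[, 2]) - TOOL_HALFWIDTH,
                   pmax(center[, 1], tip[, 1]) + TOOL_HALFWIDTH,
                   pmax(center[, 2], tip[, 2]) + TOOL_HALFWIDTH)
  clampBox <- function(b) cbind(pmax(b[, 1], 0), pmax(b[, 2], 0),
                                pmin(b[, 3], W), pmin(b[, 4], H))
  handBox <- clampBox(handBox); toolBox <- clampBox(toolBox)
  colnames(handBox) <- colnames(toolBox) <-
    c("x_min", "y_min", "x_max", "y_max")

  distractorCenters <- list(); distractorBoxes <- list()
  if (spec@nDistractors > 0L) {
    cand <- rbind(c(55, 42), c(W - 55, 42), c(55, H - 42), c(W - 55, H - 42),
                  c(W / 2, 42), c(W / 2, H - 42), c(55, H / 2), c(W - 55, H / 2))
    dists <- sqrt(rowSums(sweep(cand, 2L, anchor)^2))
    bases <- if (adversarial) {
      ang <- runif(spec@nDistractors, 0, 2 * pi)
      cbind(anchor[1] + 85 * cos(ang), anchor[2] + 85 * sin(ang))
    } else {
      ## farthest-first, keeping only bases whose drifting hand box can
      ## never come near the tool (center distance >= 160 px)
      ord <- order(-dists)
      ok <- ord[dists[ord] >= 160]
      cand[ok[seq_len(min(spec@nDistractors, length(ok)))], , drop = FALSE]
    }
    for (k in seq_len(nrow(bases))) {
      amp <- runif(1, 4, 8); per <- runif(1, 15, 35)
      if (spec@motionProgram == "static") amp <- 0  # fully frozen fixture
      ax <- runif(1, 0, 2 * pi); ph <- runif(1, 0, 2 * pi)
      d <- amp * sin(2 * pi * t / per + ph)
      dc <- cbind(bases[k, 1] + d * cos(ax), bases[k, 2] + d * sin(ax))
      dc[, 1] <- pmin(pmax(dc[, 1], HAND_HALF_X), W - HAND_HALF_X)
      dc[, 2] <- pmin(pmax(dc[, 2], HAND_HALF_Y), H - HAND_HALF_Y)
      db <- cbind(dc[, 1] - HAND_HALF_X, dc[, 2] - HAND_HALF_Y,
                  dc[, 1] + HAND_HALF_X, dc[, 2] + HAND_HALF_Y)
      colnames(db) <- c("x_min", "y_min", "x_max", "y_max")
      distractorCenters[[k]] <- dc
      distractorBoxes[[k]] <- db
    }
  }
  ## muted 12x12-px background texture, fixed for the scene; low contrast so
  ## the hand/tool sprites (not the surround) dominate the crop features
  bg <- array(runif(ceiling(W / 12) * ceiling(H / 12) * 3, 0.40, 0.54),
              c(ceiling(W / 12), ceiling(H / 12), 3))
  bg[, , 2] <- bg[, , 2] * 0.93
  bg[, , 3] <- bg[, , 3] * 0.88
  structure(list(spec = spec, frames = t, handCenter = center,
                 handBox = handBox, toolTip = tip, toolBox = toolBox,
                 toolAngle = toolAngle, distractorCenters = distractorCenters,
                 distractorBoxes = distractorBoxes, backgroundSmall = bg),
            class = "SceneTruth")
}

#' @export
print.SceneTruth <- function(x, ...) {
  cat(sprintf("SceneTruth: %d frames, class %s (%s), %d distractor(s)\n",
              x$spec@nFrames, x$spec@toolClass, x$spec@motionProgram,
              length(x$distractorBoxes)))
  invisible(x)
}

## Draw into a window whose [1,1] pixel is global pixel (x0+1, y0+1); the
## window may be the whole frame (x0 = y0 = 0) or a crop region, and the
## rasterization is identical either way.
drawEllipse <- function(frame, cx, cy, a, b, col, x0 = 0L, y0 = 0L) {
  W <- dim(frame)[1]; H <- dim(frame)[2]
  xs <- max(1L, floor(cx - a) - x0):min(W, ceiling(cx + a) - x0)
  ys <- max(1L, floor(cy - b) - y0):min(H, ceiling(cy + b) - y0)
  if (!length(xs) || xs[1] > xs[length(xs)] ||
      !length(ys) || ys[1] > ys[length(ys)]) return(frame)
  mask <- outer(((xs + x0 - 0.5 - cx) / a)^2,
                ((ys + y0 - 0.5 - cy) / b)^2, "+") <= 1
  for (ch in 1:3) {
    sub <- frame[xs, ys, ch]
    sub[mask] <- col[ch]
    frame[xs, ys, ch] <- sub
  }
  frame
}

drawSegment <- function(frame, p0, p1, halfWidth, col, x0 = 0L, y0 = 0L) {
  W <- dim(frame)[1]; H <- dim(frame)[2]
  xs <- max(1L, floor(min(p0[1], p1[1]) - halfWidth) - x0):
    min(W, ceiling(max(p0[1], p1[1]) + halfWidth) - x0)
  ys <- max(1L, floor(min(p0[2], p1[2]) - halfWidth) - y0):
    min(H, ceiling(max(p0[2], p1[2]) + halfWidth) - y0)
  if (!length(xs) || xs[1] > xs[length(xs)] ||
      !length(ys) || ys[1] > ys[length(ys)]) return(frame)
  px <- xs + x0 - 0.5; py <- ys + y0 - 0.5
  v <- p1 - p0
  len2 <- sum(v^2)
  PX <- matrix(px, length(xs), length(ys))
  PY <- matrix(py, length(xs), length(ys), byrow = TRUE)
  tt <- if (len2 == 0) matrix(0, length(xs), length(ys)) else
    pmin(pmax(((PX - p0[1]) * v[1] + (PY - p0[2]) * v[2]) / len2, 0), 1)
  d2 <- (PX - (p0[1] + tt * v[1]))^2 + (PY - (p0[2] + tt * v[2]))^2
  mask <- d2 <= halfWidth^2
  for (ch in 1:3) {
    sub <- frame[xs, ys, ch]
    sub[mask] <- col[ch]
    frame[xs, ys, ch] <- sub
  }
  frame
}

#' In-memory frame renderer for a scene
#'
#' Returns a closure rendering any frame of the scene on demand: the fixed
#' background texture, then distractor hands, the target hand, and the tool
#' on top (the tool is held in front of the hand, so its orientation is
#' visible inside the hand crop). Identical sprites for both tool classes.
#'
#' @param truth a `SceneTruth` from [makeScene()].
#' @return A function `(frameIndex, box = NULL) -> array`, 0-based frame
#'   index. With `box = NULL` the full `width x height x 3` frame is
#'   returned; with a box, only that region is rasterized (snapped outward
#'   to the pixel grid and clamped like [cropRegion()]), pixel-identical to
#'   cropping the full render — the fast path for bulk crop extraction.
#' @export
sceneFrameRenderer <- function(truth) {
  spec <- truth$spec
  W <- spec@frameWidth; H <- spec@frameHeight
  ix <- rep(seq_len(dim(truth$backgroundSmall)[1]), each = 12L)[seq_len(W)]
  iy <- rep(seq_len(dim(truth$backgroundSmall)[2]), each = 12L)[seq_len(H)]
  bgFull <- truth$backgroundSmall[ix, iy, , drop = FALSE]
  function(frameIndex, box = NULL) {
    r <- frameIndex + 1L
    if (r < 1L || r > spec@nFrames) stop("frame index out of range")
    if (is.null(box)) {
      x0 <- 0L; y0 <- 0L
      frame <- bgFull
    } else {
      b <- asBoxMatrix(box)[1L, ]
      if (b[1] >= W || b[2] >= H || b[3] <= 0 || b[4] <= 0)
        stop("box lies entirely outside the frame")
      xi <- max(1L, floor(b[1]) + 1L):min(W, ceiling(b[3]))
      yi <- max(1L, floor(b[2]) + 1L):min(H, ceiling(b[4]))
      x0 <- xi[1] - 1L; y0 <- yi[1] - 1L
      frame <- bgFull[xi, yi, , drop = FALSE]
    }
    for (k in seq_along(truth$distractorCenters))
      frame <- drawEllipse(frame, truth$distractorCenters[[k]][r, 1],
                           truth$distractorCenters[[k]][r, 2],
                           HAND_HALF_X, HAND_HALF_Y, HAND_COLOR, x0, y0)
    frame <- drawEllipse(frame, truth$handCenter[r, 1],
                         truth$handCenter[r, 2],
                         HAND_HALF_X, HAND_HALF_Y, HAND_COLOR, x0, y0)
    frame <- drawSegment(frame, truth$handCenter[r, ], truth$toolTip[r, ],
                         TOOL_HALFWIDTH, TOOL_COLOR, x0, y0)
    frame
  }
}

#' Render a scene to a directory of PNG frames
#'
#' Writes `frame_%06d.png` for every frame (0-based numbering), readable
#' back with [frameReader()].
#'
#' @param truth a `SceneTruth` from [makeScene()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
renderFrames <- function(truth, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop(sprintf("cannot create output directory %s", dir))
  render <- sceneFrameRenderer(truth)
  paths <- vapply(seq_len(truth$spec@nFrames) - 1L, function(i) {
    p <- file.path(dir, sprintf("frame_%06d.png", i))
    EBImage::writeImage(EBImage::Image(render(i), colormode = "Color"), p)
    p
  }, character(1))
  invisible(paths)
}

#' Oracle detector: ground truth corrupted by a noise model
#'
#' Stands in for the phase-1 detector. Each ground-truth box (target hand,
#' distractor hands, tool) has its corners jittered by N(0, sigma^2), is
#' dropped with probability `missRate`, and gets score
#' `clamp(1 - |N(0, scoreNoise^2)|)`; `Poisson(spuriousRate)` random false
#' boxes with low scores are added per frame. With all noise at zero the
#' output equals the ground truth exactly with score 1.
#'
#' @param truth a `SceneTruth`.
#' @param noise a [detectorNoise()] (default: the spec's noise model).
#' @param seed integer seed (default derived from the scene seed).
#' @return A detections data.frame over all frames.
#' @export
oracleDetect <- function(truth, noise = truth$spec@noise,
                         seed = truth$spec@seed + 7919L) {
  spec <- truth$spec
  W <- spec@frameWidth; H <- spec@frameHeight
  n <- spec@nFrames
  set.seed(seed)
  boxSets <- c(list(truth$handBox), truth$distractorBoxes,
               list(truth$toolBox))
  cats <- c("hand", rep("hand", length(truth$distractorBoxes)), "tool")
  rows <- list()
  for (s in seq_along(boxSets)) {
    b <- boxSets[[s]]
    keep <- if (noise@missRate > 0)
      runif(n) >= noise@missRate else rep(TRUE, n)
    if (!any(keep)) next
    bj <- b[keep, , drop = FALSE]
    if (noise@boxJitterSigma > 0) {
      bj <- bj + matrix(rnorm(length(bj), 0, noise@boxJitterSigma),
                        nrow(bj), 4L)
      bj[, 1] <- pmin(pmax(bj[, 1], 0), W - 2)
      bj[, 2] <- pmin(pmax(bj[, 2], 0), H - 2)
      bj[, 3] <- pmin(pmax(bj[, 3], bj[, 1] + 2), W)
      bj[, 4] <- pmin(pmax(bj[, 4], bj[, 2] + 2), H)
    }
    score <- if (noise@scoreNoiseSigma > 0)
      pmin(pmax(1 - abs(rnorm(sum(keep), 0, noise@scoreNoiseSigma)), 0), 1)
    else rep(1, sum(keep))
    rows[[length(rows) + 1L]] <-
      detections((which(keep) - 1L), cats[s], bj, score)
  }
  if (noise@spuriousRate > 0) {
    nSpur <- rpois(n, noise@spuriousRate)
    for (fi in which(nSpur > 0)) {
      for (k in seq_len(nSpur[fi])) {
        w <- runif(1, 20, 80); h <- runif(1, 20, 80)
        x0 <- runif(1, 0, W - w); y0 <- runif(1, 0, H - h)
        rows[[length(rows) + 1L]] <-
          detections(fi - 1L, sample(DETECTION_CATEGORIES, 1L),
                     c(x0, y0, x0 + w, y0 + h), runif(1, 0.05, 0.3))
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(detections(integer(0), character(0), matrix(numeric(0), 0, 4),
                      numeric(0)))
  out <- out[order(out$frame_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write scene ground truth as COCO detection JSON
#'
#' Standard COCO layout: `images` (one per frame, `frame_%06d.png`),
#' `categories` (`hand` = 1, `tool` = 2) and `annotations` with
#' `[x, y, w, h]` boxes, `area` and `iscrowd`. Hand annotations carry an
#' extra boolean `target` marking the operating hand (COCO readers ignore
#' unknown keys). A clip-label manifest line for the scene can be appended
#' to a JSON-lines file with [appendClipManifest()].
#'
#' @param truth a `SceneTruth`.
#' @param file output JSON path.
#' @param video video/scene identifier stored in the image entries.
#' @return Invisibly, `file`.
#' @export
writeCocoAnnotations <- function(truth, file, video = "scene") {
  spec <- truth$spec
  n <- spec@nFrames
  images <- data.frame(
    id = seq_len(n),
    file_name = sprintf("frame_%06d.png", seq_len(n) - 1L),
    width = spec@frameWidth, height = spec@frameHeight,
    video = video)
  annBoxes <- list(); annCat <- list(); annImg <- list(); annTarget <- list()
  addSet <- function(boxes, catId, target) {
    annBoxes[[length(annBoxes) + 1L]] <<- boxToCoco(boxes)
    annCat[[length(annCat) + 1L]] <<- rep(catId, nrow(boxes))
    annImg[[length(annImg) + 1L]] <<- seq_len(n)
    annTarget[[length(annTarget) + 1L]] <<- rep(target, nrow(boxes))
  }
  addSet(truth$handBox, 1L, TRUE)
  for (db in truth$distractorBoxes) addSet(db, 1L, FALSE)
  addSet(truth$toolBox, 2L, FALSE)
  bb <- do.call(rbind, annBoxes)
  ann <- lapply(seq_len(nrow(bb)), function(i) {
    list(id = i, image_id = unlist(annImg)[i],
         category_id = unlist(annCat)[i],
         bbox = as.numeric(bb[i, ]),
         area = as.numeric(bb[i, 3] * bb[i, 4]),
         iscrowd = 0L, target = unlist(annTarget)[i])
  })
  doc <- list(
    images = lapply(seq_len(n), function(i) as.list(images[i, ])),
    annotations = ann,
    categories = list(list(id = 1L, name = "hand"),
                      list(id = 2L, name = "tool")))
  jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = 10)
  invisible(file)
}

#' Read COCO annotations written by [writeCocoAnnotations()]
#'
#' @param file JSON path.
#' @return List of data.frames: `images`, `annotations` (with corner-form
#'   box columns appended), `categories`.
#' @export
readCocoAnnotations <- function(file) {
  doc <- jsonlite::fromJSON(file, simplifyDataFrame = TRUE)
  ann <- doc$annotations
  bb <- do.call(rbind, ann$bbox)
  corners <- cocoToBox(bb)
  ann$bbox <- NULL
  ann <- cbind(ann, as.data.frame(corners),
               data.frame(w = bb[, 3], h = bb[, 4]))
  list(images = doc$images, annotations = ann, categories = doc$categories)
}

#' Append a clip-label manifest line
#'
#' JSON-lines manifest of clip labels: one object per clip with the video
#' id, tool class, start frame, window length and crop source.
#'
#' @param file manifest path (appended to).
#' @param video video/scene id.
#' @param label tool class.
#' @param startFrame first frame index of the clip.
#' @param tFrames window length.
#' @return Invisibly, `file`.
#' @export
appendClipManifest <- function(file, video, label, startFrame, tFrames) {
  line <- jsonlite::toJSON(list(video = video, label = label,
                                start_frame = startFrame, t = tFrames),
                           auto_unbox = TRUE)
  cat(line, "\n", file = file, append = TRUE, sep = "")
  invisible(file)
}

#' Write detections as COCO-results-style JSON
#'
#' @param dets detections data.frame.
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
writeDetectionsJson <- function(dets, file) {
  bb <- boxToCoco(detBoxes(dets))
  res <- lapply(seq_len(nrow(dets)), function(i)
    list(image_id = dets$frame_index[i] + 1L,
         category_id = if (dets$category[i] == "hand") 1L else 2L,
         bbox = as.numeric(bb[i, ]), score = dets$score[i]))
  jsonlite::write_json(res, file, auto_unbox = TRUE, digits = 10)
  invisible(file)
}

#' Read detections from COCO-results-style JSON
#'
#' @param file path written by [writeDetectionsJson()] (or an external
#'   detector emitting the same exchange format).
#' @return A detections data.frame.
#' @export
readDetectionsJson <- function(file) {
  res <- jsonlite::fromJSON(file, simplifyDataFrame = TRUE)
  bb <- do.call(rbind, res$bbox)
  corners <- cocoToBox(bb)
  detections(res$image_id - 1L,
             ifelse(res$category_id == 1L, "hand", "tool"),
             corners, res$score)
}
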