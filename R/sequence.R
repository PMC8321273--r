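## A target track is a data.frame (frame_index, x_min, y_min, x_max, y_max)
## of the frames where a tool's operating hand was selected (ratio > 0),
## with strictly increasing frame_index.

#' Window length for a clip duration
#'
#' Number of frames spanning a duration at a frame rate; the default window
#' of 50 frames corresponds to 2 s at 25 fps, the time within which basic
#' surgical gestures (a cutting stroke, a suturing wrist rotation) complete.
#'
#' @param seconds clip duration in seconds.
#' @param fps frames per second (default 25).
#' @return Integer number of frames.
#' @examples
#' framesForDuration(2)        # 50
#' framesForDuration(1, 25)    # 25
#' @export
framesForDuration <- function(seconds, fps = 25) {
  if (seconds <= 0 || fps <= 0) stop("seconds and fps must be positive")
  as.integer(round(seconds * fps))
}

#' Maximal consecutive-frame runs of a track
#'
#' Partitions a target track into maximal runs where successive frame
#' indices differ by exactly one (strict consecutiveness; `maxGap` relaxes
#' this to tolerate gaps up to the given size, default 0).
#'
#' @param track target-track data.frame with a `frame_index` column, sorted
#'   strictly increasing.
#' @param maxGap largest tolerated gap between successive frames (default 0:
#'   only gap-free runs).
#' @return A data.frame with one row per run: `start_row`, `end_row` (row
#'   positions within the track), `start_frame`, `end_frame`, `length`
#'   (number of track entries in the run).
#' @examples
#' tr <- data.frame(frame_index = c(0:4, 7:9))
#' findRuns(tr) # two runs: lengths 5 and 3
#' @export
findRuns <- function(track, maxGap = 0L) {
  n <- nrow(track)
  if (n == 0L)
    return(data.frame(start_row = integer(0), end_row = integer(0),
                      start_frame = integer(0), end_frame = integer(0),
                      length = integer(0)))
  f <- track$frame_index
  if (n > 1L && any(diff(f) <= 0))
    stop("track frame_index must be strictly increasing")
  brk <- which(diff(f) > 1L + maxGap)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, n)
  data.frame(start_row = starts, end_row = ends,
             start_frame = f[starts], end_frame = f[ends],
             length = ends - starts + 1L)
}

#' Enumerate fixed-length window spans within runs
#'
#' For each run of length `L >= tFrames`, emits spans starting at offsets
#' 0, `stride`, `2 * stride`, ... while a full window fits; runs shorter
#' than `tFrames` emit nothing. The emitted count over all runs equals
#' `sum(max(0, floor((L - T) / stride) + 1))`.
#'
#' @param runs run table from [findRuns()].
#' @param tFrames window length T.
#' @param stride offset increment; defaults to `tFrames` (non-overlapping
#'   windows at inference time).
#' @return A data.frame of spans: `start_row`, `end_row` (track row range),
#'   `start_frame`, `run` (row index into `runs`).
#' @export
emitWindows <- function(runs, tFrames, stride = tFrames) {
  tFrames <- as.integer(tFrames); stride <- as.integer(stride)
  if (tFrames < 1L || stride < 1L) stop("tFrames and stride must be >= 1")
  spans <- lapply(seq_len(nrow(runs)), function(i) {
    L <- runs$length[i]
    if (L < tFrames) return(NULL)
    offs <- seq.int(0L, L - tFrames, by = stride)
    data.frame(start_row = runs$start_row[i] + offs,
               end_row = runs$start_row[i] + offs + tFrames - 1L,
               start_frame = runs$start_frame[i] + offs,
               run = i)
  })
  out <- do.call(rbind, spans)
  if (is.null(out))
    out <- data.frame(start_row = integer(0), end_row = integer(0),
                      start_frame = integer(0), run = integer(0))
  out
}

#' Sample random fragment offsets within runs
#'
#' Training draws one random T-frame fragment per run per epoch, uniform
#' over the valid offsets. Used by the trainer; exposed for testing the
#' uniformity of the draw.
#'
#' @param runs run table from [findRuns()].
#' @param tFrames window length T.
#' @return Integer vector, one 0-based offset per run of length >= T
#'   (shorter runs are skipped); named by the run row index.
#' @export
sampleFragmentOffsets <- function(runs, tFrames) {
  ok <- which(runs$length >= tFrames)
  offs <- vapply(ok, function(i) {
    hi <- runs$length[i] - tFrames
    if (hi == 0L) 0L else sample.int(hi + 1L, 1L) - 1L
  }, integer(1))
  setNames(offs, ok)
}

#' Build a clip window from video frames and a track span
#'
#' Crops the selected hand box out of each frame of the span (via
#' [cropRegion()] then [resizeCrop()]) and assembles the T crops into a
#' [ClipWindow-class].
#'
#' @param frames a function `frames(frameIndex)` returning the frame array
#'   for a 0-based index, or a list of frame arrays indexed by
#'   `frame_index + 1`. For frame directories see [frameReader()].
#' @param track target-track data.frame (frame_index + box columns).
#' @param span one row of [emitWindows()] output (`start_row`, `end_row`).
#' @param label clip label (default `"unknown"`).
#' @param pad crop padding fraction (default 0).
#' @return A [ClipWindow-class] of `end_row - start_row + 1` images.
#' @export
buildClip <- function(frames, track, span, label = "unknown", pad = 0) {
  rows <- span$start_row[1]:span$end_row[1]
  if (any(rows < 1L) || any(rows > nrow(track)))
    stop("span lies outside the track")
  getFrame <- if (is.function(frames)) frames else function(i) {
    f <- frames[[i + 1L]]
    if (is.null(f)) stop(sprintf("missing frame %d", i))
    f
  }
  imgs <- lapply(rows, function(r) {
    fi <- track$frame_index[r]
    box <- c(track$x_min[r], track$y_min[r], track$x_max[r], track$y_max[r])
    resizeCrop(cropRegion(getFrame(fi), box, pad = pad))
  })
  new("ClipWindow", images = imgs,
      frameIndices = as.integer(track$frame_index[rows]), label = label)
}

#' Reader over a directory of numbered frame images
#'
#' Returns a closure mapping a 0-based frame index to the image array of
#' `frame_%06d.png` in `dir`, the layout written by [renderFrames()]. A
#' missing file is an I/O error naming the frame.
#'
#' @param dir directory containing `frame_000000.png`, ...
#' @return A function `(frameIndex) -> array(width, height, 3)`.
#' @export
frameReader <- function(dir) {
  force(dir)
  function(frameIndex) {
    path <- file.path(dir, sprintf("frame_%06d.png", frameIndex))
    if (!file.exists(path))
      stop(sprintf("missing frame file: %s", path))
    img <- EBImage::readImage(path)
    a <- unclass(img)
    if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
    a[, , 1:3, drop = FALSE]
  }
}
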