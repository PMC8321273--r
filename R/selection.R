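## Detections travel as data.frames with columns
## frame_index, category ("hand"/"tool"), score, x_min, y_min, x_max, y_max.

#' Build a detections data.frame
#'
#' @param frameIndex integer frame index (0-based), recycled.
#' @param category `"hand"` or `"tool"` per row. The tool category is not a
#'   tool *class*; classes are assigned later by the motion classifier.
#' @param boxes n x 4 corner matrix (or length-4 vector).
#' @param score detection confidence in `[0,1]`, recycled.
#' @return A detections data.frame.
#' @export
detections <- function(frameIndex, category, boxes, score = 1) {
  boxes <- asBoxMatrix(boxes)
  n <- nrow(boxes)
  if (!all(category %in% DETECTION_CATEGORIES))
    stop("category must be 'hand' or 'tool'")
  if (any(score < 0 | score > 1)) stop("score must lie in [0,1]")
  if (any(frameIndex < 0)) stop("frame_index must be >= 0")
  data.frame(frame_index = as.integer(rep_len(frameIndex, n)),
             category = rep_len(category, n),
             score = rep_len(as.numeric(score), n),
             x_min = boxes[, 1], y_min = boxes[, 2],
             x_max = boxes[, 3], y_max = boxes[, 4])
}

detBoxes <- function(d) as.matrix(d[, c("x_min", "y_min", "x_max", "y_max")])

#' Select the hand operating a tool
#'
#' For one tool box, computes the overlap ratio against every candidate hand
#' box and selects the hand with the maximum ratio. When no hand overlaps
#' the tool at all (maximum ratio 0), no hand is selected: a non-overlapping
#' hand cannot be operating the tool, and the argmax over an all-zero ratio
#' set is not meaningful. Exact ratio ties are broken by higher detection
#' score, then by lower position in the hand list.
#'
#' @param hands detections data.frame of category `"hand"` (may be empty).
#' @param tool a single-row detections data.frame of category `"tool"`.
#' @return A one-row data.frame: `frame_index`, `selected_hand_index`
#'   (1-based index into `hands`, `NA` if none), `ratio`.
#' @examples
#' h <- detections(0, "hand", rbind(c(0,0,10,10), c(50,50,60,60)))
#' t <- detections(0, "tool", c(8,0,18,10))
#' selectTargetHand(h, t)
#' @export
selectTargetHand <- function(hands, tool) {
  if (nrow(tool) != 1L || tool$category != "tool")
    stop("tool must be a single detection of category 'tool'")
  if (nrow(hands) && any(hands$category != "hand"))
    stop("hands must all have category 'hand'")
  if (nrow(hands) && any(hands$frame_index != tool$frame_index))
    stop("hands and tool must share a frame_index")
  if (nrow(hands) == 0L)
    return(data.frame(frame_index = tool$frame_index,
                      selected_hand_index = NA_integer_, ratio = 0))
  r <- overlapRatio(detBoxes(hands), detBoxes(tool))
  best <- max(r)
  if (best == 0)
    return(data.frame(frame_index = tool$frame_index,
                      selected_hand_index = NA_integer_, ratio = 0))
  cand <- which(r == best)
  if (length(cand) > 1L)
    cand <- cand[order(-hands$score[cand], cand)]
  data.frame(frame_index = tool$frame_index,
             selected_hand_index = cand[1L], ratio = best)
}

#' Select a target hand for every tool in a frame
#'
#' Each tool is treated independently: one hand may be the target of more
#' than one tool. A frame without tools yields an empty result.
#'
#' @param frameDets detections data.frame for one frame (hands and tools).
#' @return A data.frame with one row per tool: `frame_index`, `tool_index`
#'   (1-based among the frame's tools), `selected_hand_index` (1-based among
#'   the frame's hands, `NA` if no hand overlaps), `ratio`.
#' @export
selectAllTargets <- function(frameDets) {
  if (nrow(frameDets) && length(unique(frameDets$frame_index)) > 1L)
    stop("frameDets must contain a single frame")
  hands <- frameDets[frameDets$category == "hand", , drop = FALSE]
  tools <- frameDets[frameDets$category == "tool", , drop = FALSE]
  if (nrow(tools) == 0L)
    return(data.frame(frame_index = integer(0), tool_index = integer(0),
                      selected_hand_index = integer(0), ratio = numeric(0)))
  out <- lapply(seq_len(nrow(tools)), function(k) {
    sel <- selectTargetHand(hands, tools[k, , drop = FALSE])
    cbind(frame_index = sel$frame_index, tool_index = k,
          sel[, c("selected_hand_index", "ratio"), drop = FALSE])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
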