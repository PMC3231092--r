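#' Normalized cross-correlation of two patches
#'
#' Pearson correlation of the pixel sets (means subtracted, scaled by the
#' two standard deviations); always in \[-1, 1\].
#'
#' @param template,candidate numeric matrices of identical shape with at
#'   least 2 pixels.
#' @return A scalar in \[-1, 1\].
#' @export
ncc <- function(template, candidate) {
  if (!all(dim(template) == dim(candidate)))
    abort("`template` and `candidate` must have identical shapes")
  if (length(template) < 2) abort("patches need at least 2 pixels")
  a <- as.vector(template); b <- as.vector(candidate)
  if (sd(a) == 0 || sd(b) == 0)
    abort("degenerate (constant) patch: NCC undefined")
  cor(a, b)
}

#' Initialize artery-movement tracking
#'
#' Fixes the first-frame ROI sub-image as the reference template `T0`; all
#' later frames are registered against it (never frame-to-frame).
#'
#' @param frame first frame (matrix).
#' @param roi a [roi_spec()] locating the template in the frame.
#' @param delta_s vertical search half-range, pixels (default 10, about
#'   1 mm at 0.106 mm/pixel).
#' @return A `cawall_track` state: the template, its origin, the
#'   cumulative vertical shift (0), and an empty NCC trace.
#' @export
track_init <- function(frame, roi, delta_s = 10) {
  template <- crop_roi(frame, roi)
  if (sd(template) == 0) abort("constant template: tracking is undefined")
  structure(list(template = template, roi = roi, shift = 0L,
                 delta_s = as.integer(delta_s),
                 ncc_trace = numeric(0), frame_index = 1L),
            class = "cawall_track")
}

#' Track the vertical artery shift into a new frame
#'
#' Evaluates the NCC of the reference template against the frame patch at
#' every integer vertical offset `s` in `[-delta_s, delta_s]` relative to
#' the previous frame's position and accumulates the best one
#' (`shift <- shift + argmax s`).  Ties prefer the smallest `|s|`, then
#' the negative `s`.  Candidate patches with zero variance score `-Inf`.
#'
#' @param state a `cawall_track` from [track_init()] or a previous call.
#' @param frame next frame (matrix, same size as the first).
#' @return The updated state (`shift`, `ncc_trace`, `frame_index`).
#' @export
track_frame <- function(state, frame) {
  roi <- state$roi
  idx <- state$frame_index + 1L
  y_base <- roi$y0 + state$shift
  svals <- seq(-state$delta_s, state$delta_s)
  svals <- svals[order(abs(svals), svals)]   # tie-break preference order
  lo <- y_base - state$delta_s
  hi <- y_base + state$delta_s + roi$height - 1L
  if (lo < 1L || hi > nrow(frame))
    abort(sprintf(
      "frame %d: tracking search window rows [%d, %d] leave the frame (1..%d)",
      idx, lo, hi, nrow(frame)))
  best <- -Inf; best_s <- 0L
  xs <- roi$x0 + seq_len(roi$width) - 1L
  for (s in svals) {
    ys <- y_base + s + seq_len(roi$height) - 1L
    patch <- frame[ys, xs, drop = FALSE]
    v <- if (sd(patch) == 0) -Inf else cor(as.vector(state$template), as.vector(patch))
    if (v > best) { best <- v; best_s <- s }
  }
  if (!is.finite(best))
    abort(sprintf("frame %d: all tracking candidates degenerate", idx))
  state$shift <- state$shift + as.integer(best_s)
  state$ncc_trace <- c(state$ncc_trace, best)
  state$frame_index <- idx
  state
}

#' @export
print.cawall_track <- function(x, ...) {
  cat(sprintf("<cawall_track> frame %d, cumulative shift %d px, last NCC %s\n",
              x$frame_index, x$shift,
              if (length(x$ncc_trace)) sprintf("%.4f", tail(x$ncc_trace, 1)) else "-"))
  invisible(x)
}
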