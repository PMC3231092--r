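#' Directional and wall-specific filter kernels
#'
#' Constructors for the small convolution kernels the detector is built
#' from: the oriented MacLeod edge operator, the 7 x 7 intima-media
#' enhancement kernels for the far and near walls, a reconstructed
#' lumen-diameter enhancement kernel, and the 9 x 1 outer-wall step kernel.
#'
#' Kernels are plain numeric matrices of class `cawall_kernel` with a
#' `label` attribute; the anchor is always the central cell.  They are
#' applied in correlation orientation (no flip) unless a caller requests
#' otherwise.
#'
#' @name kernels
NULL

new_kernel <- function(weights, label) {
  stopifnot(is.matrix(weights), nrow(weights) %% 2 == 1, ncol(weights) %% 2 == 1)
  structure(weights, label = label, class = c("cawall_kernel", "matrix", "array"))
}

#' @describeIn kernels Oriented MacLeod edge kernel.  Weights at integer
#'   offsets `(x, y)` from the anchor (x rightward, y downward) are
#'   `exp(-(x^2 + y^2) / d_c^2) * (exp(-((d_xy + d_pk) / d_pk)^2) -`
#'   `exp(-((d_xy - d_pk) / d_pk)^2))` with `d_xy = x * sin(theta) - y *
#'   cos(theta)`, the perpendicular distance of the point from an edge axis
#'   at orientation `theta` to the horizontal.  The kernel sums to zero, so
#'   a constant image gives an all-zero response.
#' @param size odd kernel side length in pixels (>= 3).
#' @param d_c radial decay constant, pixels.
#' @param d_pk distance from the edge axis to the positive/negative weight
#'   peaks, pixels.
#' @param theta edge orientation in radians; the detector uses
#'   `0, pi/4, pi/2, 3*pi/4`.
#' @return A `cawall_kernel` matrix.
#' @export
#' @examples
#' k <- build_macleod(7, 2, 2, 0)
#' abs(sum(k)) < 1e-10
build_macleod <- function(size = 7, d_c = 2, d_pk = 2, theta = 0) {
  if (size %% 2 == 0 || size < 3) abort("`size` must be odd and >= 3")
  if (d_c <= 0 || d_pk <= 0) abort("`d_c` and `d_pk` must be positive")
  h <- (size - 1) / 2
  off <- seq(-h, h)
  x <- matrix(off, size, size, byrow = TRUE)  # column offset, rightward
  y <- matrix(off, size, size)                # row offset, downward
  dxy <- x * sin(theta) - y * cos(theta)
  w <- exp(-(x^2 + y^2) / d_c^2) *
    (exp(-((dxy + d_pk) / d_pk)^2) - exp(-((dxy - d_pk) / d_pk)^2))
  new_kernel(w, sprintf("macleod(theta=%.4g)", theta))
}

#' @describeIn kernels 7 x 7 intima-media enhancement kernel.  The far-wall
#'   kernel stacks three `-1` entries above the anchor row and three `+1`
#'   entries below it (offset one column apart); in correlation orientation
#'   it responds positively at dark-above/bright-below interfaces, the
#'   leading edges of the far-wall echo bands.  The near-wall kernel is its
#'   180-degree rotation and responds at bright-above/dark-below
#'   interfaces.  Both sum to zero.
#' @param wall `"far"` or `"near"`.
#' @export
build_imt_kernel <- function(wall = c("far", "near")) {
  wall <- match.arg(wall)
  far <- matrix(0, 7, 7)
  far[1:3, 4] <- -1
  far[5:7, 5] <- 1
  w <- if (wall == "far") far else rot180(far)
  new_kernel(w, paste0("imt_", wall))
}

#' @describeIn kernels Reconstructed 7 x 7 lumen-diameter enhancement
#'   kernel: a widened antisymmetric dark-to-bright transition detector
#'   analogous to the intima-media kernels (three columns wide, so it
#'   favours laterally coherent lumen-intima edges).  This is a
#'   reconstruction in the spirit of the wall kernels, not a published
#'   matrix; the near variant is the 180-degree rotation.
#' @export
build_ld_kernel <- function(wall = c("far", "near")) {
  wall <- match.arg(wall)
  far <- matrix(0, 7, 7)
  far[1:3, 3:5] <- -1 / 3
  far[5:7, 3:5] <- 1 / 3
  w <- if (wall == "far") far else rot180(far)
  new_kernel(w, paste0("ld_", wall))
}

#' @describeIn kernels The 9 x 1 outer-wall step kernel
#'   `(-1,-1,-1,-1,0,1,1,1,1)` (a column vector): in correlation
#'   orientation it responds positively at dark-above/bright-below steps
#'   such as the tissue-adventitia transition of the near wall.
#' @export
build_outer_kernel <- function() {
  new_kernel(matrix(c(-1, -1, -1, -1, 0, 1, 1, 1, 1), ncol = 1), "outer_wall_f1")
}

#' Rotate a kernel or matrix by 180 degrees
#'
#' @param m a matrix.
#' @return The point-reflected matrix (attributes of plain matrices kept).
#' @export
rot180 <- function(m) {
  m[nrow(m):1, ncol(m):1, drop = FALSE]
}

#' Write a kernel as a plain-text matrix
#'
#' @param kernel a `cawall_kernel`.
#' @param path output file; tab-separated values, one row per line.
#' @return `path`, invisibly.
#' @export
write_kernel <- function(kernel, path) {
  utils::write.table(unclass(kernel), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.cawall_kernel <- function(x, ...) {
  cat("<cawall_kernel>", attr(x, "label"), sprintf("%d x %d\n", nrow(x), ncol(x)))
  print(round(unclass(x), 4))
  invisible(x)
}
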