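#' Min-max normalize a matrix to [0, 1]
#'
#' Degenerate (constant) inputs return the constant 0.5 map so downstream
#' optimizers always receive a valid, neutral cost surface.
#'
#' @param m numeric matrix.
#' @return Matrix of the same shape with values in \[0, 1\].
#' @export
normalize01 <- function(m) {
  rng <- range(m)
  if (!all(is.finite(rng))) abort("non-finite values in feature map")
  if (rng[1] == rng[2]) {
    m[] <- 0.5
    return(m)
  }
  (m - rng[1]) / (rng[2] - rng[1])
}

new_feature_map <- function(values, provenance) {
  structure(values, provenance = provenance,
            class = c("cawall_feature", "matrix", "array"))
}

#' Apply a kernel to an image with replicate border padding
#'
#' Correlation orientation by default (no kernel flip); set `flip = TRUE`
#' for true convolution.
#'
#' @param img numeric matrix.
#' @param kernel numeric matrix with odd dimensions.
#' @param flip rotate the kernel 180 degrees first (convolution).
#' @return Response matrix, same shape as `img`.
#' @export
apply_kernel <- function(img, kernel, flip = FALSE) {
  k <- unclass(kernel)
  if (flip) k <- rot180(k)
  xcorr2_replicate(img, k)
}

#' Directional boundary feature image F
#'
#' Combines the magnitude responses of the MacLeod kernel bank over the
#' four orientations `0, pi/4, pi/2, 3*pi/4` with the signed response of a
#' wall-specific enhancement kernel `f_x`:
#' `F = combine_theta |I (*) f_M(theta)| + I (*) f_x`, then min-max
#' normalized to \[0, 1\].  High values mark boundary evidence.
#'
#' @param roi_image numeric matrix with values in \[0, 1\].
#' @param f_x enhancement kernel (matrix), or `NULL` to use only the
#'   MacLeod magnitude term.  A sign flip of the kernel selects the
#'   opposite interface polarity.
#' @param orientations MacLeod orientations in radians.
#' @param macleod_size,d_c,d_pk MacLeod kernel geometry (pixels).
#' @param combine how to pool the per-orientation magnitudes: `"sum"`
#'   (default; uses all four angles) or `"max"`.
#' @param flip_kernels apply kernels in convolution rather than correlation
#'   orientation.
#' @param normalize min-max normalize the result (`TRUE` for pipeline use;
#'   `FALSE` exposes the raw response).
#' @return A `cawall_feature` matrix the same shape as `roi_image`.
#' @export
compute_feature_F <- function(roi_image, f_x = NULL,
                              orientations = c(0, pi / 4, pi / 2, 3 * pi / 4),
                              macleod_size = 7, d_c = 2, d_pk = 2,
                              combine = c("sum", "max"),
                              flip_kernels = FALSE, normalize = TRUE) {
  combine <- match.arg(combine)
  if (min(roi_image) < 0 || max(roi_image) > 1)
    abort("`roi_image` must be normalized to [0, 1]")
  if (macleod_size > min(dim(roi_image)))
    abort("MacLeod kernel larger than the ROI")
  mags <- lapply(orientations, function(th) {
    abs(apply_kernel(roi_image, build_macleod(macleod_size, d_c, d_pk, th),
                     flip = flip_kernels))
  })
  f <- if (combine == "sum") Reduce(`+`, mags) else Reduce(pmax, mags)
  if (!is.null(f_x)) {
    if (min(dim(f_x)) > min(dim(roi_image)) || max(dim(f_x)) > max(dim(roi_image)))
      abort("enhancement kernel larger than the ROI")
    f <- f + apply_kernel(roi_image, f_x, flip = flip_kernels)
  }
  if (normalize) f <- normalize01(f)
  new_feature_map(f, "F")
}

#' Sub-band brightness feature H
#'
#' `H(y, x) = 1 - mean(I[(y + 1):(y + r), x])` for rows strictly between
#' the outer-wall line and `M - r`; all other rows keep the neutral value
#' 1.  Low values mark rows with bright tissue directly beneath them,
#' which is the signature of the near-wall interfaces (the bright intima
#' band lies under the adventitia-media interface, and in systolic frames
#' the sub-intima echo layer lies under the intima-lumen interface).
#'
#' @param roi_image numeric matrix `M x N` in \[0, 1\].
#' @param y_outer outer-wall row per column (length `N`), or a single row
#'   recycled; rows at or above it are excluded from the band.
#' @param r averaging depth below each row, pixels (`1 <= r < M`).
#' @return A `cawall_feature` matrix, same shape as `roi_image`.
#' @export
compute_feature_H <- function(roi_image, y_outer, r = 5) {
  M <- nrow(roi_image); N <- ncol(roi_image)
  if (r < 1 || r >= M) abort("`r` must satisfy 1 <= r < M")
  if (length(y_outer) == 1) y_outer <- rep(y_outer, N)
  if (length(y_outer) != N) abort("`y_outer` must have one row per column")
  if (any(y_outer < 0 | y_outer > M)) abort("`y_outer` outside the ROI")
  H <- matrix(1, M, N)
  # windowed column means via cumulative sums
  cs <- rbind(0, apply(roi_image, 2, cumsum))
  for (x in seq_len(N)) {
    ys <- seq_len(M)
    valid <- ys > y_outer[x] & ys < M - r
    if (!any(valid)) next
    yv <- ys[valid]
    H[yv, x] <- 1 - (cs[yv + r + 1, x] - cs[yv + 1, x]) / r
  }
  new_feature_map(H, "H")
}

#' Combined near-wall cost map
#'
#' `1 - F + c * H`, min-max normalized to \[0, 1\].  Low values mark
#' boundary evidence, i.e. the result is in cost orientation for the dual
#' dynamic-programming minimizer.
#'
#' @param F,H feature maps of identical shape (`F` boundary evidence, `H`
#'   sub-band brightness).
#' @param c weighting factor for the `H` term (dimensionless, default 0.5).
#' @return A `cawall_feature` cost matrix in \[0, 1\].
#' @export
combine_near_wall <- function(F, H, c = 0.5) {
  if (!all(dim(F) == dim(H))) abort("`F` and `H` must have the same shape")
  new_feature_map(normalize01(1 - unclass(F) + c * unclass(H)), "combined")
}

#' @export
print.cawall_feature <- function(x, ...) {
  cat("<cawall_feature>", attr(x, "provenance"),
      sprintf("%d x %d, range [%.3f, %.3f]\n", nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}
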