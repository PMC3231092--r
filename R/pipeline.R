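#' Rectangular region of interest
#'
#' 1-based, inclusive pixel rectangle: top-left corner `(x0, y0)`, `width`
#' columns and `height` rows.
#'
#' @param x0,y0 top-left corner (column, row).
#' @param width,height size in pixels.
#' @return A `roi_spec` list.
#' @export
roi_spec <- function(x0, y0, width, height) {
  if (width < 1 || height < 1) abort("ROI must have positive size")
  if (x0 < 1 || y0 < 1) abort("ROI corner must be inside the frame")
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(width), height = as.integer(height)),
            class = "roi_spec")
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("<roi_spec> x %d..%d, y %d..%d (%d x %d)\n",
              x$x0, x$x0 + x$width - 1L, x$y0, x$y0 + x$height - 1L,
              x$width, x$height))
  invisible(x)
}

crop_roi <- function(frame, roi) {
  ys <- roi$y0 + seq_len(roi$height) - 1L
  xs <- roi$x0 + seq_len(roi$width) - 1L
  if (max(ys) > nrow(frame) || max(xs) > ncol(frame))
    abort("ROI extends beyond the frame")
  frame[ys, xs, drop = FALSE]
}

#' Split a two-wall ROI into near- and far-wall halves
#'
#' The upper half holds the near wall, the lower half the far wall.  Odd
#' heights give the extra row to the upper half.
#'
#' @param roi a [roi_spec()] spanning both walls.
#' @return A list with elements `near` and `far` (both `roi_spec`).
#' @export
split_roi <- function(roi) {
  if (roi$height < 2) abort("ROI height must be at least 2 to split")
  upper <- ceiling(roi$height / 2)
  list(near = roi_spec(roi$x0, roi$y0, roi$width, upper),
       far = roi_spec(roi$x0, roi$y0 + upper, roi$width, roi$height - upper))
}

#' Pipeline parameters
#'
#' All tunable parameters of the detector with their defaults: DDP
#' smoothness weights and constraints (`d_min = 4` px, about 0.42 mm at
#' 0.106 mm/px; `d_max` = 0.9 of the half-ROI height; `k = 1`), MacLeod
#' geometry, the near-wall `H` combination (`r`, `c`), the tracking search
#' half-range, and the trace smoothing window.
#'
#' @param alpha,beta DDP smoothness weights (see [ddp_config()]).
#' @param k maximum per-column step, pixels.
#' @param d_min minimum intima-adventitia separation, pixels.
#' @param d_max_frac maximum separation as a fraction of the half-ROI
#'   height.
#' @param c weighting factor of the `H` term in the near-wall cost.
#' @param r averaging depth of [compute_feature_H()], pixels.
#' @param d_c,d_pk,macleod_size MacLeod kernel geometry, pixels.
#' @param combine orientation pooling of [compute_feature_F()].
#' @param flip_kernels apply kernels in convolution orientation.
#' @param delta_s tracking search half-range, pixels.
#' @param refine apply sub-pixel edge refinement ([refine_traces()]) in
#'   [cawall_run()].
#' @param smooth_window odd moving-average window for [smooth_traces()].
#' @param pixel_size_mm calibration, mm per pixel.
#' @return A `cawall_params` list.
#' @export
cawall_params <- function(alpha = 0.3, beta = 0.15, k = 1, d_min = 4,
                          d_max_frac = 0.9, c = 0.5, r = 5,
                          d_c = 2, d_pk = 2, macleod_size = 7,
                          combine = "sum", flip_kernels = FALSE,
                          delta_s = 10, refine = TRUE, smooth_window = 5,
                          pixel_size_mm = 0.106) {
  structure(list(alpha = alpha, beta = beta, k = k, d_min = d_min,
                 d_max_frac = d_max_frac, c = c, r = r, d_c = d_c,
                 d_pk = d_pk, macleod_size = macleod_size, combine = combine,
                 flip_kernels = flip_kernels, delta_s = delta_s,
                 refine = refine, smooth_window = smooth_window,
                 pixel_size_mm = pixel_size_mm),
            class = "cawall_params")
}

as_frames <- function(x) {
  if (inherits(x, "cca_phantom")) return(x$frames)
  if (inherits(x, "frame_sequence")) return(x$frames)
  if (is.list(x) && all(vapply(x, is.matrix, logical(1)))) return(x)
  abort("`frames` must be a frame sequence, a phantom, or a list of matrices")
}

new_wall_result <- function(traces, log, wall, roi, params) {
  structure(list(traces = traces, log = log, wall = wall, roi = roi,
                 params = params),
            class = "wall_result")
}

#' Detect the near-wall intima and adventitia across a sequence
#'
#' Runs the near-wall phase on the upper half of `roi` for every frame:
#' (1) the outer-wall line by single-curve dynamic programming on the
#' normalized response to the 9 x 1 step kernel; (2) the boundary feature
#' `F` with enhancement kernel `-f_IMT(far)`; (3) the sub-band brightness
#' feature `H` below the outer wall; (4) the combined cost
#' `1 - F + c * H`; (5) dual dynamic programming with `d_min = 4`,
#' `d_max = 0.9 M`, `k = 1`.  Between frames the half-ROI is re-registered
#' vertically by NCC tracking against the first frame.
#'
#' @param frames a frame sequence ([read_sequence()]), a `cca_phantom`, or
#'   a list of matrices in \[0, 1\].
#' @param roi a [roi_spec()] spanning both walls (its upper half must
#'   contain the near wall in every frame).
#' @param params a [cawall_params()].
#' @return A `wall_result`: `traces` tibble (frame, wall, layer, column,
#'   row — frame coordinates; for the near wall the adventitia lies above
#'   the intima), and a per-frame `log` tibble (frame, shift, ncc,
#'   total_cost).
#' @export
detect_near_wall <- function(frames, roi, params = cawall_params()) {
  detect_wall_impl(frames, roi, params, wall = "near")
}

#' Detect the far-wall intima and adventitia across a sequence
#'
#' The far-wall phase on the lower half of `roi`: boundary feature `F`
#' with enhancement kernel `f_IMT(far)`, cost `1 - F`, dual dynamic
#' programming with the same constraints as the near wall, and NCC
#' tracking between frames.  For the far wall the intima lies above the
#' adventitia.
#'
#' @inheritParams detect_near_wall
#' @return A `wall_result` (see [detect_near_wall()]).
#' @export
detect_far_wall <- function(frames, roi, params = cawall_params()) {
  detect_wall_impl(frames, roi, params, wall = "far")
}

detect_wall_impl <- function(frames, roi, params, wall) {
  frames <- as_frames(frames)
  half <- split_roi(roi)[[wall]]
  M <- half$height
  d_max <- min(as.integer(floor(params$d_max_frac * M)), M - 1L)
  if (d_max < params$d_min)
    abort("half-ROI too small for the separation constraints")
  cfg <- ddp_config(alpha = params$alpha, beta = params$beta, k = params$k,
                    d_min = params$d_min, d_max = d_max)
  f_far <- build_imt_kernel("far")
  f_x <- if (wall == "near") -unclass(f_far) else unclass(f_far)
  state <- if (length(frames) > 1) track_init(frames[[1]], half, params$delta_s)

  traces <- vector("list", length(frames))
  logs <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    if (i > 1) state <- tryCatch(track_frame(state, frames[[i]]),
                                 error = function(e) abort(sprintf(
                                   "%s wall, frame %d: %s", wall, i, conditionMessage(e))))
    shift <- if (i > 1) state$shift else 0L
    roi_i <- roi_spec(half$x0, half$y0 + shift, half$width, half$height)
    I <- normalize01(crop_roi(frames[[i]], roi_i))
    cost <- wall_cost_map(I, wall, f_x, params)
    dd <- tryCatch(run_ddp(cost, cfg),
                   error = function(e) abort(sprintf(
                     "%s wall, frame %d: %s", wall, i, conditionMessage(e))))
    layers <- if (wall == "near") c(adventitia = "y1", intima = "y2")
              else c(intima = "y1", adventitia = "y2")
    traces[[i]] <- bind_rows(lapply(names(layers), function(l) {
      tibble(frame = i, wall = wall, layer = l,
             column = half$x0 + seq_along(dd$y1) - 1L,
             row = dd[[layers[[l]]]] + roi_i$y0 - 1L)
    }))
    logs[[i]] <- tibble(frame = i, shift = shift, roi_y0 = roi_i$y0,
                        ncc = if (i > 1) tail(state$ncc_trace, 1) else NA_real_,
                        total_cost = dd$total_cost)
  }
  new_wall_result(bind_rows(traces), bind_rows(logs), wall, roi, params)
}

wall_cost_map <- function(I, wall, f_x, params) {
  if (wall == "near") {
    f1 <- normalize01(apply_kernel(I, build_outer_kernel(),
                                   flip = params$flip_kernels))
    y_outer <- run_single_dp(1 - f1, params$alpha, params$beta)
    Fmap <- compute_feature_F(I, f_x, macleod_size = params$macleod_size,
                              d_c = params$d_c, d_pk = params$d_pk,
                              combine = params$combine,
                              flip_kernels = params$flip_kernels)
    H <- compute_feature_H(I, y_outer, r = params$r)
    combine_near_wall(Fmap, H, params$c)
  } else {
    Fmap <- compute_feature_F(I, f_x, macleod_size = params$macleod_size,
                              d_c = params$d_c, d_pk = params$d_pk,
                              combine = params$combine,
                              flip_kernels = params$flip_kernels)
    1 - unclass(Fmap)
  }
}

#' Refine boundary lines to sub-pixel precision
#'
#' Dual dynamic programming localizes each boundary to an integer row.
#' This step moves every detected row to the sub-pixel location of the
#' nearest intensity transition of the wall's polarity (far:
#' dark-above/bright-below; near: bright-above/dark-below): within
#' `reach` rows of the detected line the steepest one-pixel step of that
#' polarity is found, and the edge is placed at the parabolic vertex of
#' the rectified vertical gradient around it — a standard leading-edge
#' localizer that is insensitive to the thickness of the echo band on
#' either side.  Columns where refinement would push the two lines closer
#' than the `d_min` separation keep their integer rows.
#'
#' @param result a `wall_result` from [detect_near_wall()] or
#'   [detect_far_wall()] (unsmoothed).
#' @param frames the same frame sequence the result was detected on.
#' @param reach search and plateau-estimation half-range, pixels.
#' @return The `wall_result` with sub-pixel rows.
#' @export
refine_traces <- function(result, frames, reach = 3) {
  frames <- as_frames(frames)
  half <- split_roi(result$roi)[[result$wall]]
  sgn <- if (result$wall == "far") 1 else -1
  d_min <- result$params$d_min
  tr <- result$traces
  out <- vector("list", nrow(result$log))
  for (i in seq_len(nrow(result$log))) {
    y0i <- result$log$roi_y0[i]
    roi_i <- roi_spec(half$x0, y0i, half$width, half$height)
    I <- normalize01(crop_roi(frames[[result$log$frame[i]]], roi_i))
    ti <- tr[tr$frame == result$log$frame[i], ]
    w <- tidyr::pivot_wider(ti, names_from = "layer", values_from = "row")
    w <- w[order(w$column), ]
    upper_l <- if (result$wall == "near") "adventitia" else "intima"
    lower_l <- if (result$wall == "near") "intima" else "adventitia"
    y_up <- w[[upper_l]] - y0i + 1L
    y_lo <- w[[lower_l]] - y0i + 1L
    r_up <- half_max_crossing(y_up, I, sgn, reach)
    r_lo <- half_max_crossing(y_lo, I, sgn, reach)
    bad <- (r_lo - r_up) < d_min
    r_up[bad] <- y_up[bad]
    r_lo[bad] <- y_lo[bad]
    w[[upper_l]] <- r_up + y0i - 1
    w[[lower_l]] <- r_lo + y0i - 1
    out[[i]] <- tidyr::pivot_longer(w, c(!!upper_l, !!lower_l),
                                    names_to = "layer", values_to = "row")
  }
  result$traces <- bind_rows(out) %>%
    select("frame", "wall", "layer", "column", "row") %>%
    arrange(.data$frame, .data$layer, .data$column)
  result
}

# sub-pixel edge localization around integer rows; sign = +1 means the
# line is a dark-above/bright-below transition (work in a flipped column
# for the opposite polarity).  Recenter on the steepest rising one-pixel
# step within `reach`, then take the parabolic vertex of the rectified
# gradient (samples live at y + 0.5).
half_max_crossing <- function(rows, I, sgn = 1, reach = 3) {
  M <- nrow(I)
  vapply(seq_along(rows), function(x) {
    y0 <- rows[x]
    if (sgn < 0) { Iv <- rev(I[, x]); y0 <- M - y0 + 1 } else Iv <- I[, x]
    ys <- max(2, y0 - reach):min(M - 2, y0 + reach)
    g <- Iv[ys + 1] - Iv[ys]
    best <- if (max(g) <= 0) {
      as.numeric(y0)
    } else {
      ystar <- ys[which.max(g)]
      gm <- max(0, Iv[ystar] - Iv[ystar - 1])
      g0 <- Iv[ystar + 1] - Iv[ystar]
      gp <- max(0, Iv[ystar + 2] - Iv[ystar + 1])
      den <- gm - 2 * g0 + gp
      d <- if (den >= 0) 0 else max(-1, min(1, 0.5 * (gm - gp) / den))
      ystar + 0.5 + d
    }
    if (sgn < 0) M - best + 1 else best
  }, numeric(1))
}

#' Smooth detected boundary lines along the columns
#'
#' Per-frame, per-layer moving average over columns with an odd window;
#' at the edges the window shrinks symmetrically.  Boundary ordering is
#' re-checked after smoothing.
#'
#' @param result a `wall_result`.
#' @param window odd number of columns (>= 1; 1 is the identity).
#' @return The `wall_result` with smoothed (possibly fractional) rows.
#' @export
smooth_traces <- function(result, window = 5) {
  if (window %% 2 == 0) abort("`window` must be odd")
  if (window < 1) abort("`window` must be >= 1")
  if (window == 1) return(result)
  tr <- result$traces %>%
    group_by(.data$frame, .data$layer) %>%
    arrange(.data$column, .by_group = TRUE) %>%
    mutate(row = moving_average(.data$row, window)) %>%
    ungroup()
  check <- tr %>%
    tidyr::pivot_wider(names_from = "layer", values_from = "row") %>%
    mutate(ok = if (result$wall == "near") .data$adventitia <= .data$intima
                else .data$intima <= .data$adventitia)
  if (!all(check$ok)) abort("boundary ordering violated after smoothing")
  result$traces <- tr
  result
}

# shrinking-edge moving average (odd window)
moving_average <- function(v, window) {
  if (window == 1) return(v)
  half <- (window - 1) / 2
  n <- length(v)
  vapply(seq_len(n), function(i) {
    mean(v[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Assemble the lumen-diameter series
#'
#' Per column and frame, the far-wall intima row minus the near-wall
#' intima row; per frame, the column mean.  Reported in pixels and mm.
#'
#' @param near,far `wall_result`s for the near and far walls over the same
#'   frames and column span.
#' @param pixel_size_mm calibration, mm per pixel.
#' @return A `lumen_series`: `per_column` tibble (frame, column, ld_px,
#'   ld_mm) and `per_frame` tibble (frame, mean_ld_px, mean_ld_mm).
#' @export
lumen_series <- function(near, far, pixel_size_mm = 0.106) {
  ni <- near$traces %>% filter(.data$layer == "intima") %>%
    select("frame", "column", near_row = "row")
  fi <- far$traces %>% filter(.data$layer == "intima") %>%
    select("frame", "column", far_row = "row")
  j <- inner_join(ni, fi, by = c("frame", "column"))
  if (nrow(j) == 0) abort("near and far results share no frames/columns")
  j <- j %>% mutate(ld_px = .data$far_row - .data$near_row)
  if (any(j$ld_px <= 0))
    abort("crossing walls: non-positive lumen diameter encountered")
  per_column <- j %>% mutate(ld_mm = .data$ld_px * pixel_size_mm) %>%
    select("frame", "column", "ld_px", "ld_mm")
  per_frame <- per_column %>% group_by(.data$frame) %>%
    summarise(mean_ld_px = mean(.data$ld_px),
              mean_ld_mm = mean(.data$ld_mm), .groups = "drop")
  structure(list(per_column = per_column, per_frame = per_frame,
                 pixel_size_mm = pixel_size_mm),
            class = "lumen_series")
}

#' Run the full two-wall pipeline
#'
#' Near-wall phase, far-wall phase, sub-pixel edge refinement
#' ([refine_traces()], unless `params$refine` is `FALSE`), trace
#' smoothing, and lumen-diameter assembly.
#'
#' @inheritParams detect_near_wall
#' @return A `cawall_result`: smoothed `near` and `far` `wall_result`s and
#'   the `lumen` series.
#' @export
cawall_run <- function(frames, roi, params = cawall_params()) {
  near <- detect_near_wall(frames, roi, params)
  far <- detect_far_wall(frames, roi, params)
  if (isTRUE(params$refine)) {
    near <- refine_traces(near, frames)
    far <- refine_traces(far, frames)
  }
  near <- smooth_traces(near, params$smooth_window)
  far <- smooth_traces(far, params$smooth_window)
  structure(list(near = near, far = far,
                 lumen = lumen_series(near, far, params$pixel_size_mm),
                 roi = roi, params = params),
            class = "cawall_result")
}

#' @describeIn detect_near_wall Tidy a `wall_result` into its trace tibble.
#' @param x a `wall_result`.
#' @param ... unused.
#' @export
tidy.wall_result <- function(x, ...) as_tibble(x$traces)

#' @describeIn detect_near_wall One row per frame: tracking shift, NCC and
#'   DDP cost.
#' @export
glance.wall_result <- function(x, ...) as_tibble(x$log)

#' @describeIn lumen_series Tidy the per-frame mean lumen diameters.
#' @param x a `lumen_series`.
#' @param ... unused.
#' @export
tidy.lumen_series <- function(x, ...) as_tibble(x$per_frame)

#' @export
print.wall_result <- function(x, ...) {
  cat(sprintf("<wall_result> %s wall, %d frames x %d columns\n",
              x$wall, dplyr::n_distinct(x$traces$frame),
              dplyr::n_distinct(x$traces$column)))
  invisible(x)
}

#' @export
print.lumen_series <- function(x, ...) {
  cat(sprintf("<lumen_series> %d frames, mean LD %.2f px (%.3f mm)\n",
              nrow(x$per_frame), mean(x$per_frame$mean_ld_px),
              mean(x$per_frame$mean_ld_mm)))
  invisible(x)
}

#' @export
print.cawall_result <- function(x, ...) {
  cat("<cawall_result>\n")
  print(x$near); print(x$far); print(x$lumen)
  invisible(x)
}
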