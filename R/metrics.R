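#' Per-frame boundary error
#'
#' Mean absolute (unsigned) or mean raw (signed) row difference between a
#' detected line and a reference line sampled at the same columns.
#'
#' @param reference,detected numeric row vectors of equal length.
#' @param signed if `TRUE`, the mean raw difference `detected - reference`
#'   (bias); otherwise the mean absolute difference.
#' @return Error in pixels.
#' @export
frame_error <- function(reference, detected, signed = FALSE) {
  if (length(reference) != length(detected))
    abort("`reference` and `detected` must have equal length")
  if (length(reference) < 1) abort("empty traces")
  d <- detected - reference
  if (signed) mean(d) else mean(abs(d))
}

#' Sequence-level error
#'
#' Arithmetic mean of the per-frame errors.
#'
#' @param per_frame numeric vector of per-frame errors.
#' @return Mean error in pixels.
#' @export
sequence_error <- function(per_frame) {
  if (length(per_frame) == 0) abort("no per-frame errors supplied")
  mean(per_frame)
}

#' Convert pixels to millimetres
#'
#' @param value value in pixels.
#' @param pixel_size_mm calibration, mm per pixel (default 0.106).
#' @param sf significant figures for reporting (summaries use 3); `NULL`
#'   returns the exact product.
#' @return Value in mm.
#' @export
px_to_mm <- function(value, pixel_size_mm = 0.106, sf = NULL) {
  if (pixel_size_mm <= 0) abort("`pixel_size_mm` must be positive")
  out <- value * pixel_size_mm
  if (!is.null(sf)) out <- signif(out, sf)
  out
}

#' Interpolate a sparse reference line onto a column grid
#'
#' Linear interpolation between reference points, as used when a manual
#' tracing provides only a few points per frame.
#'
#' @param columns,rows reference points (at least 2).
#' @param at columns to evaluate at (must lie within the reference span).
#' @return Interpolated rows at `at`.
#' @export
interp_reference <- function(columns, rows, at) {
  if (length(columns) < 2) abort("need at least 2 reference points")
  if (min(at) < min(columns) || max(at) > max(columns))
    abort("`at` extends beyond the reference span")
  approx(columns, rows, xout = at)$y
}

#' Boundary errors of a wall result against ground truth
#'
#' Joins the detected traces with the phantom truth on frame and column
#' (the intersection of their column supports) and computes per-frame,
#' per-layer unsigned and signed errors.
#'
#' @param result a `wall_result` (smoothed or raw).
#' @param truth a truth tibble with columns `frame, wall, column,
#'   intima_row, adventitia_row` (e.g. from [generate_sequence()]).
#' @param pixel_size_mm calibration for the mm columns.
#' @return A tibble: frame, wall, layer, n, e_unsigned, e_signed (pixels)
#'   and their mm equivalents.
#' @export
wall_error <- function(result, truth, pixel_size_mm = 0.106) {
  ref <- truth %>% filter(.data$wall == result$wall) %>%
    tidyr::pivot_longer(c("intima_row", "adventitia_row"),
                        names_to = "layer", values_to = "ref_row") %>%
    mutate(layer = sub("_row$", "", .data$layer))
  j <- inner_join(result$traces, ref,
                  by = c("frame", "wall", "layer", "column"))
  if (nrow(j) == 0) abort("traces and truth share no frames/columns")
  j %>% group_by(.data$frame, .data$wall, .data$layer) %>%
    summarise(n = n(),
              e_unsigned = mean(abs(.data$row - .data$ref_row)),
              e_signed = mean(.data$row - .data$ref_row),
              .groups = "drop") %>%
    mutate(e_unsigned_mm = px_to_mm(.data$e_unsigned, pixel_size_mm),
           e_signed_mm = px_to_mm(.data$e_signed, pixel_size_mm))
}

#' Pooled error summary of a wall
#'
#' Sequence means of the per-frame unsigned and signed errors, pooled over
#' the intima and adventitia layers.
#'
#' @param errors a tibble from [wall_error()].
#' @param pixel_size_mm calibration for the mm columns.
#' @return A one-row tibble: wall, frames, E_unsigned, E_signed (pixels)
#'   and mm equivalents (3 significant figures).
#' @export
error_summary <- function(errors, pixel_size_mm = 0.106) {
  errors %>% group_by(.data$wall) %>%
    summarise(frames = dplyr::n_distinct(.data$frame),
              E_unsigned = sequence_error(.data$e_unsigned),
              E_signed = sequence_error(.data$e_signed),
              .groups = "drop") %>%
    mutate(E_unsigned_mm = px_to_mm(.data$E_unsigned, pixel_size_mm, sf = 3),
           E_signed_mm = px_to_mm(.data$E_signed, pixel_size_mm, sf = 3))
}

#' Carotid distensibility and stiffness
#'
#' `CDist = delta_area / (area_diastole * delta_pressure)` and
#' `CS = CDist^(-1/2)`.  When starting from lumen diameters, areas are
#' derived under a circular-lumen assumption `A = pi * (LD / 2)^2` (an
#' approximation: the method measures diameters, not areas).
#'
#' @param area_diastole diastolic lumen area, mm^2.
#' @param delta_area maximum systolic-diastolic area change, mm^2.
#' @param delta_pressure local pulse pressure (sphygmometer units).
#' @return A one-row tibble with `cdist` and `cs`.
#' @export
distensibility <- function(area_diastole, delta_area, delta_pressure) {
  if (area_diastole <= 0 || delta_area <= 0 || delta_pressure <= 0)
    abort("all inputs must be positive")
  cdist <- delta_area / (area_diastole * delta_pressure)
  tibble(cdist = cdist, cs = cdist^(-1 / 2))
}

#' @describeIn distensibility Distensibility from a lumen-diameter series:
#'   diastolic area from the minimum per-frame mean LD, `delta_area` from
#'   the maximum, circular-lumen assumption.
#' @param lumen a `lumen_series`.
#' @export
lumen_distensibility <- function(lumen, delta_pressure) {
  ld <- lumen$per_frame$mean_ld_mm
  a_dias <- pi * (min(ld) / 2)^2
  a_syst <- pi * (max(ld) / 2)^2
  distensibility(a_dias, a_syst - a_dias, delta_pressure)
}
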