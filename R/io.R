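#' Read a directory of grayscale frames
#'
#' Loads all PNG frames in natural filename order (numeric runs compare
#' numerically, so `frame2.png` sorts before `frame10.png`).  Pixel values
#' are in \[0, 1\] on load; color images are converted to grayscale by
#' Rec. 709 luminance with a warning.  All frames must share one shape.
#'
#' @param directory path containing the frames.
#' @param pixel_size_mm calibration attached to the sequence, mm per pixel.
#' @return A `frame_sequence`: `frames` (list of matrices), `files`, and
#'   `pixel_size_mm`.
#' @export
read_sequence <- function(directory, pixel_size_mm = 0.106) {
  if (!dir.exists(directory)) abort(sprintf("no such directory: %s", directory))
  files <- list.files(directory, pattern = "\\.png$", ignore.case = TRUE)
  if (length(files) == 0) abort(sprintf("no PNG frames found in %s", directory))
  files <- files[natural_order(files)]
  frames <- lapply(file.path(directory, files), read_gray_png)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])) {
    bad <- files[dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1]]
    abort(paste("frames differ in shape:", paste(bad, collapse = ", ")))
  }
  structure(list(frames = frames, files = files,
                 pixel_size_mm = pixel_size_mm),
            class = "frame_sequence")
}

read_gray_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) {
    warning(sprintf("color image %s converted to grayscale by luminance",
                    basename(path)), call. = FALSE)
    if (dim(img)[3] >= 3)
      img <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
    else img <- img[, , 1]
  }
  img
}

# order filenames so embedded integer runs compare numerically
natural_order <- function(x) {
  prefix <- sub("([0-9]+).*$", "", x)
  num <- suppressWarnings(as.numeric(sub("^[^0-9]*([0-9]+).*$", "\\1", x)))
  num[is.na(num)] <- Inf
  order(prefix, num, x)
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_sequence> %d frames of %d x %d px (%.3f mm/px)\n",
              length(x$frames), d[1], d[2], x$pixel_size_mm))
  invisible(x)
}

#' Write detection results to disk
#'
#' Writes `traces.csv` (frame, wall, layer, column, row_px, row_mm),
#' `lumen.csv` (frame, mean_ld_px, mean_ld_mm), the fully resolved
#' parameter set as `params.yaml`, and optionally one overlay PNG per
#' frame with the detected lines burnt in white.
#'
#' @param result a `cawall_result` from [cawall_run()].
#' @param out_dir output directory (created if needed).
#' @param frames optional frame list for overlays.
#' @param overlays write overlay PNGs.
#' @return Invisibly, the paths written.
#' @export
write_traces <- function(result, out_dir, frames = NULL, overlays = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  psz <- result$params$pixel_size_mm
  tr <- bind_rows(result$near$traces, result$far$traces) %>%
    mutate(row_px = .data$row, row_mm = .data$row * psz) %>%
    select("frame", "wall", "layer", "column", "row_px", "row_mm")
  tp <- file.path(out_dir, "traces.csv")
  utils::write.csv(tr, tp, row.names = FALSE)
  lp <- file.path(out_dir, "lumen.csv")
  utils::write.csv(result$lumen$per_frame, lp, row.names = FALSE)
  pp <- file.path(out_dir, "params.yaml")
  yaml::write_yaml(unclass(result$params), pp)
  paths <- list(traces = tp, lumen = lp, params = pp)
  if (overlays) {
    frames <- as_frames(frames)
    paths$overlays <- vapply(seq_along(frames), function(i) {
      img <- frames[[i]]
      ti <- tr[tr$frame == i, ]
      rows <- pmin(pmax(round(ti$row_px), 1), nrow(img))
      img[cbind(rows, ti$column)] <- 1
      p <- file.path(out_dir, sprintf("overlay%04d.png", i))
      png::writePNG(img, p)
      p
    }, character(1))
  }
  invisible(paths)
}

#' Read a traces CSV written by [write_traces()]
#'
#' @param path the `traces.csv` file.
#' @return A tibble with the documented schema.
#' @export
read_traces <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read/write a run configuration
#'
#' Flat key-value YAML holding [cawall_params()] fields plus the ROI and
#' frame directory; unknown keys are rejected.
#'
#' @param path YAML file.
#' @return For `read_run_config`, a list with `params` ([cawall_params()]),
#'   `roi` ([roi_spec()] or `NULL`) and any `frames`/`out` paths.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(cawall_params))
  pars <- raw[intersect(names(raw), known)]
  extra <- setdiff(names(raw), c(known, "roi", "frames", "out"))
  if (length(extra))
    abort(paste("unknown configuration keys:", paste(extra, collapse = ", ")))
  roi <- if (!is.null(raw$roi)) do.call(roi_spec, raw$roi)
  list(params = do.call(cawall_params, pars), roi = roi,
       frames = raw$frames, out = raw$out)
}
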