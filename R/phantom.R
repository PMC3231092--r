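#' Synthetic pulsatile artery phantom configuration
#'
#' Defines a longitudinal B-mode-like phantom: a dark lumen bounded by two
#' layered walls (bright intima band, dark media, bright adventitia band)
#' whose lumen diameter pulses sinusoidally over the cardiac cycle, with
#' bulk vertical wall drift, clamped multiplicative Rayleigh speckle, an
#' optional plaque bump, and an optional sub-intima noise layer that
#' appears in configured (typically systolic) frames.
#'
#' Truth rows are the four classic interfaces, sub-pixel valued: for the
#' near wall the adventitia-media and intima-lumen interfaces (each at the
#' lower edge of its bright band), for the far wall the lumen-intima and
#' media-adventitia interfaces (each at the upper edge of its bright
#' band).  Interfaces are rendered as logistic transitions of width
#' `edge_width` so sub-pixel truth is meaningful.
#'
#' @param width,height frame size in pixels.
#' @param n_frames number of frames.
#' @param pixel_size_mm calibration, mm per pixel.
#' @param lumen_center_row mean row of the lumen centre.
#' @param baseline_lumen_diameter mean lumen diameter, pixels.
#' @param pulsation_amplitude lumen-diameter pulsation amplitude, pixels;
#'   diameter at frame `t` is `baseline + amplitude *
#'   sin(2 * pi * (t - 1) / frames_per_cycle)`.
#' @param frames_per_cycle frames per cardiac cycle.
#' @param imt_near,imt_far intima-media thickness of each wall, pixels.
#' @param wall_drift_amplitude bulk vertical wall translation amplitude,
#'   pixels (same period as the pulsation).
#' @param speckle_scale speckle strength (>= 0): pixel values are
#'   multiplied by `1 + speckle_scale * (R - 1)` with `R` Rayleigh
#'   distributed with mean 1, then clamped to \[0, 1\] and quantized to
#'   8 bits.  0.25 is the package's "moderate" level (about 13 percent
#'   multiplicative standard deviation).
#' @param plaque optional `list(wall = "near"|"far", columns = c(from, to),
#'   max_extra = pixels)`: a raised-cosine focal thickening of the intima
#'   protruding into the lumen.
#' @param subintima_noise optional `list(intensity, thickness, frames)`:
#'   an echogenic clutter layer of the given intensity and pixel thickness
#'   rendered directly below the near-wall intima in the listed frames
#'   (see [systolic_frames()]).  Its upper boundary hugs the intima with
#'   anatomical sharpness; its lower boundary fades diffusely into the
#'   lumen (width scaled to the layer thickness), since speckle clutter
#'   has no distal interface.
#' @param echo_intima,echo_adventitia rendered thickness of the bright
#'   intima/adventitia echo bands, pixels.
#' @param edge_width logistic softness of every interface, pixels.
#' @param seed integer seed; identical seed and config give bit-identical
#'   sequences.
#' @return A validated `phantom_config` list.
#' @export
phantom_config <- function(width = 128, height = 160, n_frames = 80,
                           pixel_size_mm = 0.106, lumen_center_row = 80,
                           baseline_lumen_diameter = 48,
                           pulsation_amplitude = 4, frames_per_cycle = 40,
                           imt_near = 5, imt_far = 5,
                           wall_drift_amplitude = 1, speckle_scale = 0.25,
                           plaque = NULL, subintima_noise = NULL,
                           echo_intima = 2, echo_adventitia = 3,
                           edge_width = 0.7, seed = 42L) {
  cfg <- list(width = as.integer(width), height = as.integer(height),
              n_frames = as.integer(n_frames), pixel_size_mm = pixel_size_mm,
              lumen_center_row = lumen_center_row,
              baseline_lumen_diameter = baseline_lumen_diameter,
              pulsation_amplitude = pulsation_amplitude,
              frames_per_cycle = frames_per_cycle,
              imt_near = imt_near, imt_far = imt_far,
              wall_drift_amplitude = wall_drift_amplitude,
              speckle_scale = speckle_scale,
              plaque = plaque, subintima_noise = subintima_noise,
              echo_intima = echo_intima, echo_adventitia = echo_adventitia,
              edge_width = edge_width, seed = as.integer(seed))
  if (cfg$baseline_lumen_diameter - cfg$pulsation_amplitude <= 0)
    abort("baseline_lumen_diameter - pulsation_amplitude must be positive")
  if (cfg$speckle_scale < 0) abort("speckle_scale must be >= 0")
  if (cfg$echo_intima >= min(cfg$imt_near, cfg$imt_far))
    abort("intima echo band must be thinner than the IMT (media must remain)")
  if (!is.null(plaque)) {
    stopifnot(plaque$wall %in% c("near", "far"), length(plaque$columns) == 2,
              plaque$max_extra > 0)
  }
  class(cfg) <- "phantom_config"
  geo <- phantom_geometry(cfg)   # validates that geometry fits every frame
  margin <- 3 * cfg$edge_width
  bad <- geo$frame[geo$near_adventitia - cfg$echo_adventitia - margin < 1 |
                     geo$far_adventitia + cfg$echo_adventitia + margin > cfg$height]
  if (length(bad))
    abort(sprintf("wall geometry escapes the frame at frame %d", bad[1]))
  cfg
}

# interface rows per frame x column (sub-pixel, noise-free truth)
phantom_geometry <- function(cfg) {
  t <- seq_len(cfg$n_frames)
  phase <- 2 * pi * (t - 1) / cfg$frames_per_cycle
  ld <- cfg$baseline_lumen_diameter + cfg$pulsation_amplitude * sin(phase)
  shift <- cfg$wall_drift_amplitude * sin(phase)
  centre <- cfg$lumen_center_row + shift
  g <- tidyr::expand_grid(frame = t, column = seq_len(cfg$width))
  g$bulk_shift <- shift[g$frame]
  g$near_intima <- centre[g$frame] - ld[g$frame] / 2
  g$far_intima <- centre[g$frame] + ld[g$frame] / 2
  p <- numeric(nrow(g))
  if (!is.null(cfg$plaque)) {
    pl <- cfg$plaque
    inb <- g$column >= pl$columns[1] & g$column <= pl$columns[2]
    u <- (g$column[inb] - pl$columns[1]) / diff(pl$columns)
    p[inb] <- pl$max_extra * sin(pi * u)^2
    if (pl$wall == "near") g$near_intima <- g$near_intima + p
    else g$far_intima <- g$far_intima - p
  }
  # adventitia interfaces stay at the baseline wall position (a plaque
  # thickens the wall toward the lumen only)
  g$near_adventitia <- (centre[g$frame] - ld0_half(cfg, g$frame)) - cfg$imt_near
  g$far_adventitia <- (centre[g$frame] + ld0_half(cfg, g$frame)) + cfg$imt_far
  g
}

ld0_half <- function(cfg, frames) {
  phase <- 2 * pi * (frames - 1) / cfg$frames_per_cycle
  (cfg$baseline_lumen_diameter + cfg$pulsation_amplitude * sin(phase)) / 2
}

#' Frames in the systolic (expansion) phase
#'
#' The frames where the lumen diameter is increasing, i.e. where the
#' phantom's sub-intima noise layer appears when enabled.
#'
#' @param config a [phantom_config()].
#' @return Integer frame indices.
#' @export
systolic_frames <- function(config) {
  t <- seq_len(config$n_frames)
  which(cos(2 * pi * (t - 1) / config$frames_per_cycle) > 0)
}

#' Generate a phantom image sequence with exact ground truth
#'
#' Renders every frame of the configured phantom (8-bit quantized gray
#' levels in \[0, 1\]) and returns it together with the analytic,
#' noise-free boundary truth.  Layer intensities are ordered
#' lumen < media < tissue < intima < adventitia.
#'
#' @param config a [phantom_config()].
#' @return A `cca_phantom` list: `frames` (list of matrices), `truth`
#'   (tibble: frame, wall, column, intima_row, adventitia_row), `lumen`
#'   (tibble: frame, column, lumen_diameter), `shift` (tibble: frame,
#'   bulk_shift), and the `config`.
#' @export
generate_sequence <- function(config) {
  cfg <- config
  geo <- phantom_geometry(cfg)
  lev <- c(lumen = 0.05, media = 0.10, tissue = 0.30,
           intima = 0.80, adventitia = 0.90)
  noise_frames <- if (!is.null(cfg$subintima_noise)) cfg$subintima_noise$frames else integer(0)

  frames <- local_seed(cfg$seed, {
    lapply(seq_len(cfg$n_frames), function(t) {
      gt <- geo[geo$frame == t, ]
      img <- render_phantom_frame(cfg, gt, lev, noisy = t %in% noise_frames)
      if (cfg$speckle_scale > 0) {
        r <- sqrt(2 / pi) * sqrt(-2 * log(runif(length(img))))
        img <- img * (1 + cfg$speckle_scale * (r - 1))
      }
      matrix(round(pmin(pmax(img, 0), 1) * 255) / 255, cfg$height, cfg$width)
    })
  })

  truth <- bind_rows(
    tibble(frame = geo$frame, wall = "near", column = geo$column,
           intima_row = geo$near_intima, adventitia_row = geo$near_adventitia),
    tibble(frame = geo$frame, wall = "far", column = geo$column,
           intima_row = geo$far_intima, adventitia_row = geo$far_adventitia)
  ) %>% arrange(.data$frame, .data$wall, .data$column)
  lumen <- tibble(frame = geo$frame, column = geo$column,
                  lumen_diameter = geo$far_intima - geo$near_intima)
  shift <- dplyr::distinct(tibble(frame = geo$frame, bulk_shift = geo$bulk_shift))
  structure(list(frames = frames, truth = truth, lumen = lumen,
                 shift = shift, config = cfg),
            class = "cca_phantom")
}

render_phantom_frame <- function(cfg, gt, lev, noisy) {
  y <- seq_len(cfg$height)
  w <- cfg$edge_width
  profile_for <- function(i) {
    bp_pos <- c(gt$near_adventitia[i] - cfg$echo_adventitia,
                gt$near_adventitia[i],
                gt$near_intima[i] - cfg$echo_intima,
                gt$near_intima[i])
    bp_lev <- c(lev["adventitia"], lev["media"], lev["intima"],
                if (noisy) cfg$subintima_noise$intensity else lev["lumen"])
    if (noisy) {
      bp_pos <- c(bp_pos, gt$near_intima[i] + cfg$subintima_noise$thickness)
      bp_lev <- c(bp_lev, lev["lumen"])
    }
    # the clutter layer fades diffusely into the lumen (incoherent echoes,
    # not an anatomical interface); anatomical edges keep width `w`
    bp_w <- c(rep(w, 4), if (noisy) noise_edge_width(cfg), rep(w, 4))
    bp_pos <- c(bp_pos, gt$far_intima[i], gt$far_intima[i] + cfg$echo_intima,
                gt$far_adventitia[i], gt$far_adventitia[i] + cfg$echo_adventitia)
    bp_lev <- c(bp_lev, lev["intima"], lev["media"], lev["adventitia"],
                lev["tissue"])
    v <- rep(lev["tissue"], cfg$height)
    prev <- lev["tissue"]
    for (j in seq_along(bp_pos)) {
      v <- v + (bp_lev[j] - prev) * plogis((y - bp_pos[j]) / bp_w[j])
      prev <- bp_lev[j]
    }
    v
  }
  # columns share one profile unless a plaque makes geometry column-dependent
  if (is.null(cfg$plaque)) {
    matrix(profile_for(1), cfg$height, cfg$width)
  } else {
    vapply(seq_len(cfg$width), profile_for, numeric(cfg$height))
  }
}

# lower-boundary softness of the sub-intima clutter layer: diffuse, scaled
# to the layer thickness (speckle clutter has no sharp distal interface)
noise_edge_width <- function(cfg) {
  max(1.5, cfg$subintima_noise$thickness / 2)
}

# evaluate an expression under a fixed seed, restoring the caller's RNG state
local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default region of interest around the phantom walls
#'
#' Builds a rectangle guaranteed to contain the relevant wall(s) in every
#' frame with an 8-pixel margin (plus the echo bands).  For
#' `purpose = "lumen"` the rectangle spans both walls and is vertically
#' symmetric about the mean lumen centre, so that the pipeline's
#' half-split puts one wall in each half.
#'
#' @param phantom a `cca_phantom` (or its `truth` tibble plus `config`).
#' @param purpose `"lumen"`, `"imt_near"` or `"imt_far"`.
#' @param margin extra rows beyond the wall extremes, pixels.
#' @return A [roi_spec()].
#' @export
default_roi <- function(phantom, purpose = c("lumen", "imt_near", "imt_far"),
                        margin = 8) {
  purpose <- match.arg(purpose)
  truth <- phantom$truth
  cfg <- phantom$config
  if (is.null(truth) || nrow(truth) == 0) abort("empty phantom truth")
  band <- function(w) {
    tr <- truth[truth$wall == w, ]
    if (w == "near")
      c(min(tr$adventitia_row) - cfg$echo_adventitia, max(tr$intima_row))
    else
      c(min(tr$intima_row), max(tr$adventitia_row) + cfg$echo_adventitia)
  }
  rows <- switch(purpose,
    imt_near = band("near"),
    imt_far = band("far"),
    lumen = {
      b <- c(band("near")[1], band("far")[2])
      centre <- mean(c(cfg$lumen_center_row))
      hh <- max(centre - b[1], b[2] - centre)
      c(centre - hh, centre + hh)
    })
  y0 <- max(1L, as.integer(floor(rows[1] - margin)))
  y1 <- min(cfg$height, as.integer(ceiling(rows[2] + margin)))
  x0 <- 5L
  x1 <- cfg$width - 4L
  roi_spec(x0 = x0, y0 = y0, width = x1 - x0 + 1L, height = y1 - y0 + 1L)
}

#' Write a phantom to disk
#'
#' Frames as numbered 8-bit grayscale PNG files plus the truth table as
#' CSV (`frame, wall, column, intima_row, adventitia_row`).
#'
#' @param phantom a `cca_phantom`.
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with the frame paths and the truth path.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(phantom$frames), function(i) {
    p <- file.path(dir, sprintf("frame%04d.png", i))
    png::writePNG(phantom$frames[[i]], p)
    p
  }, character(1))
  tp <- file.path(dir, "truth.csv")
  utils::write.csv(phantom$truth, tp, row.names = FALSE)
  invisible(list(frames = paths, truth = tp))
}

#' @describeIn generate_sequence Tidy the phantom ground truth (one row
#'   per frame, wall and column).
#' @param x a `cca_phantom`.
#' @param ... unused.
#' @export
tidy.cca_phantom <- function(x, ...) as_tibble(x$truth)

#' @export
print.cca_phantom <- function(x, ...) {
  cat(sprintf("<cca_phantom> %d frames of %d x %d px (%.3f mm/px), speckle %.2f\n",
              x$config$n_frames, x$config$height, x$config$width,
              x$config$pixel_size_mm, x$config$speckle_scale))
  invisible(x)
}
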