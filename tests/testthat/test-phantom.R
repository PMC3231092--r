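test_that("identical seed and config give bit-identical sequences", {
  cfg <- tiny_phantom_config()
  a <- generate_sequence(cfg)
  b <- generate_sequence(cfg)
  expect_identical(a$frames, b$frames)
  expect_identical(a$truth, b$truth)
  # a different seed changes the speckle
  c <- generate_sequence(tiny_phantom_config(seed = 7))
  expect_false(identical(a$frames, c$frames))
})

test_that("a degenerate static, noise-free config freezes the sequence", {
  cfg <- tiny_phantom_config(speckle_scale = 0, pulsation_amplitude = 0,
                             wall_drift_amplitude = 0)
  ph <- generate_sequence(cfg)
  for (i in 2:cfg$n_frames) expect_identical(ph$frames[[i]], ph$frames[[1]])
  spread <- tapply(ph$truth$intima_row, ph$truth$wall, function(v) diff(range(v)))
  expect_true(all(spread == 0))
})

test_that("lumen pulsation spans twice the configured amplitude", {
  cfg <- phantom_config(pulsation_amplitude = 4, frames_per_cycle = 40,
                        n_frames = 40)
  ph <- generate_sequence(cfg)
  spread <- diff(range(ph$lumen$lumen_diameter))
  expect_equal(spread, 8, tolerance = 0.02)  # sine sampled on 40 points
})

test_that("truth lumen diameter equals the intima separation exactly", {
  ph <- generate_sequence(tiny_phantom_config(
    plaque = list(wall = "far", columns = c(20, 44), max_extra = 6)))
  near <- ph$truth[ph$truth$wall == "near", ]
  far <- ph$truth[ph$truth$wall == "far", ]
  expect_equal(far$intima_row - near$intima_row, ph$lumen$lumen_diameter)
  # intima-adventitia separation is the IMT plus the plaque profile
  base_sep <- far$adventitia_row - far$intima_row - ph$config$imt_far
  expect_true(all(base_sep >= -1e-9))
  expect_equal(max(base_sep), 6, tolerance = 1e-9)
  outside <- far$column < 20 | far$column > 44
  expect_true(all(abs(base_sep[outside]) < 1e-9))
  expect_equal(near$intima_row - near$adventitia_row,
               rep(ph$config$imt_near, nrow(near)))
})

test_that("speckle strength increases mean deviation monotonically", {
  base <- generate_sequence(tiny_phantom_config(speckle_scale = 0, n_frames = 2))
  devs <- vapply(c(0.1, 0.25, 0.5), function(s) {
    ph <- generate_sequence(tiny_phantom_config(speckle_scale = s, n_frames = 2))
    mean(abs(ph$frames[[1]] - base$frames[[1]]))
  }, numeric(1))
  expect_true(all(diff(devs) > 0))
})

test_that("truth is periodic over the cardiac cycle", {
  cfg <- tiny_phantom_config(n_frames = 16, frames_per_cycle = 8,
                             wall_drift_amplitude = 0)
  ph <- generate_sequence(cfg)
  ld <- tapply(ph$lumen$lumen_diameter, ph$lumen$frame, mean)
  expect_equal(unname(ld[1:8]), unname(ld[9:16]))
})

test_that("geometry escaping the frame is rejected with the frame named", {
  expect_error(tiny_phantom_config(lumen_center_row = 140), "frame 1")
  expect_error(tiny_phantom_config(baseline_lumen_diameter = 4,
                                   pulsation_amplitude = 5), "positive")
  expect_error(tiny_phantom_config(echo_intima = 5), "thinner")
})

test_that("systolic frames are the expansion phase of each cycle", {
  cfg <- tiny_phantom_config(n_frames = 16, frames_per_cycle = 8)
  sf <- systolic_frames(cfg)
  ld <- cfg$baseline_lumen_diameter +
    cfg$pulsation_amplitude * sin(2 * pi * (seq_len(16) - 1) / 8)
  expanding <- which(cos(2 * pi * (seq_len(16) - 1) / 8) > 0)
  expect_identical(sf, expanding)
})

test_that("default ROIs contain the relevant walls in every frame", {
  ph <- generate_sequence(tiny_phantom_config())
  for (purpose in c("imt_near", "imt_far", "lumen")) {
    roi <- default_roi(ph, purpose)
    walls <- switch(purpose, imt_near = "near", imt_far = "far",
                    lumen = c("near", "far"))
    tr <- ph$truth[ph$truth$wall %in% walls, ]
    expect_true(all(tr$intima_row >= roi$y0 &
                      tr$intima_row <= roi$y0 + roi$height - 1))
    expect_true(all(tr$adventitia_row >= roi$y0 &
                      tr$adventitia_row <= roi$y0 + roi$height - 1))
  }
  # lumen ROI is tall enough for the lumen plus both walls
  roi <- default_roi(ph, "lumen")
  expect_gte(roi$height, max(ph$lumen$lumen_diameter) +
               ph$config$imt_near + ph$config$imt_far)
  expect_error(default_roi(list(truth = NULL, config = ph$config)), "empty")
})

test_that("phantoms round-trip through PNG frames and truth CSV", {
  dir <- withr::local_tempdir()
  ph <- generate_sequence(tiny_phantom_config(n_frames = 3))
  write_phantom(ph, dir)
  seq2 <- read_sequence(dir)
  expect_length(seq2$frames, 3)
  for (i in 1:3) expect_equal(seq2$frames[[i]], ph$frames[[i]])
  truth2 <- utils::read.csv(file.path(dir, "truth.csv"))
  expect_equal(nrow(truth2), nrow(ph$truth))
  expect_equal(truth2$intima_row, ph$truth$intima_row)
})
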