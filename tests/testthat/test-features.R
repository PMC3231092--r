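# brute-force correlation with replicate padding (nested-loop oracle)
brute_xcorr <- function(img, kern) {
  M <- nrow(img); N <- ncol(img)
  ar <- (nrow(kern) - 1) / 2; ac <- (ncol(kern) - 1) / 2
  out <- matrix(0, M, N)
  for (y in 1:M) for (x in 1:N) {
    acc <- 0
    for (i in seq_len(nrow(kern))) for (j in seq_len(ncol(kern))) {
      yy <- min(max(y + i - ar - 1, 1), M)
      xx <- min(max(x + j - ac - 1, 1), N)
      acc <- acc + kern[i, j] * img[yy, xx]
    }
    out[y, x] <- acc
  }
  out
}

test_that("kernel application equals brute-force correlation/convolution", {
  withr::local_seed(11)
  img <- matrix(runif(12 * 12), 12, 12)
  for (k in list(matrix(runif(9), 3, 3), matrix(runif(25), 5, 5),
                 unclass(build_imt_kernel("far")))) {
    expect_equal(apply_kernel(img, k), brute_xcorr(img, k))
    expect_equal(apply_kernel(img, k, flip = TRUE), brute_xcorr(img, rot180(k)))
  }
  expect_error(apply_kernel(matrix(0, 4, 4), matrix(1, 7, 7)), "larger")
})

test_that("raw feature F equals its brute-force composition", {
  withr::local_seed(3)
  img <- matrix(runif(144), 12, 12)
  fx <- unclass(build_imt_kernel("far"))
  raw <- compute_feature_F(img, fx, macleod_size = 5, normalize = FALSE)
  thetas <- c(0, pi / 4, pi / 2, 3 * pi / 4)
  expected <- Reduce(`+`, lapply(thetas, function(th) {
    abs(brute_xcorr(img, unclass(build_macleod(5, 2, 2, th))))
  })) + brute_xcorr(img, fx)
  expect_equal(unclass(raw), expected, ignore_attr = TRUE)
})

test_that("feature maps obey the [0, 1] contract and degenerate guard", {
  withr::local_seed(5)
  for (i in 1:5) {
    img <- matrix(runif(100), 10, 10)
    f <- compute_feature_F(img, unclass(build_imt_kernel("near")),
                           macleod_size = 5)
    expect_gte(min(f), 0)
    expect_lte(max(f), 1)
  }
  # constant ROI: all-zero raw response, normalization guard returns 0.5
  fc <- compute_feature_F(matrix(0.4, 10, 10), NULL, macleod_size = 5)
  expect_true(all(unclass(fc) == 0.5))
  expect_error(compute_feature_F(matrix(2, 10, 10), NULL), "normalized")
})

test_that("F with a zero enhancement kernel equals the MacLeod-only term", {
  withr::local_seed(9)
  img <- matrix(runif(100), 10, 10)
  with_zero <- compute_feature_F(img, matrix(0, 3, 3), macleod_size = 5,
                                 normalize = FALSE)
  without <- compute_feature_F(img, NULL, macleod_size = 5, normalize = FALSE)
  expect_equal(unclass(with_zero), unclass(without), ignore_attr = TRUE)
})

test_that("H is the windowed sub-band mean inside its validity band", {
  M <- 12; N <- 4; r <- 3
  img <- matrix(0, M, N)
  q <- 6
  img[(q + 1):(q + r), 2] <- 1   # bright r rows directly below row q
  H <- compute_feature_H(img, y_outer = 2, r = r)
  expect_equal(H[q, 2], 0)        # 1 - mean(1)
  expect_equal(H[3, 2], 1)        # far above: all-dark window
  # rows at/above y_outer and in the bottom margin keep the neutral value
  expect_true(all(H[1:2, ] == 1))
  expect_true(all(H[(M - r):M, ] == 1))
  # all-dark and all-bright ROIs
  expect_true(all(compute_feature_H(matrix(0, 10, 3), 1, 2)[2:7, ] == 1))
  expect_true(all(compute_feature_H(matrix(1, 10, 3), 1, 2)[2:7, ] == 0))
  expect_error(compute_feature_H(img, 2, r = 12), "r")
  expect_error(compute_feature_H(img, rep(1, 3), 2), "per column")
})

test_that("H differs from 1 only strictly between y_outer and M - r", {
  withr::local_seed(21)
  img <- matrix(runif(20 * 6, 0.2, 0.9), 20, 6)
  yo <- sample(1:6, 6, replace = TRUE)
  H <- compute_feature_H(img, yo, r = 4)
  for (x in 1:6) {
    inside <- seq_len(20) > yo[x] & seq_len(20) < 20 - 4
    expect_true(all(H[!inside, x] == 1))
    expect_true(all(H[inside, x] != 1))
  }
})

test_that("near-wall combination follows 1 - F + cH with normalization", {
  withr::local_seed(2)
  f <- matrix(runif(50), 10, 5)
  h <- matrix(runif(50), 10, 5)
  expect_equal(unclass(combine_near_wall(f, h, c = 0)),
               normalize01(1 - f), ignore_attr = TRUE)
  # degenerate: F = 0, H = 1 everywhere -> constant -> 0.5 guard
  expect_true(all(combine_near_wall(matrix(0, 4, 4), matrix(1, 4, 4)) == 0.5))
  expect_error(combine_near_wall(f, matrix(0, 3, 3)), "shape")
})

test_that("the H term sharpens near-wall evidence under sub-intima clutter", {
  cfg <- phantom_config()
  phn <- generate_sequence(noise_layer_config(cfg))
  roi <- default_roi(phn, "lumen")
  h <- split_roi(roi)$near
  fx <- -unclass(build_imt_kernel("far"))
  hits <- function(costmap, ti, ta) {
    n <- 0
    for (x in seq_len(ncol(costmap))) {
      v <- costmap[, x]
      locmin <- which(diff(sign(diff(v))) > 0) + 1
      if (length(locmin) < 2) next
      best2 <- locmin[order(v[locmin])][1:2]
      if (min(abs(best2 - ti[x])) <= 1 && min(abs(best2 - ta[x])) <= 1)
        n <- n + 1
    }
    n
  }
  n_comb <- 0; n_plain <- 0
  for (fr in systolic_frames(cfg)[c(3, 5, 7)]) {
    I <- normalize01(phn$frames[[fr]][h$y0 + seq_len(h$height) - 1,
                                      h$x0 + seq_len(h$width) - 1])
    Fm <- compute_feature_F(I, fx)
    yo <- run_single_dp(1 - normalize01(apply_kernel(I, build_outer_kernel())))
    comb <- combine_near_wall(Fm, compute_feature_H(I, yo, 5), 0.5)
    tru <- dplyr::filter(phn$truth, frame == fr, wall == "near",
                         column >= h$x0, column <= h$x0 + h$width - 1)
    tru <- tru[order(tru$column), ]
    ti <- tru$intima_row - h$y0 + 1
    ta <- tru$adventitia_row - h$y0 + 1
    n_comb <- n_comb + hits(unclass(comb), ti, ta)
    n_plain <- n_plain + hits(1 - unclass(Fm), ti, ta)
  }
  expect_gt(n_comb, n_plain)
})

test_that("column argmax of far-wall F tracks the true interfaces", {
  ph <- generate_sequence(tiny_phantom_config(speckle_scale = 0, n_frames = 2))
  roi <- default_roi(ph, "imt_far", margin = 6)
  I <- normalize01(ph$frames[[1]][roi$y0 + seq_len(roi$height) - 1,
                                  roi$x0 + seq_len(roi$width) - 1])
  Fm <- compute_feature_F(I, unclass(build_imt_kernel("far")))
  am <- apply(unclass(Fm), 2, which.max)
  tru <- dplyr::filter(ph$truth, frame == 1, wall == "far",
                       column >= roi$x0, column <= roi$x0 + roi$width - 1)
  tru <- tru[order(tru$column), ]
  near_either <- pmin(abs(am - (tru$intima_row - roi$y0 + 1)),
                      abs(am - (tru$adventitia_row - roi$y0 + 1)))
  expect_lte(max(near_either), 1)
})
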