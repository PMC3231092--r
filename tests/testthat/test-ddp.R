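test_that("penalty matrix reproduces the k = 1 arrangement", {
  withr::local_seed(4)
  for (i in 1:5) {
    a <- runif(1, 0, 2); b <- runif(1, 0, 2)
    m <- penalty_matrix(a, b, 1)
    expected <- a * matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3) +
      b * matrix(c(2, 1, 2, 1, 0, 1, 2, 1, 2), 3, 3)
    expect_equal(unname(m), expected)
    # corners: main diagonal 2b, anti-diagonal 2(a+b); centre 0
    expect_equal(m[1, 1], 2 * b)
    expect_equal(m[3, 3], 2 * b)
    expect_equal(m[1, 3], 2 * (a + b))
    expect_equal(m[3, 1], 2 * (a + b))
    expect_equal(m[2, 2], 0)
  }
  expect_true(all(penalty_matrix(0, 0, 2) == 0))
  expect_equal(dim(penalty_matrix(1, 1, 2)), c(5, 5))
})

test_that("dual DP equals exhaustive enumeration on random grids", {
  withr::local_seed(100)
  for (i in 1:20) {
    M <- sample(4:5, 1); N <- sample(4:5, 1)
    cost <- matrix(runif(M * N), M, N)
    dmin <- sample(0:2, 1); dmax <- sample(dmin:(M - 1), 1)
    a <- runif(1, 0, 0.6); b <- runif(1, 0, 0.4)
    k <- if (i %% 3 == 0) 2 else 1
    cfg <- ddp_config(a, b, k, dmin, dmax)
    dd <- run_ddp(cost, cfg)
    expect_equal(dd$total_cost, oracle_min_cost(cost, k, dmin, dmax, a, b))
    expect_equal(trace_cost(cost, dd$y1, dd$y2, k, dmin, dmax, a, b),
                 dd$total_cost)
    expect_valid_dual_trace(dd, cost, cfg)
  }
})

test_that("forced-cost constructions recover the expected dual paths", {
  # two zero-cost rows at a feasible separation, a = b = 0
  cost <- matrix(1, 8, 6)
  cost[2, ] <- 0; cost[6, ] <- 0
  dd <- run_ddp(cost, ddp_config(0, 0, 1, d_min = 1, d_max = 5))
  expect_equal(dd$y1, rep(2L, 6))
  expect_equal(dd$y2, rep(6L, 6))
  expect_equal(dd$total_cost, 0)
  # constant map: cost forced to 2 N c0; tie-break picks the smallest
  # terminal state and straight lines
  c0 <- 0.3
  dd2 <- run_ddp(matrix(c0, 6, 5), ddp_config(0, 0, 1, 2, 4))
  expect_equal(dd2$total_cost, 2 * 5 * c0)
  expect_equal(dd2$y1, rep(1L, 5))
  expect_equal(dd2$y2, rep(3L, 5))
})

test_that("maximize_feature orientation flips the map", {
  withr::local_seed(8)
  cost <- matrix(runif(30), 6, 5)
  a <- run_ddp(1 - cost, ddp_config(0.2, 0.1, 1, 1, 4))
  b <- run_ddp(cost, ddp_config(0.2, 0.1, 1, 1, 4,
                                orientation = "maximize_feature"))
  expect_equal(a$y1, b$y1)
  expect_equal(a$y2, b$y2)
  expect_equal(a$total_cost, b$total_cost)
})

test_that("predecessor tables are consistent with the returned trace", {
  withr::local_seed(12)
  cost <- matrix(runif(42), 7, 6)
  cfg <- ddp_config(0.3, 0.1, 1, 1, 5)
  dd <- run_ddp(cost, cfg, tables = TRUE)
  expect_equal(dim(dd$tables$J), c(7, 7, 6))
  expect_equal(min(dd$tables$J[, , 6][is.finite(dd$tables$J[, , 6])]),
               dd$total_cost)
  for (x in 2:6) {
    expect_equal(dd$tables$C1[dd$y1[x], dd$y2[x], x], dd$y1[x - 1])
    expect_equal(dd$tables$C2[dd$y1[x], dd$y2[x], x], dd$y2[x - 1])
  }
})

test_that("increasing alpha stiffens the inter-line distance", {
  withr::local_seed(33)
  for (i in 1:5) {
    cost <- matrix(runif(48), 6, 8)
    alphas <- c(0, 0.2, 0.6, 1.5)
    costs <- numeric(0); wiggles <- numeric(0)
    for (a in alphas) {
      dd <- run_ddp(cost, ddp_config(a, 0.05, 1, 0, 5))
      costs <- c(costs, dd$total_cost)
      wiggles <- c(wiggles, sum(abs(diff(dd$y2 - dd$y1))))
    }
    expect_true(all(diff(costs) >= -1e-12))
    expect_true(all(diff(wiggles) <= 0))
  }
})

test_that("shifting the cost map shifts the optimal trace", {
  withr::local_seed(19)
  cost <- matrix(runif(40, 0.2, 0.8), 8, 5)
  cost[3, ] <- 0; cost[6, ] <- 0
  s <- 4
  shifted <- rbind(matrix(1, s, 5), cost)
  cfg <- ddp_config(0.2, 0.1, 1, 1, 6)
  a <- run_ddp(cost, cfg)
  b <- run_ddp(shifted, cfg)
  expect_equal(b$y1, a$y1 + s)
  expect_equal(b$y2, a$y2 + s)
})

test_that("single-curve DP matches its twin-path enumeration", {
  withr::local_seed(27)
  for (i in 1:10) {
    cost <- matrix(runif(48), 6, 8)
    y <- run_single_dp(cost, alpha = 0.2, beta = 0.1)
    expect_equal(run_ddp(cost, ddp_config(0.2, 0.1, 1, 0, 1))$total_cost,
                 oracle_single_min_cost(cost, 0.2, 0.1))
    expect_true(all(abs(diff(y)) <= 1))
  }
  # a single zero-cost row is recovered exactly
  cost <- matrix(1, 7, 6); cost[4, ] <- 0
  expect_equal(run_single_dp(cost), rep(4L, 6))
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(run_ddp(matrix(1, 5, 1), ddp_config()), "2 columns")
  expect_error(run_ddp(matrix(c(1, Inf, 1, 1), 2, 2),
                       ddp_config(d_min = 0, d_max = 1)), "finite")
  expect_error(run_ddp(matrix(1, 3, 4), ddp_config(d_min = 4, d_max = 8)),
               "d_min")
  expect_error(ddp_config(d_min = 3, d_max = 2), "d_min")
  expect_error(ddp_config(alpha = -1), "alpha")
})
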