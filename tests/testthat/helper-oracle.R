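# Exhaustive dual-path enumeration, independent of the DP recurrence: every
# partial path is kept explicitly (no collapsing by state), so the minimum
# is a true enumeration over all feasible dual paths.

oracle_feasible <- function(y1, y2, M, d_min, d_max) {
  y1 >= 1 & y2 <= M & y1 <= y2 & (y2 - y1) >= d_min & (y2 - y1) <= d_max
}

oracle_min_cost <- function(cost, k, d_min, d_max, alpha, beta) {
  M <- nrow(cost); N <- ncol(cost)
  pairs <- expand.grid(y1 = seq_len(M), y2 = seq_len(M))
  pairs <- pairs[oracle_feasible(pairs$y1, pairs$y2, M, d_min, d_max), ]
  if (nrow(pairs) == 0) stop("no feasible state")
  Y1 <- pairs$y1; Y2 <- pairs$y2
  C <- cost[cbind(Y1, 1)] + cost[cbind(Y2, 1)]
  offs <- expand.grid(j1 = seq(-k, k), j2 = seq(-k, k))
  pen <- alpha * abs(offs$j2 - offs$j1) + beta * (abs(offs$j1) + abs(offs$j2))
  for (x in 2:N) {
    nY1 <- rep(Y1, times = nrow(offs)) + rep(offs$j1, each = length(Y1))
    nY2 <- rep(Y2, times = nrow(offs)) + rep(offs$j2, each = length(Y1))
    nC <- rep(C, times = nrow(offs)) + rep(pen, each = length(Y1))
    keep <- oracle_feasible(nY1, nY2, M, d_min, d_max)
    Y1 <- nY1[keep]; Y2 <- nY2[keep]
    C <- nC[keep] + cost[cbind(Y1, x)] + cost[cbind(Y2, x)]
  }
  min(C)
}

# recompute the cost of a given dual trace (independent R implementation)
# and assert its feasibility under the constraint set
trace_cost <- function(cost, y1, y2, k, d_min, d_max, alpha, beta) {
  M <- nrow(cost); N <- ncol(cost)
  stopifnot(length(y1) == N, length(y2) == N)
  stopifnot(all(oracle_feasible(y1, y2, M, d_min, d_max)))
  if (N > 1) {
    j1 <- diff(y1); j2 <- diff(y2)
    stopifnot(all(abs(j1) <= k), all(abs(j2) <= k))
    pen <- sum(alpha * abs(j2 - j1) + beta * (abs(j1) + abs(j2)))
  } else pen <- 0
  sum(cost[cbind(y1, seq_len(N))] + cost[cbind(y2, seq_len(N))]) + pen
}

# single-curve enumeration (twin-path construction oracle for run_single_dp):
# y2 in {y1, y1 + 1}, as the degenerate dual band [0, 1] allows
oracle_single_min_cost <- function(cost, alpha, beta) {
  oracle_min_cost(cost, k = 1, d_min = 0, d_max = 1, alpha = alpha, beta = beta)
}

expect_valid_dual_trace <- function(dd, cost, cfg) {
  M <- nrow(cost)
  expect_true(all(dd$y1 >= 1 & dd$y2 <= M))
  expect_true(all(dd$y1 <= dd$y2))
  expect_true(all(dd$y2 - dd$y1 >= cfg$d_min))
  expect_true(all(dd$y2 - dd$y1 <= cfg$d_max))
  if (length(dd$y1) > 1) {
    expect_true(all(abs(diff(dd$y1)) <= cfg$k))
    expect_true(all(abs(diff(dd$y2)) <= cfg$k))
  }
}
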