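#' Dual dynamic-programming configuration
#'
#' Constraint set for the dual-curve optimizer: per-column step bound `k`,
#' separation band `[d_min, d_max]` between the two curves, smoothness
#' weights `alpha` (dual-line change, the thickness smoothness) and `beta`
#' (single-line steps), and the cost orientation.
#'
#' @param alpha weight (>= 0) on `|j2 - j1|`, the per-column change of the
#'   inter-line distance.
#' @param beta weight (>= 0) on `|j1| + |j2|`, the per-line step sizes.
#' @param k maximum per-column row step, pixels (>= 1).
#' @param d_min,d_max minimum/maximum separation `y2 - y1`, pixels,
#'   `0 <= d_min <= d_max`.
#' @param orientation `"minimize_cost"` (map is a cost surface) or
#'   `"maximize_feature"` (map is boundary evidence; it is flipped to
#'   `1 - map` internally).
#' @return A `ddp_config` list.
#' @export
ddp_config <- function(alpha = 0.3, beta = 0.15, k = 1, d_min = 4, d_max = 40,
                       orientation = c("minimize_cost", "maximize_feature")) {
  orientation <- match.arg(orientation)
  if (alpha < 0 || beta < 0) abort("`alpha` and `beta` must be >= 0")
  if (k < 1) abort("`k` must be >= 1")
  if (d_min < 0 || d_max < d_min) abort("require 0 <= d_min <= d_max")
  structure(list(alpha = alpha, beta = beta, k = as.integer(k),
                 d_min = as.integer(d_min), d_max = as.integer(d_max),
                 orientation = orientation),
            class = "ddp_config")
}

#' Transition penalty matrix
#'
#' Entry `(j1, j2)` (offsets of the upper and lower curve, each in
#' `-k ... k`) equals `alpha * |j2 - j1| + beta * (|j1| + |j2|)`: for
#' curves moving jointly the inter-line change is `|j2 - j1|`.  For
#' `k = 1` this is the familiar 3 x 3 arrangement with `0` at the centre,
#' `2 * beta` on the main-diagonal corners and `2 * (alpha + beta)` on the
#' anti-diagonal corners.
#'
#' @param alpha,beta smoothness weights (see [ddp_config()]).
#' @param k maximum per-column step, pixels.
#' @return A `(2k + 1) x (2k + 1)` matrix with `dimnames` giving `j1`
#'   (rows) and `j2` (columns).
#' @export
penalty_matrix <- function(alpha, beta, k = 1) {
  if (k < 1) abort("`k` must be >= 1")
  j <- seq(-k, k)
  m <- outer(j, j, function(j1, j2) alpha * abs(j2 - j1) + beta * (abs(j1) + abs(j2)))
  dimnames(m) <- list(j1 = j, j2 = j)
  m
}

#' Extract two constrained curves by dual dynamic programming
#'
#' Finds the pair of non-crossing curves `y1(x) <= y2(x)` minimizing
#' `sum_x [cost(x, y1) + cost(x, y2)] + sum_x [alpha * |j2 - j1| +
#' beta * (|j1| + |j2|)]` subject to `d_min <= y2 - y1 <= d_max` and
#' per-column steps of at most `k` rows, by exact forward recursion and
#' backtracking through predecessor tables.  Tie-breaking is
#' deterministic: equal-cost predecessors prefer `(0, 0)`, then smallest
#' `|j1| + |j2|`, then lexicographic `(j1, j2)`; equal-cost terminal
#' states prefer the smallest `(y1, y2)` lexicographically.
#'
#' @param cost_map numeric matrix (rows x columns), finite values; with
#'   `orientation = "maximize_feature"` in `config` the map is flipped to
#'   `1 - cost_map` first.
#' @param config a [ddp_config()].
#' @param tables also return the full `J`/`C1`/`C2` tables (arrays indexed
#'   `[y1, y2, x]`).
#' @return A `cawall_ddp` object: integer row traces `y1`, `y2` (length =
#'   number of columns), `total_cost`, the `config`, and optionally
#'   `tables`.
#' @export
run_ddp <- function(cost_map, config = ddp_config(), tables = FALSE) {
  m <- unclass(cost_map)
  if (!is.matrix(m)) abort("`cost_map` must be a matrix")
  if (any(!is.finite(m))) abort("`cost_map` contains non-finite values")
  if (config$orientation == "maximize_feature") m <- 1 - m
  res <- ddp_core(m, config$k, config$d_min, config$d_max,
                  config$alpha, config$beta, tables)
  out <- list(y1 = as.integer(res$y1), y2 = as.integer(res$y2),
              total_cost = res$total_cost, config = config)
  if (tables) out$tables <- res[c("J", "C1", "C2")]
  structure(out, class = "cawall_ddp")
}

#' Extract a single curve (degenerate dual programming)
#'
#' Runs [run_ddp()] with the degenerate separation band `[0, 1]` and
#' `k = 1`, returning the upper curve.  Used for the outer-wall line of
#' the near-wall phase.
#'
#' @inheritParams run_ddp
#' @param alpha,beta smoothness weights.
#' @return Integer row per column.
#' @export
run_single_dp <- function(cost_map, alpha = 0.3, beta = 0.15,
                          orientation = "minimize_cost") {
  cfg <- ddp_config(alpha = alpha, beta = beta, k = 1, d_min = 0, d_max = 1,
                    orientation = orientation)
  run_ddp(cost_map, cfg)$y1
}

#' @export
print.cawall_ddp <- function(x, ...) {
  cat(sprintf("<cawall_ddp> %d columns, total cost %.4f, separation [%d, %d]\n",
              length(x$y1), x$total_cost, x$config$d_min, x$config$d_max))
  invisible(x)
}

#' @describeIn run_ddp Tidy a trace into a tibble with one row per column.
#' @param x a `cawall_ddp` object.
#' @param ... unused.
#' @export
tidy.cawall_ddp <- function(x, ...) {
  tibble(column = seq_along(x$y1), y1 = x$y1, y2 = x$y2)
}
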