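# Brute-force SSE grid-search oracles, independent of the closed-form /
# lm-based fitting code they check. Coarse-to-fine refinement: each pass
# lays a uniform grid over the current parameter box, evaluates the sum of
# squared errors at every node, and zooms into a window of +/- 2 grid steps
# around the best node.
#
# The full line is searched in centred coordinates (slope b, level-at-mean
# a0), where SSE(b, a0) = sum((y - a0 - b*(x - xbar))^2) is orthogonal in
# the two parameters, so the refinement cannot fall off the diagonal valley
# that the raw (slope, intercept) surface has. The reported intercept is
# a0 - b*xbar, with its resolution widened accordingly.

grid_search_line <- function(x, y, n_grid = 61, passes = 6,
                             slope_range = c(-50, 50), level_range = NULL) {
  xbar <- mean(x)
  xc <- x - xbar
  if (is.null(level_range)) {
    spread <- max(diff(range(y)), 1)
    level_range <- c(min(y) - spread, max(y) + spread)
  }
  for (p in seq_len(passes)) {
    bs <- seq(slope_range[1], slope_range[2], length.out = n_grid)
    as <- seq(level_range[1], level_range[2], length.out = n_grid)
    sse <- matrix(NA_real_, n_grid, n_grid)
    for (i in seq_len(n_grid)) {
      r <- y - bs[i] * xc
      for (j in seq_len(n_grid)) sse[i, j] <- sum((r - as[j])^2)
    }
    idx <- arrayInd(which.min(sse), dim(sse))
    b_step <- bs[2] - bs[1]
    a_step <- as[2] - as[1]
    best_b <- bs[idx[1]]
    best_a0 <- as[idx[2]]
    slope_range <- c(best_b - 2 * b_step, best_b + 2 * b_step)
    level_range <- c(best_a0 - 2 * a_step, best_a0 + 2 * a_step)
  }
  list(slope = best_b, intercept = best_a0 - best_b * xbar,
       slope_resolution = b_step,
       intercept_resolution = a_step + b_step * abs(xbar))
}

grid_search_origin <- function(x, y, n_grid = 201, passes = 5,
                               slope_range = c(-50, 50)) {
  for (p in seq_len(passes)) {
    bs <- seq(slope_range[1], slope_range[2], length.out = n_grid)
    sse <- vapply(bs, function(b) sum((y - b * x)^2), numeric(1))
    best_b <- bs[which.min(sse)]
    step <- bs[2] - bs[1]
    slope_range <- c(best_b - 2 * step, best_b + 2 * step)
  }
  list(slope = best_b, slope_resolution = step)
}
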