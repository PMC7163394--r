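# Independent oracles: deliberately naive implementations used only to
# check the package's optimized code paths.

# Build an intake_profile directly from (t, y) vectors.
make_profile <- function(t, y, bw = 50, interval = t[2] - t[1],
                         goat_id = "GX", period = 1, day = 1) {
  structure(list(t = t, y = y, bw = bw, dm_fraction = 1, interval = interval,
                 total_window = length(t) * interval,
                 goat_id = goat_id, breed = "Alpine", period = period, day = day),
            class = "intake_profile")
}

# Least-squares line SSE by the direct covariance formula.
oracle_line_sse <- function(t, y) {
  if (length(t) < 2) stop("need >= 2 points")
  b <- stats::cov(t, y) / stats::var(t)
  if (!is.finite(b)) b <- 0
  a <- mean(y) - b * mean(t)
  sum((y - a - b * t)^2)
}

# Exhaustive minimum of sum(SSE) + penalty * (#change-points), enumerating
# every composition of the series into segments of >= min_len samples by
# plain tree recursion (no memoization). Per-segment costs are tabulated
# once with the naive covariance formula; the enumeration itself only
# sums table lookups.
oracle_best_segmentation_cost <- function(t, y, penalty, min_len = 2L) {
  n <- length(y)
  C <- matrix(Inf, n, n)
  for (i in 1:(n - min_len + 1L))
    for (j in (i + min_len - 1L):n)
      C[i, j] <- oracle_line_sse(t[i:j], y[i:j])
  rec <- function(start) {
    best <- Inf
    for (end in (start + min_len - 1L):n) {
      rest <- n - end
      if (rest != 0L && rest < min_len) next
      cost <- C[start, end] + if (rest == 0L) 0 else penalty + rec(end + 1L)
      if (cost < best) best <- cost
    }
    best
  }
  rec(1L)
}

# Optimal 1-D k-clustering total within-cluster SSE by dynamic programming
# over the sorted values (optimal 1-D clusters are contiguous).
oracle_kmeans1d_sse <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  cx <- c(0, cumsum(x)); cx2 <- c(0, cumsum(x^2))
  sse <- function(i, j) {
    m <- j - i + 1
    s <- cx[j + 1] - cx[i]
    max(0, cx2[j + 1] - cx2[i] - s^2 / m)
  }
  D <- matrix(Inf, k, n)
  for (j in 1:n) D[1, j] <- sse(1, j)
  if (k > 1) for (q in 2:k) for (j in q:n)
    D[q, j] <- min(vapply(q:j, function(i) D[q - 1, i - 1] + sse(i, j), numeric(1)))
  D[k, n]
}

# Dense two-stage grid search over (a, b) minimizing the RMSE of the
# exponential intake model on a profile.
oracle_grid_rmse <- function(profile, zoom = 2) {
  t <- profile$t; y <- profile$y
  rmse <- function(a, b) sqrt(mean((y - a * (1 - exp(-b * t)))^2))
  a_grid <- seq(0.7, 1.3, length.out = 101) * max(y)
  b_grid <- exp(seq(log(1e-4), log(0.3), length.out = 161))
  best <- c(Inf, NA, NA)
  for (z in seq_len(zoom)) {
    for (a in a_grid) for (b in b_grid) {
      r <- rmse(a, b)
      if (r < best[1]) best <- c(r, a, b)
    }
    a_grid <- seq(0.97, 1.03, length.out = 61) * best[2]
    b_grid <- seq(0.9, 1.1, length.out = 61) * best[3]
  }
  best[1]
}

# Sequential sums of squares through R's own linear-model machinery with
# term order preserved.
oracle_seq_ss <- function(formula, data) {
  tt <- terms(formula, keep.order = TRUE)
  stats::anova(stats::lm(tt, data = data))
}
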