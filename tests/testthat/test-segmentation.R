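# Change-point segmentation, slope clustering and the first-meal rule.

test_that("an exact two-piece curve is cut at the true breakpoint", {
  tt <- seq(0, 898, 2)
  y <- 0.5 * pmin(tt, 300)
  for (pen in c(0.1, 1, 10)) {
    seg <- segment_profile(make_profile(tt, y), penalty = pen)
    expect_equal(nrow(seg), 2)
    expect_lte(abs(seg$t_start[2] - 300), 2)  # kink sample may tie either side
    expect_equal(seg$slope, c(0.5, 0), tolerance = 1e-9)
  }
  # BIC default also finds it
  seg <- segment_profile(make_profile(tt, y))
  expect_equal(nrow(seg), 2)
})

test_that("a constant curve is one zero-slope segment", {
  tt <- seq(0, 198, 2)
  seg <- segment_profile(make_profile(tt, rep(5, length(tt))), penalty = 1)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$slope, 0)
  expect_equal(seg$intake, 0)
  expect_equal(seg$t_start, 0)
  expect_equal(seg$t_end, 200)
})

test_that("dynamic programming equals exhaustive search on small grids", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(8:16, 1)
    tt <- seq(0, by = 2, length.out = n)
    k <- sample(1:3, 1)
    bp <- sort(sample(seq(2, n - 2, by = 2), k - 1))
    slopes <- runif(k, 0, 1)
    y <- numeric(n); cur <- 0; prev <- 1
    for (s in seq_len(k)) {
      end <- if (s < k) bp[s] else n
      idx <- prev:end
      y[idx] <- cur + slopes[s] * (seq_along(idx) - 1) * 2
      cur <- y[end]; prev <- end + 1
    }
    y <- y + rnorm(n, 0, 0.3)
    pen <- runif(1, 0.05, 5)
    p <- make_profile(tt, y)
    seg <- segment_profile(p, penalty = pen)
    expect_equal(attr(seg, "cost"),
                 oracle_best_segmentation_cost(tt, y, pen),
                 tolerance = 1e-8)
  }
})

test_that("segment intakes tile the window and sum to the final value", {
  set.seed(3)
  tt <- seq(0, 898, 2)
  y <- cummax(cumsum(rnorm(length(tt), 0.03, 0.05)))
  y <- y - y[1]
  seg <- segment_profile(make_profile(tt, y))
  expect_equal(seg$t_start[1], 0)
  expect_equal(seg$t_end[nrow(seg)], 900)
  expect_equal(seg$t_start[-1], seg$t_end[-nrow(seg)])   # no gaps or overlap
  expect_equal(sum(seg$intake), y[length(y)])
  expect_error(segment_profile(make_profile(tt, y), penalty = -1), "positive")
})

test_that("well-separated slope groups are recovered and ordered", {
  set.seed(5)
  truth <- rep(c(0, 0.05, 0.12, 0.2, 0.32, 0.5, 0.7, 1), each = 25)
  slopes <- truth + rnorm(length(truth), 0, 0.004)
  model <- fit_cluster_model(slopes, k = 8, seed = 1)
  expect_true(all(diff(model$centers) > 0))
  lab <- assign_clusters(data.frame(slope = slopes), model)$cluster
  # exact recovery of the 8 groups up to the (increasing) relabeling
  expect_equal(lab, rep(1:8, each = 25))
  # near-zero slopes live in the lowest clusters
  expect_true(all(lab[truth == 0] <= 2))
})

test_that("1-D k-means attains the optimal clustering objective on small inputs", {
  set.seed(19)
  for (rep in 1:5) {
    x <- c(rnorm(6, 0, 0.02), rnorm(6, 0.5, 0.02), rnorm(6, 1.2, 0.02))
    model <- fit_cluster_model(x, k = 3, seed = rep)
    lab <- assign_clusters(data.frame(slope = x), model)$cluster
    obj <- sum(unlist(lapply(split(x, lab), function(g) sum((g - mean(g))^2))))
    expect_equal(obj, oracle_kmeans1d_sse(x, 3), tolerance = 1e-8)
  }
})

test_that("cluster assignment breaks boundary ties downward and ignores order", {
  model <- structure(list(centers = c(0, 1, 2), boundaries = c(0.5, 1.5), k = 3,
                          method = "kmeans"), class = "slope_clusters")
  seg <- data.frame(slope = c(0.5, 1.5, 0.2, 1.9))
  lab <- assign_clusters(seg, model)$cluster
  expect_equal(lab, c(1L, 2L, 1L, 3L))        # exact midpoints go down
  perm <- sample(nrow(seg))
  expect_equal(assign_clusters(seg[perm, , drop = FALSE], model)$cluster,
               lab[perm])
})

test_that("quantile fallback fires when slopes are too few", {
  expect_warning(model <- fit_cluster_model(rep(c(0, 1), 10), k = 8),
                 "quantile")
  expect_equal(model$method, "quantile")
  lab <- assign_clusters(data.frame(slope = c(0, 1)), model)$cluster
  expect_true(all(lab %in% 1:8))
})

mk_segments <- function(t_end, cluster, y_rate = NULL) {
  t_start <- c(0, head(t_end, -1))
  data.frame(t_start = t_start, t_end = t_end,
             duration = t_end - t_start,
             intake = ifelse(cluster >= 3, (t_end - t_start) * 0.4, 0),
             cluster = cluster)
}

test_that("a single bout followed by a long flat tail is one complete meal", {
  seg <- mk_segments(c(60, 900), c(7L, 1L))
  meal <- first_meal(seg)
  expect_true(meal$complete)
  expect_equal(meal$first_meal_intake, 24)
  expect_equal(meal$first_meal_end, 60)
  expect_equal(meal$n_segments_in_meal, 1L)
})

test_that("a 20-min pause does not split a meal but a 30-min pause does", {
  seg <- mk_segments(c(40, 60, 100, 900), c(8L, 1L, 6L, 1L))
  meal <- first_meal(seg, min_pause = 30)
  expect_equal(meal$n_segments_in_meal, 2L)           # both bouts merged
  expect_equal(meal$first_meal_intake, 40 * 0.4 + 40 * 0.4)
  seg2 <- mk_segments(c(40, 70, 110, 900), c(8L, 1L, 6L, 1L))
  meal2 <- first_meal(seg2, min_pause = 30)
  expect_equal(meal2$n_segments_in_meal, 1L)          # 30-min pause ends it
  expect_equal(meal2$first_meal_intake, 16)
})

test_that("first-meal intake is monotone in the minimum pause duration", {
  set.seed(23)
  for (rep in 1:20) {
    k <- sample(3:9, 1)
    t_end <- sort(sample(seq(20, 900, 20), k))
    t_end[k] <- 900
    seg <- mk_segments(t_end, sample(1:8, k, replace = TRUE))
    intakes <- vapply(c(10, 20, 30, 45, 60),
                      function(mp) first_meal(seg, min_pause = mp)$first_meal_intake,
                      numeric(1))
    expect_true(all(diff(intakes) >= -1e-12))
  }
})

test_that("meals without a qualifying pause run to the window end and are flagged", {
  seg <- mk_segments(c(500, 900), c(5L, 4L))
  meal <- first_meal(seg)
  expect_false(meal$complete)
  expect_equal(meal$first_meal_end, 900)
  expect_error(first_meal(mk_segments(c(900), NA)), "cluster")
})
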