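## Penalized piecewise-linear segmentation of cumulative intake curves,
## slope clustering into ordered classes, and the first-meal rule.

## Exact optimal partitioning by dynamic programming. Each segment is an
## independent least-squares line; total cost = sum of segment SSEs +
## penalty * (number of change-points). Returns segment end indices.
seg_dp <- function(t, y, penalty, min_len = 2L) {
  n <- length(y)
  if (n < min_len) stop_domain("segmentation: series shorter than min_len")
  ct <- c(0, cumsum(t));      cy <- c(0, cumsum(y))
  ctt <- c(0, cumsum(t * t)); cty <- c(0, cumsum(t * y))
  cyy <- c(0, cumsum(y * y))
  F <- c(-penalty, rep(Inf, n))
  ptr <- integer(n)
  for (j in seq_len(n)) {
    if (j < min_len) next
    i <- seq_len(j - min_len + 1L)       # candidate segment starts
    m <- j - i + 1
    St <- ct[j + 1] - ct[i];   Sy <- cy[j + 1] - cy[i]
    Stt <- ctt[j + 1] - ctt[i]; Sty <- cty[j + 1] - cty[i]
    Syy <- cyy[j + 1] - cyy[i]
    sxx <- Stt - St * St / m
    sxy <- Sty - St * Sy / m
    syy <- Syy - Sy * Sy / m
    sse <- pmax(syy - ifelse(sxx > 0, sxy * sxy / sxx, 0), 0)
    cand <- F[i] + penalty + sse
    best <- which.min(cand)
    F[j + 1] <- cand[best]
    ptr[j] <- best
  }
  ends <- integer(0)
  e <- n
  while (e > 0) {
    ends <- c(e, ends)
    e <- ptr[e] - 1L
  }
  k <- length(ends)
  list(ends = ends, cost = F[n + 1], rss = F[n + 1] - penalty * (k - 1), k = k)
}

seg_line <- function(t, y) {
  # least-squares line through (t, y); slope 0 for degenerate spread
  mt <- mean(t); my <- mean(y)
  sxx <- sum((t - mt)^2)
  slope <- if (sxx > 0) sum((t - mt) * (y - my)) / sxx else 0
  c(slope = slope, intercept = my - slope * mt)
}

#' Segment a cumulative intake profile by slope change-points
#'
#' Cuts the curve into contiguous linear segments by exact penalized
#' least-squares change-point detection, solved by dynamic programming
#' (every segment is an independent least-squares line; the objective is
#' the total squared error plus `penalty` per change-point, minimized
#' globally). When `penalty` is `NULL`, the segmentation is computed for
#' each value of `penalty_grid` and the one minimizing a BIC-type score
#' `n log(RSS/n) + (3k - 1) log(n)` (slope, intercept and boundary per
#' segment) is returned. Segments tile the half-open window, so their
#' intakes sum exactly to the intake at the window end.
#'
#' @param profile an `intake_profile` (normally the 900-min clip).
#' @param penalty positive penalty per change-point, in squared
#'   g DM/kg BW; `NULL` (default) selects it from `penalty_grid` by BIC.
#' @param penalty_grid candidate penalties for BIC selection.
#' @param min_len minimum segment length in samples.
#' @return data.frame of class `segmentation` with one row per segment:
#'   `t_start`, `t_end` (half-open, min), `duration`, `n`, `slope`
#'   (g DM/kg BW per min), `intake` (g DM/kg BW gained over the segment).
#'   Attributes `penalty`, `rss` and `cost` record the fit.
#' @export
segment_profile <- function(profile, penalty = NULL,
                            penalty_grid = c(0.01, 0.05, 0.2, 1, 5, 25),
                            min_len = 2L) {
  stopifnot(inherits(profile, "intake_profile"))
  t <- profile$t; y <- profile$y; n <- length(y)
  if (!is.null(penalty)) {
    if (length(penalty) != 1 || penalty <= 0)
      stop_domain("segment_profile: penalty must be a single positive number")
    sol <- seg_dp(t, y, penalty, min_len)
    used <- penalty
  } else {
    if (any(penalty_grid <= 0))
      stop_domain("segment_profile: penalties must be positive")
    sols <- lapply(penalty_grid, function(p) seg_dp(t, y, p, min_len))
    bic <- vapply(sols, function(s)
      n * log(max(s$rss, 1e-12) / n) + (3 * s$k - 1) * log(n), numeric(1))
    ks <- vapply(sols, `[[`, integer(1), "k")
    pick <- order(bic, ks)[1]        # ties -> fewer segments
    sol <- sols[[pick]]
    used <- penalty_grid[pick]
  }
  starts <- c(1L, utils::head(sol$ends, -1) + 1L)
  seg <- do.call(rbind, lapply(seq_along(starts), function(s) {
    i <- starts[s]:sol$ends[s]
    ln <- seg_line(t[i], y[i])
    # intake = y(t_end) - y(t_start): the curve is read at the segment
    # boundaries, i.e. at the next segment's first sample (the last sample
    # for the final segment), so intakes telescope exactly to y[n] - y[1]
    y_end <- if (sol$ends[s] < n) y[sol$ends[s] + 1] else y[n]
    data.frame(
      t_start = t[starts[s]],
      t_end = if (sol$ends[s] < n) t[sol$ends[s] + 1] else t[n] + profile$interval,
      n = length(i), slope = ln[["slope"]], intercept = ln[["intercept"]],
      intake = y_end - y[starts[s]])
  }))
  seg$duration <- seg$t_end - seg$t_start
  attr(seg, "penalty") <- used
  attr(seg, "rss") <- sol$rss
  attr(seg, "cost") <- sol$cost
  class(seg) <- c("segmentation", "data.frame")
  seg
}

#' Fit an ordered slope-cluster model
#'
#' Classifies segment slopes into `k` ordered clusters by one-dimensional
#' k-means (seeded, multi-start), relabeled by increasing centroid so that
#' cluster `k` holds the fastest eating rates and cluster 1 slopes near
#' zero (no intake). With fewer than `k` distinct slopes the model falls
#' back to quantile boundaries with a warning.
#'
#' @param slopes numeric vector of segment slopes, usually pooled over all
#'   profiles of a dataset so labels are comparable across animals.
#' @param k number of clusters.
#' @param seed integer seed for the k-means starts.
#' @return object of class `slope_clusters`: list with increasing
#'   `centers`, the assignment `boundaries` (midpoints), `k` and `method`.
#' @export
fit_cluster_model <- function(slopes, k = 8, seed = 1) {
  slopes <- slopes[is.finite(slopes)]
  if (!length(slopes)) stop_domain("fit_cluster_model: no finite slopes")
  distinct <- sort(unique(slopes))
  if (length(distinct) < k) {
    warning("fewer distinct slopes than clusters; falling back to quantile boundaries")
    centers <- stats::quantile(slopes, probs = (2 * seq_len(k) - 1) / (2 * k),
                               names = FALSE, type = 7)
    method <- "quantile"
  } else {
    centers <- with_seed(substream_seed(seed, "kmeans"), {
      km <- stats::kmeans(slopes, centers = k, nstart = 25, iter.max = 200)
      as.numeric(km$centers)
    })
    method <- "kmeans"
  }
  centers <- sort(centers)
  boundaries <- (utils::head(centers, -1) + utils::tail(centers, -1)) / 2
  structure(list(centers = centers, boundaries = boundaries, k = k,
                 method = method),
            class = "slope_clusters")
}

#' @export
print.slope_clusters <- function(x, ...) {
  cat("Slope clusters (", x$method, "), centers 1..", x$k, ":\n  ",
      paste(sprintf("%.4f", x$centers), collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' Assign segments to slope clusters
#'
#' Nearest-centroid assignment via the model's interval boundaries; a
#' slope exactly on a boundary goes to the lower cluster (the
#' conservative choice for meal continuation). Labels run 1 (slowest) to
#' `k` (fastest) and do not depend on segment order.
#'
#' @param segments a `segmentation` data.frame (or any data.frame with a
#'   `slope` column).
#' @param model a `slope_clusters` model.
#' @return `segments` with an integer `cluster` column added.
#' @export
assign_clusters <- function(segments, model) {
  stopifnot(inherits(model, "slope_clusters"))
  need_cols(segments, "slope", "segments")
  segments$cluster <- findInterval(segments$slope, model$boundaries,
                                   left.open = TRUE) + 1L
  segments
}

#' First meal after feed delivery
#'
#' Scans labeled segments in time order, accumulating the intake of
#' eating segments (cluster 3 and above) until the first near-zero-slope
#' segment (cluster 1 or 2) lasting at least `min_pause` minutes; shorter
#' pauses do not end the meal, so bouts separated by brief interruptions
#' are merged. If no qualifying pause exists the meal extends to the end
#' of the window and is flagged (`complete = FALSE`).
#'
#' When the `profile` is supplied, the intake of each contiguous run of
#' eating segments is read off the cumulative curve just outside the run
#' boundaries (the sample before the run starts and the first sample of
#' the following segment). A change-point tied within one sample of a
#' true bout boundary then still yields the exact bout intake, because
#' the neighbouring segments are flat. Without the profile the
#' segment-table intakes are summed, which can leak up to one sample of
#' intake per boundary into an adjacent flat segment.
#'
#' @param segments a `segmentation` data.frame with a `cluster` column
#'   (see [assign_clusters()]).
#' @param min_pause minimum pause duration in minutes ending a meal.
#' @param profile optional `intake_profile` the segments were fitted on.
#' @return object of class `meal_result`: list with `first_meal_end`
#'   (min), `first_meal_intake` (g DM/kg BW), `n_segments_in_meal` and
#'   `complete`.
#' @export
first_meal <- function(segments, min_pause = 30, profile = NULL) {
  need_cols(segments, c("t_start", "t_end", "duration", "intake"), "segments")
  if (is.null(segments$cluster) || anyNA(segments$cluster))
    stop_domain("first_meal: segments must carry cluster labels; run assign_clusters()")
  seg <- segments[order(segments$t_start), , drop = FALSE]
  stop_at <- which(seg$cluster <= 2 & seg$duration >= min_pause)
  complete <- length(stop_at) > 0
  last <- if (complete) stop_at[1] - 1L else nrow(seg)
  eating <- which(seq_len(nrow(seg)) <= last & seg$cluster >= 3)
  if (!length(eating)) {
    end <- if (complete) seg$t_start[stop_at[1]] else 0
    return(structure(list(first_meal_end = end, first_meal_intake = 0,
                          n_segments_in_meal = 0L, complete = complete),
                     class = "meal_result"))
  }
  runs <- split(eating, cumsum(c(1, diff(eating) != 1)))
  if (is.null(profile)) {
    intake <- sum(seg$intake[eating])
  } else {
    y <- profile$y
    read_at <- function(tv) {           # curve value at a segment boundary
      i <- which(profile$t >= tv - 1e-9)
      if (length(i)) y[i[1]] else y[length(y)]
    }
    intake <- sum(vapply(runs, function(r) {
      lo <- seg$t_start[r[1]] - profile$interval      # sample before the run
      hi <- seg$t_end[r[length(r)]]                   # next segment's first sample
      read_at(hi) - if (lo < profile$t[1]) y[1] else read_at(lo)
    }, numeric(1)))
  }
  end <- seg$t_end[eating[length(eating)]]
  structure(list(first_meal_end = end, first_meal_intake = intake,
                 n_segments_in_meal = length(eating), complete = complete),
            class = "meal_result")
}
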