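## Reading trough-weight recordings and converting them into clean,
## monotone cumulative intake profiles scaled to body weight.

trough_cols <- c("goat_id", "period", "day", "t_min", "weight_g")

## Validate a long trough table; returns a data.frame of violations
## (possibly empty) with columns cell, issue.
validate_trough <- function(df, interval = NULL, max_gap = 3) {
  need_cols(df, trough_cols, "trough table")
  issues <- list()
  add <- function(cell, issue) issues[[length(issues) + 1]] <<-
    data.frame(cell = cell, issue = issue, stringsAsFactors = FALSE)
  keys <- interaction(df$goat_id, df$period, df$day, drop = TRUE)
  for (k in levels(keys)) {
    s <- df[keys == k, , drop = FALSE]
    cell <- sprintf("goat %s period %s day %s", s$goat_id[1], s$period[1], s$day[1])
    if (anyNA(s$t_min) || anyNA(s$weight_g)) {
      add(cell, "missing t_min or weight_g values"); next
    }
    if (any(s$weight_g < 0))
      add(cell, sprintf("negative weight at t_min %s",
                        paste(s$t_min[s$weight_g < 0][1:min(3, sum(s$weight_g < 0))],
                              collapse = ", ")))
    if (anyDuplicated(s$t_min))
      add(cell, sprintf("duplicated t_min %s", s$t_min[duplicated(s$t_min)][1]))
    tt <- sort(unique(s$t_min))
    if (length(tt) >= 2) {
      dt <- diff(tt)
      step <- interval %||% min(dt)
      if (any(abs(dt / step - round(dt / step)) > 1e-8)) {
        add(cell, "irregular sampling grid")
      } else if (any(round(dt / step) - 1 > max_gap)) {
        add(cell, sprintf("gap of %d samples exceeds max_gap = %d",
                          max(round(dt / step) - 1), max_gap))
      }
    }
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(cell = character(0), issue = character(0), stringsAsFactors = FALSE)
}

#' Read trough-weight recordings
#'
#' Reads a long-format CSV (or takes an equivalent data.frame) of trough
#' weights with columns `goat_id`, `period`, `day`, `t_min` (minutes since
#' the afternoon feed delivery) and `weight_g` (g as-fed); a `breed` column
#' is carried through when present. Each goat x period x day series is
#' validated: duplicated timestamps, negative weights and irregular grids
#' are collected and reported as an error naming the offending cells.
#' Gaps of up to `max_gap` missing samples are filled by linear
#' interpolation; longer gaps are a validation error (such goat-days
#' should be excluded upstream).
#'
#' @param path CSV file path, or a data.frame already in memory.
#' @param max_gap maximum run of missing samples to interpolate.
#' @param interval expected sampling interval in minutes (default: inferred
#'   per series as the smallest time step).
#' @return a long data.frame sorted by goat, period, day and time, with any
#'   interpolated samples filled in.
#' @export
read_trough_series <- function(path, max_gap = 3, interval = NULL) {
  df <- if (is.data.frame(path)) path else utils::read.csv(path, stringsAsFactors = FALSE)
  problems <- validate_trough(df, interval = interval, max_gap = max_gap)
  if (nrow(problems))
    stop_domain("invalid trough recordings:\n",
                paste(sprintf("  %s: %s", problems$cell, problems$issue)[
                  seq_len(min(10, nrow(problems)))], collapse = "\n"))
  keys <- interaction(df$goat_id, df$period, df$day, drop = TRUE)
  out <- lapply(levels(keys), function(k) {
    s <- df[keys == k, , drop = FALSE]
    s <- s[order(s$t_min), , drop = FALSE]
    tt <- s$t_min
    step <- interval %||% min(diff(tt))
    full <- seq(tt[1], tt[length(tt)], by = step)
    if (length(full) > nrow(s)) {
      w <- stats::approx(tt, s$weight_g, xout = full)$y
      filled <- s[rep(1, length(full)), , drop = FALSE]
      filled$t_min <- full
      filled$weight_g <- w
      s <- filled
    }
    s
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write trough recordings to CSV
#'
#' @param df long trough table as produced by [simulate_herd()] or
#'   [read_trough_series()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_trough_series <- function(df, path) {
  need_cols(df, trough_cols, "trough table")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Cumulative intake profile from one trough series
#'
#' Converts one goat-day of trough weights into a cumulative dry matter
#' intake profile in g DM per kg body weight:
#' `y(t) = (weight(0) - weight(t)) * dm_fraction / bw`, followed by
#' monotone cleaning with a running maximum so transient positive weight
#' artefacts (refill bumps, load-cell noise) never make the cumulative
#' curve decrease. The result is non-decreasing with `y[1] = 0`, and is
#' unchanged when the raw weights are already non-increasing.
#'
#' @param series data.frame for a single goat-day with columns `t_min`
#'   and `weight_g` (metadata columns `goat_id`, `breed`, `period`, `day`
#'   are carried through when present).
#' @param bw body weight in kg (> 0).
#' @param dm_fraction DM fraction of the offered feed, in (0, 1].
#' @return an object of class `intake_profile`: list with `t`, `y`, `bw`,
#'   `dm_fraction`, `interval`, `total_window` and the series metadata.
#' @export
cumulative_intake <- function(series, bw, dm_fraction = 1) {
  need_cols(series, c("t_min", "weight_g"), "series")
  if (length(bw) != 1 || is.na(bw) || bw <= 0)
    stop_domain("bw must be a single positive body weight in kg")
  if (dm_fraction <= 0 || dm_fraction > 1)
    stop_domain("dm_fraction must be in (0, 1]")
  s <- series[order(series$t_min), , drop = FALSE]
  tt <- s$t_min
  if (length(tt) < 2) stop_domain("series must hold at least two samples")
  if (anyDuplicated(tt)) stop_domain("series has duplicated timestamps")
  interval <- diff(tt)[1]
  if (any(abs(diff(tt) - interval) > 1e-8))
    stop_domain("series grid is irregular; read it with read_trough_series() first")
  y_raw <- (s$weight_g[1] - s$weight_g) * dm_fraction / bw
  y <- cummax(pmax(y_raw, 0))
  structure(list(t = tt - tt[1], y = y, bw = bw, dm_fraction = dm_fraction,
                 interval = interval,
                 total_window = length(tt) * interval,
                 goat_id = s$goat_id[1] %||% NA, breed = s$breed[1] %||% NA,
                 period = s$period[1] %||% NA, day = s$day[1] %||% NA),
            class = "intake_profile")
}

#' @export
print.intake_profile <- function(x, ...) {
  cat(sprintf("Intake profile %s P%s D%s: %d samples @ %g min, final %.2f g DM/kg BW\n",
              x$goat_id, x$period, x$day, length(x$y), x$interval,
              x$y[length(x$y)]))
  invisible(x)
}

#' Clip an intake profile to an analysis window
#'
#' Windows are half-open `[0, duration)`: a 900-min clip of a 2-min grid
#' keeps exactly 450 samples. Clipping to the profile's full span is the
#' identity, and `clip_window(clip_window(p, d1), d2)` equals
#' `clip_window(p, min(d1, d2))`.
#'
#' @param profile an `intake_profile`.
#' @param duration window length in minutes; must be a positive multiple of
#'   the sampling interval and at most the profile span.
#' @return the clipped `intake_profile`.
#' @export
clip_window <- function(profile, duration) {
  stopifnot(inherits(profile, "intake_profile"))
  if (duration <= 0 || abs(duration / profile$interval -
                           round(duration / profile$interval)) > 1e-8)
    stop_domain("duration must be a positive multiple of the sampling interval")
  if (duration > profile$total_window)
    stop_domain("duration exceeds the profile's recording span")
  keep <- profile$t < duration
  out <- profile
  out$t <- profile$t[keep]
  out$y <- profile$y[keep]
  out$total_window <- duration
  out
}

#' Build intake profiles for every goat-day of a dataset
#'
#' Joins the trough recordings with the body-weight and feed tables and
#' returns one [cumulative_intake()] profile per goat x period x day.
#'
#' @param trough long trough table.
#' @param bw_table data.frame `goat_id`, `period`, `bw`.
#' @param feed_table data.frame with `goat_id`, `period`, `day`,
#'   `dm_fraction` (optional; DM fraction defaults to 1).
#' @return named list of `intake_profile` objects, keyed
#'   `"goat_id|period|day"`.
#' @export
build_profiles <- function(trough, bw_table, feed_table = NULL) {
  need_cols(trough, trough_cols, "trough table")
  need_cols(bw_table, c("goat_id", "period", "bw"), "bw table")
  keys <- interaction(trough$goat_id, trough$period, trough$day, drop = TRUE)
  out <- list()
  for (k in levels(keys)) {
    s <- trough[keys == k, , drop = FALSE]
    gid <- s$goat_id[1]; p <- s$period[1]; d <- s$day[1]
    bw <- bw_table$bw[bw_table$goat_id == gid & bw_table$period == p]
    if (length(bw) != 1)
      stop_domain(sprintf("bw table has %d rows for goat %s period %s",
                          length(bw), gid, p))
    dmf <- 1
    if (!is.null(feed_table) && "dm_fraction" %in% names(feed_table)) {
      hit <- feed_table$dm_fraction[feed_table$goat_id == gid &
                                      feed_table$period == p & feed_table$day == d]
      if (length(hit) == 1) dmf <- hit
    }
    out[[paste(gid, p, d, sep = "|")]] <- cumulative_intake(s, bw, dmf)
  }
  out
}
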