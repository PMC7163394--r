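## The eleven aggregate feed-intake-pattern traits per goat-day, and their
## goat x period means.

#' Names of the eleven aggregate traits
#'
#' `ddmi` (intake over the full 22-h recording), `dmi90`, `dmi180`,
#' `dmi900` (cumulative intake at 90/180/900 min), `p90 = dmi90/dmi900`,
#' `p180 = dmi180/dmi900`, `a`, `ab` and `rmse_ab` from the exponential
#' model, `first_meal_dmi`, and the NDF sorting index. All intakes in
#' g DM/kg BW.
#'
#' @return character vector of length 11.
#' @export
trait_names <- function() {
  c("ddmi", "dmi90", "dmi180", "dmi900", "p90", "p180",
    "a", "ab", "rmse_ab", "first_meal_dmi", "ndf_sorting")
}

## Half-open window read: profile value at the last sample before `minute`.
window_value <- function(profile, minute) {
  keep <- profile$t < minute
  if (!any(keep)) stop_domain("window boundary before the first sample")
  profile$y[max(which(keep))]
}

#' NDF sorting index
#'
#' Ratio between the NDF content of the intake, reconstructed by mass
#' balance from the quantity and NDF content of the offered feed and of
#' the refusals, and the NDF content of the offered diet:
#' `intake_ndf = (offered_dm * offered_ndf - refusal_dm * refusal_ndf) /
#' (offered_dm - refusal_dm)`, index `= intake_ndf / offered_ndf`.
#' A value below 1 means the goat sorted against fibre. Invariant to
#' rescaling all masses by a constant. With zero intake (refusal equals
#' offer) the index is undefined and `NA` is returned with a warning.
#'
#' @param offered_dm offered mass, g DM.
#' @param offered_ndf NDF fraction of the offered diet, in (0, 1).
#' @param refusal_dm refused mass, g DM (`<= offered_dm`).
#' @param refusal_ndf NDF fraction of the refusal, in (0, 1).
#' @return the dimensionless sorting index.
#' @export
ndf_sorting <- function(offered_dm, offered_ndf, refusal_dm, refusal_ndf) {
  if (any(offered_ndf <= 0 | offered_ndf >= 1, na.rm = TRUE) ||
      any(refusal_ndf <= 0 | refusal_ndf >= 1, na.rm = TRUE))
    stop_domain("NDF fractions must lie in (0, 1)")
  if (any(refusal_dm > offered_dm, na.rm = TRUE))
    stop_domain("refusal_dm cannot exceed offered_dm")
  if (any(refusal_dm < 0 | offered_dm <= 0, na.rm = TRUE))
    stop_domain("masses must be non-negative with offered_dm > 0")
  intake_dm <- offered_dm - refusal_dm
  out <- ifelse(refusal_dm == 0, 1,
                ((offered_dm * offered_ndf - refusal_dm * refusal_ndf) /
                   intake_dm) / offered_ndf)
  zero <- !is.na(intake_dm) & intake_dm <= 0
  if (any(zero)) {
    warning("zero intake: NDF sorting undefined, returning NA")
    out[zero] <- NA_real_
  }
  out
}

#' Aggregate traits for one goat-day
#'
#' Combines a full-window intake profile, an exponential fit, a first-meal
#' result and the feed/refusal composition into the eleven aggregate
#' traits. Window reads use the half-open convention (value at the last
#' sample before the boundary), matching the 450-sample 900-min window.
#' A day with zero 15-h intake has undefined ratios and is flagged for
#' exclusion from downstream statistics.
#'
#' @param profile full-window `intake_profile` (22 h).
#' @param fit `exp_fit` from the 900-min clip.
#' @param meal `meal_result` from the 900-min segmentation.
#' @param offered_dm,offered_ndf,refusal_dm,refusal_ndf feed and refusal
#'   records for the day; any `NA` leaves `ndf_sorting` as `NA`.
#' @return one-row data.frame: metadata, the eleven traits, `converged`
#'   and `flagged`.
#' @export
compute_traits <- function(profile, fit, meal,
                           offered_dm = NA, offered_ndf = NA,
                           refusal_dm = NA, refusal_ndf = NA) {
  stopifnot(inherits(profile, "intake_profile"), inherits(fit, "exp_fit"),
            inherits(meal, "meal_result"))
  ddmi <- window_value(profile, profile$total_window)
  dmi90 <- window_value(profile, 90)
  dmi180 <- window_value(profile, 180)
  dmi900 <- window_value(profile, 900)
  flagged <- dmi900 <= 0
  sorting <- if (anyNA(c(offered_dm, offered_ndf, refusal_dm, refusal_ndf)))
    NA_real_
  else ndf_sorting(offered_dm, offered_ndf, refusal_dm, refusal_ndf)
  data.frame(
    goat_id = profile$goat_id, breed = profile$breed,
    period = profile$period, day = profile$day,
    ddmi = ddmi, dmi90 = dmi90, dmi180 = dmi180, dmi900 = dmi900,
    p90 = if (flagged) NA_real_ else dmi90 / dmi900,
    p180 = if (flagged) NA_real_ else dmi180 / dmi900,
    a = fit$a, ab = fit$ab, rmse_ab = fit$rmse,
    first_meal_dmi = meal$first_meal_intake,
    ndf_sorting = sorting,
    converged = fit$converged, flagged = flagged,
    stringsAsFactors = FALSE)
}

#' Trait table for a whole dataset
#'
#' Runs the per-goat-day chain (profile, 900-min clip, exponential fit,
#' segmentation, pooled slope clustering, first meal, sorting index) over
#' a full set of recordings and returns the stacked trait records. Slope
#' clusters are fitted on the pooled segment slopes of the whole dataset
#' so labels are comparable across animals.
#'
#' @param trough long trough table (see [read_trough_series()]).
#' @param bw_table data.frame `goat_id`, `period`, `bw` (kg).
#' @param feed_table data.frame `goat_id`, `period`, `day`,
#'   `offered_dm_g`, `offered_ndf`, `dm_fraction`.
#' @param refusal_table data.frame `goat_id`, `period`, `day`,
#'   `refusal_dm_g`, `refusal_ndf`.
#' @param day_window analysis window after delivery, min (900 = 15 h).
#' @param k_clusters number of slope clusters.
#' @param min_pause minimum pause ending a meal, min.
#' @param seed seed for the cluster fit.
#' @param penalty,penalty_grid segmentation penalty controls
#'   (see [segment_profile()]).
#' @return data.frame of trait records, one row per goat-day, with the
#'   fitted `slope_clusters` model in attribute `"cluster_model"`.
#' @export
compute_trait_table <- function(trough, bw_table, feed_table = NULL,
                                refusal_table = NULL, day_window = 900,
                                k_clusters = 8, min_pause = 30, seed = 1,
                                penalty = NULL,
                                penalty_grid = c(0.01, 0.05, 0.2, 1, 5, 25)) {
  profiles <- build_profiles(trough, bw_table, feed_table)
  clips <- lapply(profiles, clip_window, duration = day_window)
  fits <- lapply(clips, fit_exponential)
  segs <- lapply(clips, segment_profile, penalty = penalty,
                 penalty_grid = penalty_grid)
  model <- fit_cluster_model(unlist(lapply(segs, `[[`, "slope")),
                             k = k_clusters, seed = seed)
  rows <- lapply(names(profiles), function(key) {
    p <- profiles[[key]]
    labeled <- assign_clusters(segs[[key]], model)
    meal <- first_meal(labeled, min_pause = min_pause, profile = clips[[key]])
    feed <- ref <- NULL
    if (!is.null(feed_table))
      feed <- feed_table[feed_table$goat_id == p$goat_id &
                           feed_table$period == p$period &
                           feed_table$day == p$day, , drop = FALSE]
    if (!is.null(refusal_table))
      ref <- refusal_table[refusal_table$goat_id == p$goat_id &
                             refusal_table$period == p$period &
                             refusal_table$day == p$day, , drop = FALSE]
    compute_traits(p, fits[[key]], meal,
                   offered_dm = if (length(feed$offered_dm_g)) feed$offered_dm_g else NA,
                   offered_ndf = if (length(feed$offered_ndf)) feed$offered_ndf else NA,
                   refusal_dm = if (length(ref$refusal_dm_g)) ref$refusal_dm_g else NA,
                   refusal_ndf = if (length(ref$refusal_ndf)) ref$refusal_ndf else NA)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "cluster_model") <- model
  out
}

#' Trait table for a synthetic herd
#'
#' Convenience wrapper running [compute_trait_table()] on the tables of a
#' [simulate_herd()] result.
#'
#' @param herd a `synthetic_herd` (with profiles).
#' @param ... passed to [compute_trait_table()].
#' @return trait-record data.frame.
#' @export
herd_traits <- function(herd, ...) {
  stopifnot(inherits(herd, "synthetic_herd"))
  if (is.null(herd$trough))
    stop_domain("herd was simulated with profiles = FALSE; no trough series available")
  compute_trait_table(herd$trough, herd$bw_table, herd$feed_table,
                      herd$refusal_table, ...)
}

#' Goat x period means of the trait records
#'
#' Arithmetic mean of the available days per goat x period cell for each
#' of the eleven traits (missing values, e.g. sorting indices for days
#' without refusal analyses, are dropped per trait). Cells observed on
#' fewer than two days are flagged; empty cells are omitted with a
#' warning. Flagged (zero-intake) day records are excluded.
#'
#' @param records trait-record data.frame from [compute_trait_table()].
#' @return data.frame with one row per goat x period: metadata, trait
#'   means, `n_days` and `incomplete` flag.
#' @export
goat_period_means <- function(records) {
  need_cols(records, c("goat_id", "breed", "period", trait_names()), "trait records")
  if (!is.null(records$flagged) && any(records$flagged)) {
    warning(sum(records$flagged), " zero-intake day record(s) excluded from means")
    records <- records[!records$flagged, , drop = FALSE]
  }
  if (!nrow(records)) { warning("no usable records"); return(records) }
  key <- interaction(records$goat_id, records$period, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    s <- records[key == k, , drop = FALSE]
    means <- vapply(trait_names(), function(tr) mean(s[[tr]], na.rm = TRUE),
                    numeric(1))
    means[is.nan(means)] <- NA_real_
    cbind(data.frame(goat_id = s$goat_id[1], breed = s$breed[1],
                     period = s$period[1], stringsAsFactors = FALSE),
          as.data.frame(as.list(means)),
          data.frame(n_days = nrow(s), incomplete = nrow(s) < 2))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$goat_id, out$period), , drop = FALSE]
  rownames(out) <- NULL
  out
}
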