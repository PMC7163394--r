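## Synthetic herd generator: seeded trough-weight recordings with known
## latent traits, so the whole phenotyping pipeline is testable without
## animal data.

#' Herd and recording design
#'
#' Describes the experimental layout: number of goats and their breeds, the
#' number of physiological periods and recording days per period, and the
#' recording geometry of the trough scale (sampling interval, total window
#' after the afternoon feed delivery, scale resolution).
#'
#' The default mirrors a 35-goat herd (13 Alpine, 22 Saanen) recorded over
#' 4 periods x 4 days, sampled every 2 min for 22 h with a 5-g scale.
#'
#' Recording grids are half-open: samples sit at `0, interval, ...,
#' window - interval` (so a 22-h window at 2-min sampling holds 660
#' samples and its 900-min clip holds 450).
#'
#' @param n_goats number of goats (>= 2).
#' @param breeds character vector of per-goat breed labels (two levels
#'   expected); default splits goats 13:22 between `"Alpine"` and
#'   `"Saanen"` proportionally.
#' @param n_periods number of physiological periods.
#' @param n_days recording days per period.
#' @param interval sampling interval in minutes.
#' @param window total recording span in minutes after the afternoon
#'   delivery; must be a multiple of `interval`.
#' @param resolution scale resolution in g as-fed.
#' @return an object of class `herd_design`.
#' @export
#' @examples
#' herd_design(n_goats = 4, n_periods = 2, n_days = 2)
herd_design <- function(n_goats = 35, breeds = NULL, n_periods = 4, n_days = 4,
                        interval = 2, window = 1320, resolution = 5) {
  if (is.null(breeds)) {
    n_a <- max(1L, round(n_goats * 13 / 35))
    breeds <- rep(c("Alpine", "Saanen"), c(n_a, n_goats - n_a))
  }
  if (n_goats < 2) stop_domain("design: n_goats must be >= 2")
  if (length(breeds) != n_goats)
    stop_domain("design: breeds must have one label per goat")
  if (n_periods < 1 || n_days < 1)
    stop_domain("design: n_periods and n_days must be >= 1")
  if (interval <= 0) stop_domain("design: sampling interval must be > 0")
  if (window <= 0 || window %% interval != 0)
    stop_domain("design: window must be a positive multiple of the interval")
  if (resolution <= 0) stop_domain("design: scale resolution must be > 0")
  structure(list(n_goats = as.integer(n_goats), breeds = as.character(breeds),
                 n_periods = as.integer(n_periods), n_days = as.integer(n_days),
                 interval = interval, window = window, resolution = resolution),
            class = "herd_design")
}

#' @export
print.herd_design <- function(x, ...) {
  cat("Herd design:", x$n_goats, "goats (",
      paste(names(table(x$breeds)), table(x$breeds), collapse = ", "), "),",
      x$n_periods, "periods x", x$n_days, "days;",
      x$window, "min window @", x$interval, "min,",
      x$resolution, "g resolution\n")
  invisible(x)
}

goat_ids <- function(design) sprintf("G%02d", seq_len(design$n_goats))

#' Variance structure of the synthetic herd
#'
#' Governs how much trait variation the generator places at each level of
#' the design. `sd_goat` is the between-goat SD of the latent daily intake
#' level (g DM/kg BW); `period_shift` is a vector of deterministic
#' per-period shifts of that level (period is a fixed effect);
#' `sd_day` is the SD of systematic day-number effects nested in goat;
#' `sd_resid` is the residual goat-period-day trait SD; `sd_noise` is the
#' within-series load-cell noise SD in g as-fed, applied before
#' quantization; `bump_prob` is the per-sample probability of a transient
#' positive weight artefact (to exercise monotone cleaning).
#'
#' @param sd_goat between-goat SD, g DM/kg BW.
#' @param period_shift numeric vector of per-period shifts, g DM/kg BW.
#' @param sd_day SD of day-number effects within goat.
#' @param sd_resid residual per goat-period-day SD.
#' @param sd_noise observation noise SD on trough weights, g as-fed.
#' @param bump_prob per-sample probability of a transient positive bump.
#' @return an object of class `variance_spec`.
#' @export
variance_spec <- function(sd_goat = 9.5, period_shift = c(-2, 2, -3, 1),
                          sd_day = 0.8, sd_resid = 2, sd_noise = 2,
                          bump_prob = 0.002) {
  sds <- c(sd_goat = sd_goat, sd_day = sd_day, sd_resid = sd_resid,
           sd_noise = sd_noise)
  if (any(sds < 0)) stop_domain("variances: SDs must be >= 0")
  if (bump_prob < 0 || bump_prob > 1)
    stop_domain("variances: bump_prob must be in [0, 1]")
  structure(list(sd_goat = sd_goat, period_shift = period_shift,
                 sd_day = sd_day, sd_resid = sd_resid, sd_noise = sd_noise,
                 bump_prob = bump_prob),
            class = "variance_spec")
}

#' Repeatability implied by a variance specification
#'
#' Returns the large-sample value of the between/(between + within)
#' repeatability ratio of true goat-period trait means under a given design
#' and variance structure, i.e. the limit of the method-of-moments
#' estimator used by [repeatability_ratio()]. Deterministic period shifts
#' enter the within-goat mean square, and day-number effects (being shared
#' across periods within a goat) act like extra between-goat variance.
#'
#' @param variances a [variance_spec()].
#' @param design a [herd_design()].
#' @return the implied ratio in `[0, 1]`.
#' @export
implied_icc <- function(variances, design) {
  L <- design$n_periods
  K <- design$n_days
  shifts <- rep_len(variances$period_shift, L)
  s_delta2 <- if (L > 1) stats::var(shifts) else 0
  sigma_b <- variances$sd_goat^2 + variances$sd_day^2 / K
  sigma_e <- variances$sd_resid^2 / K
  between <- max(0, sigma_b - s_delta2 / L)
  within <- s_delta2 + sigma_e
  if (between + within <= 0) return(NA_real_)
  between / (between + within)
}

#' Variance specification targeting a given repeatability
#'
#' Convenience constructor for simulation studies: builds a
#' [variance_spec()] with zero period shifts and zero day effects whose
#' implied between/(between + within) ratio of goat-period means equals
#' `icc` exactly, by solving for the between-goat SD.
#'
#' @param icc target ratio in (0, 1).
#' @param sd_resid residual per goat-period-day SD.
#' @param n_days recording days per period (enters the within-goat
#'   variance of period means as `sd_resid^2 / n_days`).
#' @param ... further arguments passed to [variance_spec()].
#' @return a `variance_spec`.
#' @export
variance_spec_for_icc <- function(icc, sd_resid = 4, n_days = 4, ...) {
  if (icc <= 0 || icc >= 1) stop_domain("icc must be in (0, 1)")
  sd_goat <- sd_resid * sqrt(icc / (1 - icc) / n_days)
  variance_spec(sd_goat = sd_goat, period_shift = rep(0, 4), sd_day = 0,
                sd_resid = sd_resid, ...)
}

## Calibration constants of the generator (see the methods vignette for the
## rationale behind each value). Overridable via simulate_herd(calibration=).
default_calibration <- function() {
  list(
    # breed-level mean daily intake at the reference period, g DM/kg BW;
    # period_shift moves these across periods
    breed_dmi900 = c(Alpine = 36.8, Saanen = 31.8, other = 34.3),
    # breed-level body weight at the first period, kg, and its SD
    breed_bw = c(Alpine = 45.9, Saanen = 51.4, other = 48.5),
    sd_bw = 3.5,
    # per-period additive BW growth, kg (recycled/extended if needed)
    bw_growth = c(0, 4, 7, 9),
    # initial intake rate: log-normal parameters and truncation, g DM/kg BW/min
    rate_meanlog = log(0.6), rate_sdlog = 0.25, rate_range = c(0.4, 1.2),
    # eagerness (share of the 15-h intake taken in the first meal): logit-normal
    eager_mean = 0.6, eager_sdlogit = 0.6, eager_range = c(0.2, 0.95),
    # fibre sorting intensity: gamma(shape, rate) so mean = shape/rate
    sort_shape = 4, sort_rate = 40,
    # per-period multiplier of sorting intensity (sorting grows with age)
    sort_age_factor = c(0.7, 0.9, 1.1, 1.3),
    # per-period DM fraction and NDF fraction of the offered TMR
    dm_fraction = c(0.54, 0.56, 0.55, 0.55),
    offered_ndf = c(0.42, 0.43, 0.42, 0.41),
    # night intake (900 min .. window) as a fraction of the 15-h intake
    night_frac = c(0.08, 0.22),
    # refusal as a fraction of offered DM
    refusal_frac = c(0.10, 0.25)
  )
}

per_period <- function(x, n) {
  if (length(x) >= n) x[seq_len(n)] else {
    extra <- x[length(x)] + (x[length(x)] - x[length(x) - 1]) * seq_len(n - length(x))
    c(x, extra)
  }
}

lookup_breed <- function(tab, breed) {
  out <- tab[breed]
  out[is.na(out)] <- tab[["other"]]
  unname(out)
}

#' Simulate one goat-day trough-weight recording
#'
#' Generates a bout schedule (one large first meal followed by 0-6 later
#' bouts separated by pauses of at least 30 min, plus optional night bouts
#' after the 900-min mark) and the corresponding trough-weight series:
#' the trough starts at the offered as-fed mass, decreases piecewise
#' linearly while the goat eats, and is observed with additive load-cell
#' noise, occasional transient positive bumps and quantization at the
#' scale resolution. Bout schedules that would overrun the window are
#' regenerated internally, dropping bouts as a last resort, so the
#' returned series is always valid.
#'
#' @param traits list or one-row data.frame with `initial_rate`
#'   (g DM/kg BW/min), `eagerness` (share of the 15-h intake eaten in the
#'   first meal, in (0, 1]) and `bw` (kg).
#' @param design a [herd_design()].
#' @param seed integer seed for this goat-day.
#' @param dmi900 target cumulative intake at 900 min, g DM/kg BW.
#' @param ddmi target intake over the whole window, g DM/kg BW
#'   (default: `dmi900` plus a drawn night fraction).
#' @param dm_fraction DM fraction of the offered feed.
#' @param offered_dm offered mass in g DM (default: total intake inflated
#'   by a drawn refusal fraction).
#' @param variances a [variance_spec()] (noise and bump settings).
#' @return list with `series` (data.frame `t_min`, `weight_g`), `bouts`
#'   (data.frame `bout`, `phase`, `t_start`, `t_end`, `rate`, `intake`),
#'   realized `dmi900`, `ddmi`, `first_meal`, and the `offered_dm` /
#'   `dm_fraction` used.
#' @export
simulate_day_profile <- function(traits, design, seed = 1,
                                 dmi900 = NULL, ddmi = NULL,
                                 dm_fraction = 0.55, offered_dm = NULL,
                                 variances = variance_spec()) {
  stopifnot(inherits(design, "herd_design"))
  traits <- as.list(traits)
  if (is.null(dmi900)) dmi900 <- traits$mean_dmi900
  bw <- traits$bw
  if (any(c(traits$initial_rate, traits$eagerness, bw, dmi900) <= 0, na.rm = TRUE) ||
      anyNA(c(traits$initial_rate, traits$eagerness, bw, dmi900)))
    stop_domain("simulate_day_profile: traits, bw and dmi900 must be positive")
  if (traits$eagerness > 1) stop_domain("simulate_day_profile: eagerness must be in (0, 1]")
  cal <- default_calibration()

  with_seed(substream_seed(seed, "bouts"), {
    if (is.null(ddmi)) ddmi <- dmi900 * (1 + stats::runif(1, cal$night_frac[1], cal$night_frac[2]))
    day_limit <- min(900, design$window) - 5
    # bout boundaries are snapped to the sampling grid: a scale sampling
    # every `interval` minutes cannot resolve sub-sample meal boundaries,
    # and on-grid kinks keep the latent schedule recoverable exactly
    iv <- design$interval
    snap_dur <- function(dur) pmax(2 * iv, round(dur / iv) * iv)
    # pauses stay >= 30 min but clear the meal-detection threshold by one
    # sample: a pause of exactly 30 min is a knife-edge for the rule when a
    # boundary sample ties into the neighbouring bout
    snap_pause <- function(p) pmax(30 + iv, round(p / iv) * iv)
    r1 <- clamp(traits$initial_rate * stats::runif(1, 0.9, 1.1),
                cal$rate_range[1] - 0.05, 2)
    t0 <- round(stats::runif(1, 0, 4) / iv) * iv
    f1 <- traits$eagerness * dmi900
    remaining <- dmi900 - f1
    n_later <- if (remaining < 1) 0L else min(6L, stats::rpois(1, 1.2) + 1L)
    if (n_later == 0L) { f1 <- dmi900; remaining <- 0 }

    schedule_later <- function(n_later) {
      # returns a bout table or NULL when the window cannot hold the schedule
      for (try in seq_len(25)) {
        dur1 <- snap_dur(f1 / r1)
        if (t0 + dur1 > day_limit) { return(NULL) }
        bouts <- data.frame(phase = "day", t_start = t0, t_end = t0 + dur1,
                            rate = f1 / dur1, intake = f1, stringsAsFactors = FALSE)
        if (n_later > 0) {
          w <- stats::rgamma(n_later, shape = 2, rate = 1)
          shares <- w / sum(w) * remaining
          rates <- r1 * stats::runif(n_later, 0.3, 0.7)
          cur <- t0 + dur1
          ok <- TRUE
          for (b in seq_len(n_later)) {
            pause <- snap_pause(30 + stats::rexp(1, rate = 1 / 45))
            s <- cur + pause
            dur <- snap_dur(shares[b] / rates[b])
            e <- s + dur
            if (e > day_limit) { ok <- FALSE; break }
            bouts <- rbind(bouts, data.frame(phase = "day", t_start = s, t_end = e,
                                             rate = shares[b] / dur, intake = shares[b],
                                             stringsAsFactors = FALSE))
            cur <- e
          }
          if (!ok) next
        }
        return(bouts)
      }
      NULL
    }
    bouts <- NULL
    while (is.null(bouts)) {
      bouts <- schedule_later(n_later)
      if (is.null(bouts)) {
        if (n_later > 0L) {
          n_later <- n_later - 1L
          if (n_later == 0L) { f1 <- dmi900; remaining <- 0 }
        } else {
          # even the single bout does not fit: eat faster
          r1 <- r1 * 1.5
        }
      }
    }

    night_budget <- ddmi - dmi900
    if (design$window > 910 && night_budget > 0.5) {
      n_night <- sample(0:2, 1, prob = c(0.2, 0.5, 0.3))
      if (n_night > 0) {
        for (try in seq_len(25)) {
          w <- stats::rgamma(n_night, shape = 2, rate = 1)
          shares <- w / sum(w) * night_budget
          rates <- r1 * stats::runif(n_night, 0.3, 0.7)
          cur <- 900
          nb <- NULL
          ok <- TRUE
          for (b in seq_len(n_night)) {
            pause <- snap_pause(30 + stats::rexp(1, rate = 1 / 60))
            s <- cur + pause
            dur <- snap_dur(shares[b] / rates[b])
            e <- s + dur
            if (e > design$window - 10) { ok <- FALSE; break }
            nb <- rbind(nb, data.frame(phase = "night", t_start = s, t_end = e,
                                       rate = shares[b] / dur, intake = shares[b],
                                       stringsAsFactors = FALSE))
            cur <- e
          }
          if (ok) { bouts <- rbind(bouts, nb); break }
          if (try == 25) n_night <- 0L
        }
      }
    }
    bouts$bout <- seq_len(nrow(bouts))
    bouts <- bouts[c("bout", "phase", "t_start", "t_end", "rate", "intake")]

    ddmi_real <- sum(bouts$intake)
    dmi900_real <- sum(bouts$intake[bouts$phase == "day"])
    if (is.null(offered_dm))
      offered_dm <- ddmi_real * bw /
        (1 - stats::runif(1, cal$refusal_frac[1], cal$refusal_frac[2]))

    tt <- seq(0, design$window - design$interval, by = design$interval)
    cum <- numeric(length(tt))
    for (b in seq_len(nrow(bouts))) {
      dur <- bouts$t_end[b] - bouts$t_start[b]
      cum <- cum + bouts$rate[b] * clamp(tt - bouts$t_start[b], 0, dur)
    }
    offered_asfed <- offered_dm / dm_fraction
    w <- offered_asfed - cum * bw / dm_fraction
    if (variances$sd_noise > 0)
      w <- w + stats::rnorm(length(w), 0, variances$sd_noise)
    if (variances$bump_prob > 0) {
      idx <- which(stats::runif(length(w)) < variances$bump_prob)
      if (length(idx)) w[idx] <- w[idx] + stats::runif(length(idx), 5, 25)
    }
    w <- pmax(round(w / design$resolution) * design$resolution, 0)

    list(series = data.frame(t_min = tt, weight_g = w),
         bouts = bouts,
         dmi900 = dmi900_real, ddmi = ddmi_real, first_meal = f1,
         offered_dm = offered_dm, dm_fraction = dm_fraction)
  })
}

#' Simulate the refusal left in the trough
#'
#' Applies the goat's fibre-sorting behaviour to the mass balance between
#' offered feed, intake and refusal. Sorting against fibre makes the NDF
#' (neutral detergent fibre) fraction of the intake lower than that of the
#' offered diet, and consequently the NDF fraction of the refusal higher;
#' NDF mass is conserved exactly. With `sorting_intensity = 0` the refusal
#' composition equals the offered composition and the downstream sorting
#' index is exactly 1.
#'
#' @param sorting_intensity non-negative sorting intensity (0 = no sorting).
#' @param offered_dm offered mass, g DM.
#' @param offered_ndf NDF fraction of the offered diet, in (0, 1).
#' @param intake_dm mass eaten, g DM; must satisfy
#'   `0 <= intake_dm <= offered_dm`.
#' @param seed integer seed.
#' @return list with `dm` (refusal mass, g DM) and `ndf` (refusal NDF
#'   fraction; `NA` when nothing is refused).
#' @export
simulate_refusal <- function(sorting_intensity, offered_dm, offered_ndf,
                             intake_dm, seed = 1) {
  if (sorting_intensity < 0) stop_domain("sorting_intensity must be >= 0")
  if (offered_ndf <= 0 || offered_ndf >= 1)
    stop_domain("offered_ndf must be a fraction in (0, 1)")
  if (intake_dm < 0 || intake_dm > offered_dm)
    stop_domain("intake_dm must satisfy 0 <= intake_dm <= offered_dm")
  refusal_dm <- offered_dm - intake_dm
  if (refusal_dm < 1e-9 || intake_dm < 1e-9) {
    return(list(dm = refusal_dm, ndf = if (refusal_dm < 1e-9) NA_real_ else offered_ndf))
  }
  with_seed(substream_seed(seed, "refusal"), {
    s <- exp(-sorting_intensity * stats::runif(1, 0.8, 1.2))
    intake_ndf <- offered_ndf * s
    refusal_ndf <- (offered_dm * offered_ndf - intake_dm * intake_ndf) / refusal_dm
    if (refusal_ndf > 0.92) {
      # cap the refusal enrichment; re-solve the intake fraction from it
      refusal_ndf <- 0.92
      intake_ndf <- (offered_dm * offered_ndf - refusal_dm * refusal_ndf) / intake_dm
      intake_ndf <- max(intake_ndf, 0.05 * offered_ndf)
      refusal_ndf <- (offered_dm * offered_ndf - intake_dm * intake_ndf) / refusal_dm
    }
    list(dm = refusal_dm, ndf = refusal_ndf)
  })
}

#' Missing-record pattern over a herd design
#'
#' Draws a deterministic set of missing goat-day cells shaped like the
#' losses typical of automated recording campaigns: 13 affected goats, of
#' which four lose 2 days, one loses 3 days and eight lose 1 day (19 cells
#' in total), with the affected goats and cells sampled from the design
#' under the given seed. Custom counts may be supplied.
#'
#' @param design a [herd_design()].
#' @param seed integer seed.
#' @param counts integer vector: days lost per affected goat.
#' @return data.frame with columns `goat_id`, `period`, `day`.
#' @export
missing_cells_pattern <- function(design, seed = 1,
                                  counts = c(rep(2L, 4), 3L, rep(1L, 8))) {
  stopifnot(inherits(design, "herd_design"))
  if (length(counts) > design$n_goats)
    stop_domain("more affected goats than goats in the design")
  if (any(counts > design$n_periods * design$n_days))
    stop_domain("a goat cannot lose more cells than it has")
  with_seed(substream_seed(seed, "missing"), {
    goats <- sample(goat_ids(design), length(counts))
    cells <- expand.grid(period = seq_len(design$n_periods),
                         day = seq_len(design$n_days))
    out <- do.call(rbind, lapply(seq_along(goats), function(i) {
      pick <- cells[sample(nrow(cells), counts[i]), , drop = FALSE]
      data.frame(goat_id = goats[i], period = pick$period, day = pick$day,
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}

#' Simulate a synthetic herd of trough-weight recordings
#'
#' Draws per-goat latent traits (daily intake level, initial intake rate,
#' eagerness, fibre-sorting intensity, body weight), applies deterministic
#' period shifts and random day effects, and generates one trough-weight
#' series plus feed and refusal records per goat x period x day cell (minus
#' an optional missing-cell list). The latent truth (goat traits, per-day
#' realized targets and the exact bout schedules) is returned alongside the
#' data so downstream estimates can be validated against it.
#'
#' Every goat-day uses its own seed substream derived from `seed`, so the
#' dataset is bit-reproducible and cells shared between two runs that
#' differ only in their missing lists are identical.
#'
#' @param design a [herd_design()].
#' @param variances a [variance_spec()].
#' @param seed integer seed.
#' @param missing optional data.frame (`goat_id`, `period`, `day`) of cells
#'   to drop, e.g. from [missing_cells_pattern()].
#' @param profiles if `FALSE`, skip trough series / feed / refusal
#'   generation and return only the latent truth (fast path for
#'   simulation studies of the statistical layer).
#' @param calibration named list overriding entries of the generator's
#'   calibration constants (see the methods vignette).
#' @return an object of class `synthetic_herd`: list with `design`,
#'   `trough` (long data.frame: `goat_id`, `breed`, `period`, `day`,
#'   `t_min`, `weight_g`), `bw_table`, `feed_table`, `refusal_table` and
#'   `truth` (list `goats`, `days`, `bouts`).
#' @export
simulate_herd <- function(design, variances = variance_spec(), seed = 1,
                          missing = NULL, profiles = TRUE,
                          calibration = list()) {
  stopifnot(inherits(design, "herd_design"), inherits(variances, "variance_spec"))
  cal <- utils::modifyList(default_calibration(), calibration)
  ids <- goat_ids(design)
  shifts <- rep_len(variances$period_shift, design$n_periods)
  growth <- per_period(cal$bw_growth, design$n_periods)
  dmf <- per_period(cal$dm_fraction, design$n_periods)
  ndf <- per_period(cal$offered_ndf, design$n_periods)
  sortf <- per_period(cal$sort_age_factor, design$n_periods)

  goats <- with_seed(substream_seed(seed, "goats"), {
    data.frame(
      goat_id = ids, breed = design$breeds,
      mean_dmi900 = pmax(8, lookup_breed(cal$breed_dmi900, design$breeds) +
                           stats::rnorm(design$n_goats, 0, variances$sd_goat)),
      initial_rate = clamp(stats::rlnorm(design$n_goats, cal$rate_meanlog, cal$rate_sdlog),
                           cal$rate_range[1], cal$rate_range[2]),
      eagerness = clamp(stats::plogis(stats::rnorm(design$n_goats,
                                                   stats::qlogis(cal$eager_mean),
                                                   cal$eager_sdlogit)),
                        cal$eager_range[1], cal$eager_range[2]),
      sorting_intensity = stats::rgamma(design$n_goats, cal$sort_shape, cal$sort_rate),
      bw_base = pmax(25, lookup_breed(cal$breed_bw, design$breeds) +
                       stats::rnorm(design$n_goats, 0, cal$sd_bw)),
      stringsAsFactors = FALSE)
  })
  day_eff <- with_seed(substream_seed(seed, "dayeff"), {
    matrix(stats::rnorm(design$n_goats * design$n_days, 0, variances$sd_day),
           design$n_goats, design$n_days)
  })
  bw_table <- with_seed(substream_seed(seed, "bw"), {
    out <- expand.grid(period = seq_len(design$n_periods), goat_id = ids,
                       stringsAsFactors = FALSE)[2:1]
    g <- match(out$goat_id, ids)
    out$breed <- goats$breed[g]
    out$bw <- round(goats$bw_base[g] + growth[out$period] +
                      stats::rnorm(nrow(out), 0, 0.5), 1)
    out
  })

  cells <- expand.grid(day = seq_len(design$n_days),
                       period = seq_len(design$n_periods),
                       goat_id = ids, stringsAsFactors = FALSE)[3:1]
  if (!is.null(missing)) {
    need_cols(missing, c("goat_id", "period", "day"), "missing-cell list")
    key <- function(d) paste(d$goat_id, d$period, d$day)
    bad <- setdiff(key(missing), key(cells))
    if (length(bad)) stop_domain("missing cells outside the design: ",
                                 paste(bad, collapse = "; "))
    cells <- cells[!key(cells) %in% key(missing), , drop = FALSE]
  }

  trough_list <- feed_list <- refusal_list <- days_list <- bouts_list <-
    vector("list", nrow(cells))
  for (r in seq_len(nrow(cells))) {
    gid <- cells$goat_id[r]; p <- cells$period[r]; d <- cells$day[r]
    g <- match(gid, ids)
    cseed <- substream_seed(seed, "cell", gid, p, d)
    tgt <- with_seed(cseed, {
      list(dmi900 = max(5, goats$mean_dmi900[g] + shifts[p] + day_eff[g, d] +
                          stats::rnorm(1, 0, variances$sd_resid)),
           eager = clamp(goats$eagerness[g] + stats::rnorm(1, 0, 0.03), 0.15, 0.97),
           dm_fraction = clamp(dmf[p] + stats::rnorm(1, 0, 0.005), 0.4, 0.7),
           offered_ndf = clamp(ndf[p] + stats::rnorm(1, 0, 0.005), 0.2, 0.6))
    })
    bw_gp <- bw_table$bw[bw_table$goat_id == gid & bw_table$period == p]
    if (!profiles) {
      days_list[[r]] <- data.frame(
        goat_id = gid, breed = goats$breed[g], period = p, day = d,
        dmi900_true = tgt$dmi900, ddmi_true = NA_real_,
        first_meal_true = NA_real_, n_bouts = NA_integer_,
        eagerness_day = tgt$eager, bw = bw_gp, stringsAsFactors = FALSE)
      next
    }
    prof <- simulate_day_profile(
      traits = list(initial_rate = goats$initial_rate[g], eagerness = tgt$eager,
                    bw = bw_gp),
      design = design, seed = substream_seed(cseed, "prof"),
      dmi900 = tgt$dmi900, dm_fraction = tgt$dm_fraction,
      variances = variances)
    intake_dm <- prof$ddmi * bw_gp
    ref <- simulate_refusal(goats$sorting_intensity[g] * sortf[p],
                            prof$offered_dm, tgt$offered_ndf, intake_dm,
                            seed = substream_seed(cseed, "ref"))
    meta <- data.frame(goat_id = gid, breed = goats$breed[g], period = p,
                       day = d, stringsAsFactors = FALSE)
    trough_list[[r]] <- cbind(meta[rep(1, nrow(prof$series)), , drop = FALSE],
                              prof$series)
    feed_list[[r]] <- cbind(meta, data.frame(
      offered_dm_g = prof$offered_dm, offered_ndf = tgt$offered_ndf,
      dm_fraction = prof$dm_fraction))
    refusal_list[[r]] <- cbind(meta, data.frame(
      refusal_dm_g = ref$dm, refusal_ndf = ref$ndf))
    days_list[[r]] <- cbind(meta, data.frame(
      dmi900_true = prof$dmi900, ddmi_true = prof$ddmi,
      first_meal_true = prof$first_meal, n_bouts = nrow(prof$bouts),
      eagerness_day = tgt$eager, bw = bw_gp))
    bouts_list[[r]] <- cbind(meta[rep(1, nrow(prof$bouts)), , drop = FALSE],
                             prof$bouts)
  }

  bind <- function(l) if (all(vapply(l, is.null, logical(1)))) NULL else {
    out <- do.call(rbind, l); rownames(out) <- NULL; out
  }
  structure(list(design = design, variances = variances, seed = seed,
                 trough = bind(trough_list), bw_table = bw_table,
                 feed_table = bind(feed_list), refusal_table = bind(refusal_list),
                 truth = list(goats = goats, days = bind(days_list),
                              bouts = bind(bouts_list))),
            class = "synthetic_herd")
}

#' @export
print.synthetic_herd <- function(x, ...) {
  n_series <- if (is.null(x$truth$days)) 0 else nrow(x$truth$days)
  cat("Synthetic herd:", x$design$n_goats, "goats,", n_series,
      "goat-day cells (seed", x$seed, ")\n")
  if (is.null(x$trough)) cat("  truth only (profiles = FALSE)\n")
  invisible(x)
}

#' Write a synthetic herd to CSV files
#'
#' Writes `trough.csv` (long format: `goat_id`, `breed`, `period`, `day`,
#' `t_min`, `weight_g`), `feed.csv`, `refusal.csv`, `bw.csv` and the truth
#' tables `truth_goats.csv`, `truth_days.csv`, `truth_bouts.csv`.
#'
#' @param herd a `synthetic_herd`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_herd_csv <- function(herd, dir) {
  stopifnot(inherits(herd, "synthetic_herd"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- list(trough = herd$trough, feed = herd$feed_table,
                 refusal = herd$refusal_table, bw = herd$bw_table,
                 truth_goats = herd$truth$goats, truth_days = herd$truth$days,
                 truth_bouts = herd$truth$bouts)
  files <- character(0)
  for (nm in names(tables)) {
    if (is.null(tables[[nm]])) next
    f <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
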