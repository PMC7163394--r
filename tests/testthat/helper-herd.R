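# Shared fixture builders. Everything is generated in code under fixed
# seeds; nothing is read from disk.

small_design <- function(n_goats = 4, n_periods = 2, n_days = 2, ...) {
  herd_design(n_goats = n_goats, n_periods = n_periods, n_days = n_days, ...)
}

small_herd <- function(seed = 42, ...) {
  simulate_herd(small_design(...), seed = seed)
}

# Hand-built trait records table (no pipeline involved) for the
# statistical layer: goat + period + day-level noise with known effects.
toy_records <- function(n_goats = 6, n_periods = 2, n_days = 2, seed = 1,
                        sd_goat = 2, sd_noise = 0.5, breed_gap = 0) {
  set.seed(seed)
  ids <- sprintf("G%02d", seq_len(n_goats))
  breeds <- rep(c("Alpine", "Saanen"), length.out = n_goats)
  g_eff <- rnorm(n_goats, 0, sd_goat)
  df <- expand.grid(day = seq_len(n_days), period = seq_len(n_periods),
                    goat_id = ids, stringsAsFactors = FALSE)[3:1]
  i <- match(df$goat_id, ids)
  df$breed <- breeds[i]
  df$y <- 30 + g_eff[i] + breed_gap * (df$breed == "Alpine") +
    0.5 * df$period + rnorm(nrow(df), 0, sd_noise)
  df
}
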