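# Synthetic herd generator: determinism, bookkeeping, mass conservation
# and calibration of the latent-trait structure.

test_that("identical seeds yield bit-identical datasets", {
  h1 <- small_herd(seed = 7)
  h2 <- small_herd(seed = 7)
  expect_identical(h1$trough, h2$trough)
  expect_identical(h1$truth, h2$truth)
  expect_identical(h1$refusal_table, h2$refusal_table)
  h3 <- small_herd(seed = 8)
  expect_false(identical(h1$trough, h3$trough))
})

test_that("series count follows the design minus the missing list", {
  d <- small_design(n_goats = 5, n_periods = 2, n_days = 3)
  h <- simulate_herd(d, seed = 1)
  cells <- unique(h$trough[c("goat_id", "period", "day")])
  expect_equal(nrow(cells), 5 * 2 * 3)
  miss <- data.frame(goat_id = c("G01", "G02"), period = c(1, 2), day = c(2, 3))
  hm <- simulate_herd(d, seed = 1, missing = miss)
  expect_equal(nrow(unique(hm$trough[c("goat_id", "period", "day")])), 5 * 2 * 3 - 2)
  # shared cells are identical across the two runs
  key <- function(x) paste(x$goat_id, x$period, x$day, x$t_min)
  common <- intersect(key(h$trough), key(hm$trough))
  expect_identical(h$trough$weight_g[match(common, key(h$trough))],
                   hm$trough$weight_g[match(common, key(hm$trough))])
  expect_error(simulate_herd(d, seed = 1,
                             missing = data.frame(goat_id = "G09", period = 1, day = 1)),
               "outside the design")
})

test_that("missing-cell pattern drops 19 cells over 13 goats", {
  d <- herd_design()
  miss <- missing_cells_pattern(d, seed = 3)
  expect_equal(nrow(miss), 19)
  counts <- table(miss$goat_id)
  expect_equal(length(counts), 13)
  expect_equal(sort(as.integer(counts)), c(rep(1L, 8), rep(2L, 4), 3L))
  expect_false(anyDuplicated(miss) > 0)
})

test_that("a single large first bout leaves the trough flat afterwards", {
  d <- small_design(resolution = 1e-6)
  v <- variance_spec(sd_noise = 0, bump_prob = 0)
  prof <- simulate_day_profile(
    traits = list(initial_rate = 0.6, eagerness = 0.999, bw = 50),
    design = d, seed = 5, dmi900 = 30, ddmi = 30, variances = v)
  expect_equal(nrow(prof$bouts), 1)
  expect_equal(prof$first_meal, 30)
  after <- prof$series$weight_g[prof$series$t_min >= prof$bouts$t_end[1]]
  expect_lt(diff(range(after)), 1e-9)
  # trough is non-increasing before noise
  expect_true(all(diff(prof$series$weight_g) <= 1e-9))
})

test_that("truth bout intake and series-implied intake agree to scale resolution", {
  d <- small_design(n_goats = 3)
  v <- variance_spec(sd_noise = 0, bump_prob = 0)
  h <- simulate_herd(d, v, seed = 21)
  key <- function(x) paste(x$goat_id, x$period, x$day)
  for (k in unique(key(h$truth$days))) {
    s <- h$trough[key(h$trough) == k, ]
    td <- h$truth$days[key(h$truth$days) == k, ]
    feed <- h$feed_table[key(h$feed_table) == k, ]
    implied_dm <- (s$weight_g[1] - s$weight_g[nrow(s)]) * feed$dm_fraction
    expect_lt(abs(implied_dm - td$ddmi_true * td$bw), d$resolution)
  }
})

test_that("mass and NDF balances are conserved for every goat-day", {
  h <- small_herd(seed = 9)
  key <- function(x) paste(x$goat_id, x$period, x$day)
  m <- match(key(h$refusal_table), key(h$feed_table))
  td <- h$truth$days[match(key(h$feed_table), key(h$truth$days)), ]
  intake_dm <- td$ddmi_true * td$bw
  expect_equal(h$feed_table$offered_dm_g[m] - intake_dm,
               h$refusal_table$refusal_dm_g, tolerance = 1e-9)
  # refusal is enriched in NDF (goats sort against fibre)
  expect_true(all(h$refusal_table$refusal_ndf >= h$feed_table$offered_ndf[m] - 1e-9))
  # reconstructed intake NDF conserves offered NDF mass exactly
  o <- h$feed_table$offered_dm_g[m]; no <- h$feed_table$offered_ndf[m]
  r <- h$refusal_table$refusal_dm_g; nr <- h$refusal_table$refusal_ndf
  intake_ndf <- (o * no - r * nr) / (o - r)
  expect_equal(intake_ndf * (o - r) + nr * r, no * o, tolerance = 1e-9)
})

test_that("refusal composition is unselective when sorting intensity is zero", {
  ref <- simulate_refusal(0, offered_dm = 2000, offered_ndf = 0.4,
                          intake_dm = 1500, seed = 2)
  expect_equal(ref$dm, 500)
  expect_equal(ref$ndf, 0.4)
  expect_equal(ndf_sorting(2000, 0.4, ref$dm, ref$ndf), 1)
  expect_error(simulate_refusal(0.1, 1000, 0.4, 1200, seed = 1), "intake_dm")
})

test_that("calibrated sorting gives an NDF sorting index below 1 on average", {
  h <- small_herd(seed = 13, n_goats = 8)
  key <- function(x) paste(x$goat_id, x$period, x$day)
  m <- match(key(h$refusal_table), key(h$feed_table))
  idx <- ndf_sorting(h$feed_table$offered_dm_g[m], h$feed_table$offered_ndf[m],
                     h$refusal_table$refusal_dm_g, h$refusal_table$refusal_ndf)
  expect_lt(mean(idx), 1)
  expect_true(all(idx > 0 & idx <= 1 + 1e-9))
})

test_that("breed calibration puts lactation-period intakes in the printed range", {
  d <- herd_design()
  h <- simulate_herd(d, seed = 31, profiles = FALSE)
  td <- h$truth$days[h$truth$days$period == 2, ]
  means <- tapply(td$dmi900_true, td$breed, mean)
  expect_gt(means[["Alpine"]], means[["Saanen"]])
  expect_true(all(means > 28 & means < 45))
})

test_that("goat-period trait means have a CV near 30%, latent ICC near its implied value", {
  d <- herd_design()
  v <- variance_spec()
  h <- simulate_herd(d, v, seed = 17, profiles = FALSE)
  agg <- aggregate(dmi900_true ~ goat_id + period, h$truth$days, mean)
  cv <- sd(agg$dmi900_true) / mean(agg$dmi900_true)
  expect_gt(cv, 0.2)
  expect_lt(cv, 0.4)
  # empirical repeatability of true goat-period means tracks implied_icc()
  # (equal breed means so the between-goat variance is just sd_goat^2)
  eq <- list(breed_dmi900 = c(Alpine = 34.3, Saanen = 34.3, other = 34.3))
  est <- vapply(1:30, function(s) {
    hs <- simulate_herd(d, v, seed = s, profiles = FALSE, calibration = eq)
    a <- aggregate(dmi900_true ~ goat_id + period, hs$truth$days, mean)
    repeatability_ratio(a, "dmi900_true")$ratio
  }, numeric(1))
  expect_lt(abs(mean(est) - implied_icc(v, d)), 0.08)
})

test_that("invalid designs and variance specs are rejected", {
  expect_error(herd_design(n_goats = 1), "n_goats")
  expect_error(herd_design(window = 1321), "multiple")
  expect_error(herd_design(resolution = 0), "resolution")
  expect_error(herd_design(breeds = c("A", "S")), "one label per goat")
  expect_error(variance_spec(sd_goat = -1), "SDs")
  expect_error(variance_spec_for_icc(1.2), "icc")
})
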