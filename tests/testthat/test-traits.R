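# Aggregate trait computation, the NDF sorting index and goat x period
# means.

toy_meal <- function(intake = 10, end = 60) {
  structure(list(first_meal_end = end, first_meal_intake = intake,
                 n_segments_in_meal = 1L, complete = TRUE), class = "meal_result")
}

full_profile <- function(y_fun, bw = 50) {
  tt <- seq(0, 1318, 2)
  make_profile(tt, y_fun(tt), bw = bw)
}

test_that("a constant-rate eater has p90 near 0.1 and p180 near 0.2", {
  p <- full_profile(function(t) 0.03 * pmin(t, 900))
  f <- fit_exponential(clip_window(p, 900))
  tr <- compute_traits(p, f, toy_meal())
  # half-open reads: the boundary sample sits one interval before 90/180/900
  expect_equal(tr$p90, 88 / 898, tolerance = 1e-9)
  expect_equal(tr$p180, 178 / 898, tolerance = 1e-9)
  expect_equal(tr$p90, 0.1, tolerance = 0.03)
  expect_equal(tr$p180, 0.2, tolerance = 0.02)
})

test_that("a goat that stops eating after 60 min has p90 = p180 = 1", {
  p <- full_profile(function(t) 0.4 * pmin(t, 60))
  f <- fit_exponential(clip_window(p, 900))
  tr <- compute_traits(p, f, toy_meal(intake = 24))
  expect_equal(tr$p90, 1)
  expect_equal(tr$p180, 1)
  expect_equal(tr$dmi900, tr$ddmi)
  expect_equal(tr$first_meal_dmi, 24)
})

test_that("trait ordering invariants hold on simulated herds across seeds", {
  for (seed in c(1, 2)) {
    h <- small_herd(seed = seed, n_goats = 4, n_periods = 2, n_days = 2)
    tr <- herd_traits(h)
    expect_true(all(tr$dmi90 <= tr$dmi180 + 1e-9))
    expect_true(all(tr$dmi180 <= tr$dmi900 + 1e-9))
    expect_true(all(tr$dmi900 <= tr$ddmi + 1e-9))
    expect_true(all(tr$p90 <= tr$p180 + 1e-9))
    expect_true(all(tr$p180 <= 1 + 1e-9))
    expect_true(all(tr$p90 >= 0))
    expect_true(all(tr$first_meal_dmi <= tr$dmi900 + 1e-9))
    expect_true(all(tr$rmse_ab >= 0))
    expect_true(all(c("a", "ab", "rmse_ab", "ndf_sorting") %in% names(tr)))
  }
})

test_that("the NDF sorting index matches the hand mass balance", {
  # offered 2000 g at 0.40 NDF, refusal 200 g at 0.55 NDF:
  # intake NDF mass = 800 - 110 = 690 over 1800 g -> 0.38333 / 0.40
  expect_equal(ndf_sorting(2000, 0.40, 200, 0.55), (690 / 1800) / 0.40,
               tolerance = 1e-12)
  expect_equal(ndf_sorting(2000, 0.40, 200, 0.55), 0.9583, tolerance = 1e-4)
  expect_equal(ndf_sorting(2000, 0.40, 0, 0.40), 1)       # no refusals
  expect_equal(ndf_sorting(2000, 0.40, 300, 0.40), 1)     # unselective refusal
  # invariant to rescaling all masses
  expect_equal(ndf_sorting(2000, 0.40, 200, 0.55),
               ndf_sorting(20, 0.40, 2, 0.55))
  expect_warning(out <- ndf_sorting(1000, 0.4, 1000, 0.4), "zero intake")
  expect_true(is.na(out))
  expect_error(ndf_sorting(1000, 0.4, 1200, 0.5), "exceed")
  expect_error(ndf_sorting(1000, 1.2, 100, 0.5), "fractions")
})

test_that("p90 and p180 are invariant to body-weight rescaling", {
  h <- small_herd(seed = 6, n_goats = 2, n_periods = 1, n_days = 1)
  key <- paste(h$trough$goat_id, h$trough$period, h$trough$day)
  s <- h$trough[key == key[1], ]
  p1 <- cumulative_intake(s, bw = 50, dm_fraction = 0.55)
  p2 <- cumulative_intake(s, bw = 75, dm_fraction = 0.55)
  window_read <- function(p, m) p$y[max(which(p$t < m))]
  expect_equal(window_read(p1, 90) / window_read(p1, 900),
               window_read(p2, 90) / window_read(p2, 900), tolerance = 1e-12)
})

test_that("goat x period means average available days and flag sparse cells", {
  rec <- toy_records(n_goats = 2, n_periods = 2, n_days = 4)
  # dress the toy table up as trait records with identical day values
  for (tr in trait_names()) rec[[tr]] <- rep(c(1, 2, 3, 4), length.out = nrow(rec))
  rec$ddmi <- rec$dmi900 + 1   # keep ordering plausible
  rec$flagged <- FALSE
  m <- goat_period_means(rec)
  expect_equal(nrow(m), 4)
  expect_equal(m$dmi90, rep(mean(c(1, 2, 3, 4)), 4))
  expect_false(any(m$incomplete))
  # a cell with a single day is flagged
  rec1 <- rec[!(rec$goat_id == "G01" & rec$period == 1 & rec$day > 1), ]
  m1 <- goat_period_means(rec1)
  expect_true(m1$incomplete[m1$goat_id == "G01" & m1$period == 1])
  expect_equal(m1$n_days[m1$goat_id == "G01" & m1$period == 1], 1)
  # identical days mean equals the day value
  rec2 <- rec
  for (tr in trait_names()) rec2[[tr]] <- 7
  expect_true(all(goat_period_means(rec2)$dmi900 == 7))
})

test_that("zero-intake days are excluded from means with a warning", {
  rec <- toy_records(n_goats = 2, n_periods = 1, n_days = 2)
  for (tr in trait_names()) rec[[tr]] <- 5
  rec$flagged <- c(TRUE, rep(FALSE, nrow(rec) - 1))
  expect_warning(m <- goat_period_means(rec), "zero-intake")
  expect_equal(m$n_days[m$goat_id == "G01"], 1)
})
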