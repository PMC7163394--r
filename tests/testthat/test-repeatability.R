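# Nested fixed-effect ANOVA with custom error terms, repeatability
# measures and between-period correlations.

test_that("sequential sums of squares match R's linear-model decomposition", {
  rec <- toy_records(n_goats = 4, n_periods = 2, n_days = 2, seed = 3)
  a <- fit_full_anova(rec, "y")
  d <- data.frame(y = rec$y, breed = factor(rec$breed),
                  goat = factor(rec$goat_id), day = factor(rec$day),
                  period = factor(rec$period))
  o <- oracle_seq_ss(y ~ breed + goat + goat:day + period + breed:period, d)
  expect_equal(a$ss[1:5], o$`Sum Sq`[1:5], tolerance = 1e-9)
  expect_equal(a$df[1:5], o$Df[1:5])
  expect_equal(a$ss[6], o$`Sum Sq`[6], tolerance = 1e-9)  # residual
  expect_equal(a$df[6], o$Df[6])
  # day(goat), period and the interaction keep R's residual-based F tests
  expect_equal(a$f[3:5], o$`F value`[3:5], tolerance = 1e-9)
  # breed is retested against goat-within-breed
  expect_equal(a$f[1], a$ms[1] / a$ms[2], tolerance = 1e-12)
  # unbalanced data still decompose to the same totals
  rec2 <- rec[-c(2, 9), ]
  a2 <- fit_full_anova(rec2, "y")
  expect_equal(sum(a2$ss), sum((rec2$y - mean(rec2$y))^2), tolerance = 1e-9)
})

test_that("F statistics ignore a constant added to all observations", {
  rec <- toy_records(n_goats = 5, n_periods = 2, n_days = 3, seed = 5)
  a1 <- fit_full_anova(rec, "y")
  rec$y <- rec$y + 1000
  a2 <- fit_full_anova(rec, "y")
  expect_equal(a1$f, a2$f, tolerance = 1e-8)
  expect_equal(a1$p, a2$p, tolerance = 1e-8)
})

test_that("the day test is calibrated under a null day effect", {
  d <- herd_design(n_goats = 12, n_periods = 2, n_days = 3)
  v0 <- variance_spec(sd_day = 0)
  pv <- vapply(1:40, function(s) {
    h <- simulate_herd(d, v0, seed = 500 + s, profiles = FALSE)
    within_period_repeatability(fit_full_anova(h$truth$days, "dmi900_true"))$p_value
  }, numeric(1))
  # loose binomial band at 40 replicates; the full calibration runs at 200
  expect_lt(mean(pv < 0.05), 0.2)
  expect_gt(mean(pv), 0.3)
})

test_that("repeatability decisions follow the day-effect p-value and threshold", {
  rec <- toy_records(n_goats = 4, n_periods = 2, n_days = 2, seed = 8)
  a <- fit_full_anova(rec, "y")
  w <- within_period_repeatability(a, threshold = 0.95)
  expect_identical(w$repeatable, w$p_value > 0.95)
  expect_identical(within_period_repeatability(a, threshold = 0)$repeatable, TRUE)
  expect_identical(within_period_repeatability(a, threshold = 1)$repeatable, FALSE)
  expect_equal(within_period_repeatability(a, threshold = 0.5)$threshold, 0.5)
})

test_that("the simplified model tests breed on the goat-within-breed stratum", {
  rec <- toy_records(n_goats = 8, n_periods = 4, n_days = 1, seed = 2)
  names(rec)[names(rec) == "y"] <- "trait"
  a <- fit_simplified_anova(rec, "trait")
  expect_equal(a$error_term[a$effect == "breed"], "goat(breed)")
  expect_equal(a$f[1], a$ms[1] / a$ms[2], tolerance = 1e-12)
  o <- oracle_seq_ss(trait ~ breed + goat + period + breed:period,
                     data.frame(trait = rec$trait, breed = factor(rec$breed),
                                goat = factor(rec$goat_id),
                                period = factor(rec$period)))
  expect_equal(a$ss[1:4], o$`Sum Sq`[1:4], tolerance = 1e-9)
  gm <- attr(a, "group_means")
  expect_equal(nrow(gm$period), 4)
  expect_equal(nrow(gm$breed), 2)
  expect_true(all(nchar(gm$period$letters) >= 1))
})

test_that("duplicating every row leaves simplified-model estimates unchanged", {
  rec <- toy_records(n_goats = 6, n_periods = 3, n_days = 1, seed = 4)
  a1 <- fit_simplified_anova(rec, "y")
  a2 <- fit_simplified_anova(rbind(rec, rec), "y")
  gm1 <- attr(a1, "group_means"); gm2 <- attr(a2, "group_means")
  expect_equal(gm1$period$mean, gm2$period$mean, tolerance = 1e-12)
  expect_equal(gm1$breed$mean, gm2$breed$mean, tolerance = 1e-12)
  # mean squares per effect are identical up to the doubled residual df
  expect_equal(a1$ss[1:4] * 2, a2$ss[1:4], tolerance = 1e-9)
})

test_that("breed test holds its size when breed truly has no effect", {
  pv <- vapply(1:60, function(s) {
    rec <- toy_records(n_goats = 12, n_periods = 4, n_days = 1,
                       seed = 700 + s, breed_gap = 0)
    a <- fit_simplified_anova(rec, "y")
    a$p[a$effect == "breed"]
  }, numeric(1))
  expect_lt(mean(pv < 0.05), 0.17)   # loose band at 60 replicates
})

test_that("between-period correlations are symmetric with exact extremes", {
  rec <- toy_records(n_goats = 8, n_periods = 3, n_days = 1, seed = 6)
  # period 2 duplicates period 1 exactly
  rec$y[rec$period == 2] <- rec$y[rec$period == 1]
  cc <- between_period_correlations(rec, "y")
  expect_equal(cc$r["1", "2"], 1, tolerance = 1e-12)
  expect_identical(cc$r, t(cc$r))
  expect_identical(cc$p, t(cc$p))
  expect_equal(diag(cc$r), c("1" = 1, "2" = 1, "3" = 1))
  expect_equal(cc$stars["1", "2"], "**")
  # too few complete pairs stays NA
  rec2 <- rec[!(rec$period == 3 & rec$goat_id %in% sprintf("G%02d", 1:6)), ]
  cc2 <- between_period_correlations(rec2, "y")
  expect_true(is.na(cc2$r["1", "3"]))
  expect_equal(cc2$n["1", "3"], 2)
})

test_that("repeatability ratio hits the exact endpoints and is affine invariant", {
  tab <- expand.grid(goat_id = c("A", "B", "C"), period = 1:3)
  tab$y <- c(1, 5, 9)[match(tab$goat_id, c("A", "B", "C"))]
  expect_equal(repeatability_ratio(tab, "y")$ratio, 1)   # no within variance
  tab$y <- 4
  expect_equal(repeatability_ratio(tab, "y")$ratio, 0)   # no variance at all
  set.seed(10)
  tab$y <- rnorm(nrow(tab), 10, 2) + c(0, 3, 6)[match(tab$goat_id, c("A", "B", "C"))]
  r1 <- repeatability_ratio(tab, "y")
  tab$y <- 100 - 7 * tab$y
  r2 <- repeatability_ratio(tab, "y")
  expect_equal(r1$ratio, r2$ratio, tolerance = 1e-12)
  expect_error(suppressWarnings(repeatability_ratio(tab[tab$period == 1, ], "y")),
               "two goats")
})
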