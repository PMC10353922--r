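test_that("weekly tallies are exact arithmetic on counts", {
  # week 1 has 1 F + 3 M, week 2 all male
  ds <- make_visits(rep(2000, 5), c(3, 4, 5, 6, 10),
                    c("F", "M", "M", "M", "M"), rep("A", 5))
  s <- weekly_female_proportion(ds, 2000)
  expect_equal(s$week, c(1, 2))
  expect_equal(s$p_female, c(0.25, 0))
  expect_equal(s$n_female + s$n_male, c(4, 1))

  only_m <- make_visits(rep(2000, 3), c(10, 80, 150), rep("M", 3),
                        rep("A", 3))
  expect_true(all(weekly_female_proportion(only_m, 2000)$p_female == 0))
})

test_that("weekly tallies match generator truth totals", {
  sim <- simulate_season(season_config(n_years = 3), seed = 5)
  for (y in unique(sim$data$year)) {
    s <- weekly_female_proportion(sim$data, y)
    tc <- sim$truth$counts
    expect_equal(sum(s$n_female), sum(tc$count[tc$year == y & tc$sex == "F"]))
    expect_equal(sum(s$n_male), sum(tc$count[tc$year == y & tc$sex == "M"]))
  }
})

test_that("overlap window follows the 25-75% female rule", {
  series <- data.frame(year = 2000, week = 1:5,
                       n_female = c(0, 1, 4, 6, 9),
                       n_male = c(10, 9, 6, 4, 1))
  series$p_female <- series$n_female / (series$n_female + series$n_male)
  expect_equal(series$p_female, c(0, 0.1, 0.4, 0.6, 0.9))
  w <- detect_overlap_window(series)
  expect_equal(c(w$start_week, w$end_week), c(3, 4))
  expect_false(w$excluded)

  # all weeks mixed: whole series qualifies
  flat <- data.frame(year = 2000, week = 1:6, n_female = 5, n_male = 5,
                     p_female = 0.5)
  w <- detect_overlap_window(flat)
  expect_equal(c(w$start_week, w$end_week), c(1, 6))

  # never reaches 25% female
  low <- data.frame(year = 2000, week = 1:3, n_female = 0, n_male = 10,
                    p_female = 0)
  expect_true(detect_overlap_window(low)$excluded)
})

test_that("windows spanning too few observation days are excluded", {
  series <- data.frame(year = 2000, week = 24:26,
                       n_female = c(2, 5, 5), n_male = c(8, 5, 5))
  series$p_female <- series$n_female / (series$n_female + series$n_male)
  # only 2 distinct survey days fall inside the detected window (weeks 25-26)
  w <- detect_overlap_window(series, min_days = 4,
                             obs_days = c(150, 170, 175, 200))
  expect_true(w$excluded)
  expect_match(w$reason, "insufficient days")
  w2 <- detect_overlap_window(series, min_days = 2,
                              obs_days = c(150, 170, 175, 200))
  expect_false(w2$excluded)
  expect_equal(w2$n_observation_days, 2)
})

test_that("methods-text end rule is available behind the flag", {
  series <- data.frame(year = 2000, week = 1:5,
                       p_female = c(0, 0.1, 0.4, 0.6, 0.9),
                       n_female = 1, n_male = 1)
  w <- detect_overlap_window(series, rule = "methods")
  # end = the week females first exceed 75%
  expect_equal(c(w$start_week, w$end_week), c(3, 5))
})

test_that("overlap restriction agrees with a brute-force day filter", {
  sim <- simulate_season(season_config(n_years = 6), seed = 13)
  ds <- sim$data
  windows <- overlap_windows(ds)
  kept <- restrict_to_overlap(ds, windows)

  # brute-force oracle: row-by-row membership test
  expected_keep <- vapply(seq_len(nrow(ds)), function(i) {
    w <- windows[windows$year == ds$year[i], ]
    !w$excluded && ds$ordinal_day[i] >= w$start_day &&
      ds$ordinal_day[i] <= w$end_day
  }, logical(1))
  expect_equal(nrow(kept), sum(expected_keep))

  # restriction never increases any per-year per-sex count
  tot <- function(d) tapply(d$count, list(d$year, d$sex), sum, default = 0L)
  full_tot <- tot(ds)
  kept_tot <- tot(kept)
  expect_true(all(kept_tot <= full_tot[rownames(kept_tot),
                                       colnames(kept_tot)]))
})

test_that("window day bounds are inclusive", {
  # records exactly on the window's start and end days are retained
  ds <- make_visits(rep(2000, 6), c(15, 16, 20, 21, 14, 22),
                    c("F", "M", "F", "M", "M", "F"), rep("A", 6))
  windows <- data.frame(year = 2000, start_week = 3, end_week = 3,
                        start_day = 15, end_day = 21,
                        n_observation_days = 4L, excluded = FALSE,
                        reason = "")
  kept <- restrict_to_overlap(ds, windows)
  expect_setequal(kept$ordinal_day, c(15, 16, 20, 21))

  all_excluded <- transform(windows, excluded = TRUE)
  expect_equal(nrow(restrict_to_overlap(ds, all_excluded)), 0)
})

test_that("median dates use the lower-median convention", {
  ds <- make_visits(rep(2000, 4), c(10, 20, 30, 40), rep("F", 4),
                    rep("A", 4))
  med <- median_foraging_dates(ds)
  expect_equal(med$median_day, 20L)  # lower of the middle pair

  wt <- make_visits(rep(2000, 2), c(10, 30), rep("M", 2), c("A", "A"),
                    count = c(3, 1))
  expect_equal(median_foraging_dates(wt)$median_day, 10L)
})

test_that("median-gap regression matches closed-form cases", {
  ds <- make_visits(rep(c(2000, 2001, 2002), each = 2),
                    c(100, 100, 100, 110, 100, 120),
                    rep(c("F", "M"), 3), rep("A", 6))
  # gaps by year: 0, 10, 20
  r <- median_gap_regression(c(`2000` = 0.1, `2001` = 0.3, `2002` = 0.5), ds)
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, 0.02)

  r0 <- median_gap_regression(c(`2000` = 0.2, `2001` = 0.2, `2002` = 0.2), ds)
  expect_equal(r0$slope, 0)
  expect_equal(r0$r_squared, 0)

  expect_error(
    median_gap_regression(c(`2000` = 0.1, `2001` = 0.3), ds),
    ">= 3 years")
})

test_that("median-gap regression recovers a known slope", {
  set.seed(31)
  n <- 24
  gap <- sample(0:30, n, replace = TRUE)
  d <- 0.02 * gap + rnorm(n, 0, 0.05)
  years <- 1991:(1990 + n)
  # build a dataset whose per-year median gap equals `gap`
  ds <- make_visits(rep(years, each = 2),
                    as.vector(rbind(150 + gap, 150)),
                    rep(c("F", "M"), n),
                    rep("A", 2 * n))
  r <- median_gap_regression(stats::setNames(d, years), ds)
  se <- summary(r$fit)$coefficients["gap", "Std. Error"]
  expect_lt(abs(r$slope - 0.02), 3 * se)
})
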