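#' Weekly sex ratio of observations
#'
#' Tallies female and male visits per week within one year. Weeks are fixed
#' 7-day bins anchored at ordinal day 1 (days 1-7 = week 1), deterministic
#' across locales and years. Weeks with no observations are omitted.
#'
#' @param ds A `"visitation"` data.frame.
#' @param year Year to tally.
#' @return A data.frame with columns `year`, `week`, `n_female`, `n_male`,
#'   `p_female` (proportion female; `NaN` only if both are zero, which
#'   cannot occur for emitted weeks).
#' @export
weekly_female_proportion <- function(ds, year) {
  sub <- ds[ds$year == year, , drop = FALSE]
  if (nrow(sub) == 0) stop("no records for year ", year, call. = FALSE)
  wk <- ordinal_week(sub$ordinal_day)
  f <- tapply(sub$count * (sub$sex == "F"), wk, sum, default = 0L)
  m <- tapply(sub$count * (sub$sex == "M"), wk, sum, default = 0L)
  out <- data.frame(
    year = year,
    week = as.integer(names(f)),
    n_female = as.integer(f),
    n_male = as.integer(m),
    row.names = NULL
  )
  out <- out[order(out$week), , drop = FALSE]
  out$p_female <- out$n_female / (out$n_female + out$n_male)
  rownames(out) <- NULL
  out
}

#' @keywords internal
ordinal_week <- function(day) ((as.integer(day) - 1L) %/% 7L) + 1L

week_start_day <- function(week) (week - 1L) * 7L + 1L
week_end_day <- function(week) week * 7L

#' Detect the male-female overlap window for one year
#'
#' The overlap period is defined on weekly female proportions: the window
#' runs from the first week in which females comprise at least `lower`
#' (default 0.25) of observations through the last week in which they
#' comprise no more than `upper` (default 0.75), i.e. the first through last
#' weeks with a mixed sex ratio (`rule = "caption"`). The alternative
#' `rule = "methods"` ends the window at the first week after the start in
#' which the female proportion exceeds `upper`.
#'
#' A year is excluded — excluded is a value carried on the window, not an
#' error — when no qualifying pair of weeks exists, or when fewer than
#' `min_days` distinct observation days fall inside the window (seasons
#' where overlap narrows to a handful of survey days cannot support a
#' within-year comparison).
#'
#' @param series Weekly series from [weekly_female_proportion()].
#' @param min_days Minimum distinct observation days inside the window
#'   (default 4).
#' @param obs_days Optional integer vector of the year's distinct
#'   observation days, used for the `min_days` rule; when `NULL` the rule is
#'   not applied.
#' @param lower,upper Female-proportion thresholds (defaults 0.25, 0.75).
#' @param rule `"caption"` (default) or `"methods"`; see Details.
#' @return A one-row data.frame of class `"overlap_window"` with columns
#'   `year`, `start_week`, `end_week`, `start_day`, `end_day`,
#'   `n_observation_days`, `excluded`, `reason`.
#' @export
detect_overlap_window <- function(series, min_days = 4, obs_days = NULL,
                                  lower = 0.25, upper = 0.75,
                                  rule = c("caption", "methods")) {
  rule <- match.arg(rule)
  stopifnot(nrow(series) > 0, lower < upper)
  year <- series$year[1]
  p <- series$p_female
  wk <- series$week
  start_idx <- which(p >= lower)[1]
  window <- NULL
  if (!is.na(start_idx)) {
    if (rule == "caption") {
      end_idx <- max(which(p <= upper & seq_along(p) >= start_idx), -Inf)
      if (is.finite(end_idx)) window <- c(start_idx, end_idx)
    } else {
      after <- which(p > upper & seq_along(p) >= start_idx)
      end_idx <- if (length(after)) after[1] else length(p)
      window <- c(start_idx, end_idx)
    }
  }
  if (is.null(window)) {
    return(overlap_window_row(year, NA, NA, 0L, TRUE, "no qualifying weeks"))
  }
  sw <- wk[window[1]]; ew <- wk[window[2]]
  ndays <- if (is.null(obs_days)) {
    NA_integer_
  } else {
    length(unique(obs_days[obs_days >= week_start_day(sw) &
                             obs_days <= week_end_day(ew)]))
  }
  if (!is.na(ndays) && ndays < min_days) {
    return(overlap_window_row(year, sw, ew, ndays, TRUE, "insufficient days"))
  }
  overlap_window_row(year, sw, ew, ndays, FALSE, "")
}

overlap_window_row <- function(year, sw, ew, ndays, excluded, reason) {
  out <- data.frame(
    year = year,
    start_week = as.integer(sw), end_week = as.integer(ew),
    start_day = if (is.na(sw)) NA_integer_ else week_start_day(as.integer(sw)),
    end_day = if (is.na(ew)) NA_integer_ else week_end_day(as.integer(ew)),
    n_observation_days = as.integer(ndays),
    excluded = excluded, reason = reason,
    stringsAsFactors = FALSE
  )
  class(out) <- c("overlap_window", "data.frame")
  out
}

#' Overlap windows for every year of a dataset
#'
#' @param ds A `"visitation"` data.frame.
#' @inheritParams detect_overlap_window
#' @return A data.frame with one [detect_overlap_window()] row per year.
#' @export
overlap_windows <- function(ds, min_days = 4, lower = 0.25, upper = 0.75,
                            rule = c("caption", "methods")) {
  rule <- match.arg(rule)
  years <- sort(unique(ds$year))
  rows <- lapply(years, function(y) {
    detect_overlap_window(
      weekly_female_proportion(ds, y),
      min_days = min_days,
      obs_days = unique(ds$ordinal_day[ds$year == y]),
      lower = lower, upper = upper, rule = rule
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("overlap_window", "data.frame")
  out
}

#' Restrict a dataset to per-year overlap windows
#'
#' Keeps exactly the records whose ordinal day lies inside their year's
#' window (bounds inclusive at day resolution); years with an excluded
#' window are dropped entirely.
#'
#' @param ds A `"visitation"` data.frame.
#' @param windows Output of [overlap_windows()].
#' @return A `"visitation"` data.frame.
#' @export
restrict_to_overlap <- function(ds, windows) {
  keep <- rep(FALSE, nrow(ds))
  ok <- windows[!windows$excluded, , drop = FALSE]
  for (i in seq_len(nrow(ok))) {
    keep <- keep | (ds$year == ok$year[i] &
                      ds$ordinal_day >= ok$start_day[i] &
                      ds$ordinal_day <= ok$end_day[i])
  }
  out <- ds[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Median foraging date per year and sex
#'
#' Count-weighted median ordinal day; with an even number of visits the
#' lower median is taken, so the result is always an observed integer day.
#'
#' @param ds A `"visitation"` data.frame.
#' @return A data.frame `year`, `sex`, `median_day`.
#' @export
median_foraging_dates <- function(ds) {
  grp <- interaction(ds$year, ds$sex, drop = TRUE)
  med <- tapply(seq_len(nrow(ds)), grp, function(idx) {
    days <- sort(rep(ds$ordinal_day[idx], ds$count[idx]))
    days[floor((length(days) + 1) / 2)]  # lower median
  })
  keys <- strsplit(names(med), ".", fixed = TRUE)
  data.frame(
    year = as.integer(vapply(keys, `[`, "", 1)),
    sex = vapply(keys, `[`, "", 2),
    median_day = as.integer(med),
    row.names = NULL
  )
}

#' Regress yearly dissimilarity on the male-female median-date gap
#'
#' Interannual variation in how far apart the sexes forage in time should
#' predict how dissimilar their plant use is: ordinary least squares of the
#' per-year Morisita-Horn dissimilarity on the absolute gap (days) between
#' female and male median foraging dates.
#'
#' @param per_year_dmh Named numeric vector of per-year dissimilarities
#'   (names = years).
#' @param ds The `"visitation"` data.frame the medians are computed from.
#' @return List of class `"gap_regression"`: `slope`, `intercept`,
#'   `r_squared`, `adj_r_squared`, `p_value`, `n`, `data`.
#' @export
median_gap_regression <- function(per_year_dmh, ds) {
  med <- median_foraging_dates(ds)
  wide <- merge(med[med$sex == "F", c("year", "median_day")],
                med[med$sex == "M", c("year", "median_day")],
                by = "year", suffixes = c("_f", "_m"))
  wide$gap <- abs(wide$median_day_f - wide$median_day_m)
  d <- data.frame(year = as.integer(names(per_year_dmh)),
                  dmh = as.numeric(per_year_dmh))
  dat <- merge(d, wide[, c("year", "gap")], by = "year")
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < 3) {
    stop("need >= 3 years with both a dissimilarity value and both sexes",
         call. = FALSE)
  }
  fit <- stats::lm(dmh ~ gap, data = dat)
  # degenerate (perfect or constant) fits are handled explicitly below
  sm <- suppressWarnings(summary(fit))
  if (stats::var(dat$dmh) == 0) {
    # constant response: no variation to explain
    r2 <- 0; adj <- 0; p <- 1
  } else if (sm$sigma == 0) {
    # perfectly collinear points
    r2 <- 1; adj <- 1; p <- 0
  } else {
    r2 <- sm$r.squared
    adj <- sm$adj.r.squared
    p <- stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                   lower.tail = FALSE)
  }
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    adj_r_squared = adj,
    p_value = as.numeric(p),
    n = nrow(dat),
    data = dat,
    fit = fit
  ), class = "gap_regression")
}

#' @export
print.gap_regression <- function(x, ...) {
  cat("Dissimilarity ~ |median F day - median M day| (n =", x$n, "years)\n")
  cat(sprintf("  slope = %.4g, R2 = %.3f (adj %.3f), p = %.3g\n",
              x$slope, x$r_squared, x$adj_r_squared, x$p_value))
  invisible(x)
}
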