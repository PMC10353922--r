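#' Build a sex-year plant assemblage
#'
#' The assemblage is the vector of visit counts to each plant species by one
#' sex in one year — the unit on which diversity and dissimilarity are
#' computed.
#'
#' @param ds A `"visitation"` data.frame.
#' @param year Year to select.
#' @param sex `"F"` or `"M"`.
#' @return Named integer vector of visit counts (possibly empty).
#' @export
build_assemblage <- function(ds, year, sex) {
  sub <- ds[ds$year == year & ds$sex == sex, , drop = FALSE]
  if (nrow(sub) == 0) return(stats::setNames(integer(0), character(0)))
  counts <- tapply(sub$count, sub$plant_species, sum)
  stats::setNames(as.integer(counts), names(counts))
}

#' Richness, Shannon entropy and effective species number
#'
#' Shannon entropy H = -sum p_i log p_i (natural log, 0 log 0 = 0) over
#' relative visit frequencies; the effective species number exp(H) is the
#' Hill number of order 1 — the number of equally visited species that
#' would give the same entropy. Unlike raw entropy it is on a species
#' scale, so sex differences read directly as "species' worth" of diversity.
#'
#' @param counts Named or unnamed non-negative count vector with a positive
#'   total.
#' @return List with `richness`, `shannon_H`,
#'   `effective_species_number`.
#' @export
diversity_metrics <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) {
    stop("diversity metrics are undefined for an empty assemblage",
         call. = FALSE)
  }
  p <- counts[counts > 0] / total
  H <- -sum(p * log(p))
  list(richness = sum(counts > 0), shannon_H = H,
       effective_species_number = exp(H))
}

#' Diversity metrics for every sex-year of a dataset
#'
#' @param ds A `"visitation"` data.frame.
#' @return Data.frame with one row per (year, sex) having at least one
#'   visit: `year`, `sex`, `n_visits`, `richness`, `shannon_H`,
#'   `effective_species_number`.
#' @export
diversity_table <- function(ds) {
  combos <- unique(ds[, c("year", "sex")])
  combos <- combos[order(combos$year, combos$sex), , drop = FALSE]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    a <- build_assemblage(ds, combos$year[i], combos$sex[i])
    m <- diversity_metrics(a)
    data.frame(year = combos$year[i], sex = combos$sex[i],
               n_visits = sum(a), richness = m$richness,
               shannon_H = m$shannon_H,
               effective_species_number = m$effective_species_number)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired sex comparison of a diversity metric across years
#'
#' Fits the linear mixed model `metric ~ sex + (1 | year)` by REML, with
#' year as a random intercept to absorb the within-year pairing of male and
#' female values. The reported effect is female minus male, with
#' Satterthwaite degrees of freedom. A singular fit (between-year variance
#' estimated at zero) falls back to a paired t-test, with a message.
#'
#' @param metrics Output of [diversity_table()] (or any data.frame with
#'   `year`, `sex` and the metric column).
#' @param metric Column to analyse, e.g. `"effective_species_number"` or
#'   `"richness"`.
#' @return List of class `"sex_comparison"`: `metric`, `sex_effect`
#'   (female minus male), `se`, `t_stat`, `df`, `p_value`, `n_years`,
#'   `method` (`"lmm"` or `"paired_t"`), `residuals_by_year` (mixed-model
#'   residuals ordered by year), `per_year_sign` (per-year female minus
#'   male differences for years with both sexes).
#' @export
paired_sex_comparison <- function(metrics, metric = "effective_species_number") {
  stopifnot(metric %in% names(metrics))
  d <- data.frame(
    year = factor(metrics$year),
    sex = factor(metrics$sex, levels = c("M", "F")),
    value = metrics[[metric]]
  )
  d <- d[stats::complete.cases(d), , drop = FALSE]
  tab <- table(d$year, d$sex)
  paired_years <- rownames(tab)[tab[, "M"] > 0 & tab[, "F"] > 0]
  if (length(paired_years) < 3) {
    stop("need >= 3 years with both sexes present", call. = FALSE)
  }
  diffs <- vapply(paired_years, function(y) {
    mean(d$value[d$year == y & d$sex == "F"]) -
      mean(d$value[d$year == y & d$sex == "M"])
  }, numeric(1))

  if (stats::sd(diffs) == 0) {
    # no variation in the paired differences: effect is exact, no test
    out <- list(
      metric = metric, sex_effect = mean(diffs), se = 0, t_stat = NA_real_,
      df = NA_real_, p_value = NA_real_, n_years = length(paired_years),
      method = "degenerate", residuals_by_year = rep(0, length(diffs)),
      fit = NULL, per_year_sign = diffs
    )
    class(out) <- "sex_comparison"
    return(out)
  }

  fit <- suppressMessages(
    lmerTest::lmer(value ~ sex + (1 | year), data = d, REML = TRUE)
  )
  singular <- lme4::isSingular(fit, tol = 1e-4)
  if (!singular) {
    co <- stats::coef(summary(fit))["sexF", ]
    res <- stats::residuals(fit)
    ord <- order(as.integer(as.character(d$year)))
    out <- list(
      metric = metric, sex_effect = unname(co["Estimate"]),
      se = unname(co["Std. Error"]), t_stat = unname(co["t value"]),
      df = unname(co["df"]), p_value = unname(co["Pr(>|t|)"]),
      n_years = length(paired_years), method = "lmm",
      residuals_by_year = res[ord], fit = fit
    )
  } else {
    message("singular mixed-model fit (zero between-year variance); ",
            "falling back to a paired t-test")
    tt <- stats::t.test(diffs)
    out <- list(
      metric = metric, sex_effect = unname(tt$estimate),
      se = unname(tt$stderr), t_stat = unname(tt$statistic),
      df = unname(tt$parameter), p_value = tt$p.value,
      n_years = length(paired_years), method = "paired_t",
      residuals_by_year = diffs - mean(diffs), fit = NULL
    )
  }
  out$per_year_sign <- diffs
  class(out) <- "sex_comparison"
  out
}

#' @export
print.sex_comparison <- function(x, ...) {
  cat("Sex comparison of", x$metric, "over", x$n_years, "paired years (",
      x$method, ")\n")
  cat(sprintf("  female - male = %.3f (SE %.3f), t(%.1f) = %.2f, p = %.3g\n",
              x$sex_effect, x$se, x$df, x$t_stat, x$p_value))
  cat(sprintf("  female larger in %d of %d years\n",
              sum(x$per_year_sign > 0), length(x$per_year_sign)))
  invisible(x)
}

#' Residual autocorrelation diagnostics
#'
#' Interannual autocorrelation in diversity metrics would violate the
#' mixed model's independence assumption. Computes the sample
#' autocorrelation function of year-ordered residuals at lags
#' 1..min(max_lag, n - 2) and the Durbin-Watson statistic
#' DW = sum (e_t - e_(t-1))^2 / sum e_t^2 (DW near 2 = no lag-1
#' autocorrelation, toward 0 = positive, toward 4 = negative).
#'
#' @param residuals Numeric residuals ordered by year, or a
#'   `"sex_comparison"` object (its `residuals_by_year` are used).
#' @param max_lag Largest lag to report (default 15).
#' @return List with `acf` (named numeric, lags 1..L) and
#'   `durbin_watson`.
#' @export
residual_time_diagnostics <- function(residuals, max_lag = 15) {
  if (inherits(residuals, "sex_comparison")) {
    residuals <- residuals$residuals_by_year
  }
  e <- as.numeric(residuals)
  n <- length(e)
  if (n < 2) stop("need >= 2 residuals", call. = FALSE)
  L <- min(max_lag, n - 2)
  ac <- if (L >= 1) {
    a <- stats::acf(e, lag.max = L, plot = FALSE, demean = TRUE)
    stats::setNames(as.numeric(a$acf)[-1], seq_len(L))
  } else {
    stats::setNames(numeric(0), character(0))
  }
  dw <- sum(diff(e)^2) / sum(e^2)
  list(acf = ac, durbin_watson = dw)
}
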