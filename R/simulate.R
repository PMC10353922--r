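#' Default flowering community for simulated seasons
#'
#' Six focal nectar species with staggered trapezoidal bloom windows
#' spanning the survey season (ordinal days 153-281) and sex-specific
#' preference weights: the two milkweeds bloom early and carry male-leaning
#' weights, the thistles/beebalm/knapweed bloom mid-to-late season and
#' carry female-leaning weights. Availability ramps linearly from
#' `bloom_start` to `full_start`, plateaus at 1 until `full_end`, and
#' ramps down to 0 at `bloom_end`.
#'
#' @return Data.frame with columns `species`, `bloom_start`, `full_start`,
#'   `full_end`, `bloom_end`, `pref_f`, `pref_m`.
#' @export
default_plants <- function() {
  data.frame(
    species = c("Asclepias syriaca", "Asclepias tuberosa",
                "Cirsium pumilum", "Monarda fistulosa",
                "Centaurea stoebe", "Cirsium discolor"),
    bloom_start = c(153, 155, 160, 170, 175, 215),
    full_start = c(160, 165, 175, 185, 190, 230),
    full_end = c(185, 195, 210, 230, 260, 270),
    bloom_end = c(200, 215, 225, 250, 281, 281),
    pref_f = c(0.5, 1.0, 1.5, 1.6, 1.4, 1.6),
    pref_m = c(2.0, 1.8, 0.9, 0.8, 0.8, 0.8),
    stringsAsFactors = FALSE
  )
}

#' Season simulation configuration
#'
#' Defaults emulate the study system: weekly Pollard-walk surveys over
#' ordinal days 153-281; protandrous flight curves with the male activity
#' peak at day 180 (mid-June emergence), the female peak 14 days later,
#' and a 12-day Gaussian spread per sex; about 150 visits per sex per year
#' (matching a two-decade record of ~6500 observations over 21 years and
#' two sexes); and the [default_plants()] community. A shared per-year
#' phenological shift (`year_shift_sd`, applied identically to both sexes
#' so equal-sex configurations stay exchangeable) produces interannual
#' variation. A fraction `ambiguous_rate` of the two congeners'
#' (`ambiguous_pair`) records is masked to the genus-level
#' `ambiguous_label`.
#'
#' @param n_years Number of seasons (default 21).
#' @param first_year First calendar year (default 1998).
#' @param season Integer `c(first, last)` survey ordinal days.
#' @param survey_interval Days between survey days (default 7, weekly).
#' @param male_peak_day,female_peak_day Flight-curve peaks.
#' @param male_sd,female_sd Flight-curve spreads (days).
#' @param visits_per_sex Expected total visits per sex per year.
#' @param year_shift_sd SD (days) of the shared per-year phenology shift.
#' @param sex_shift_sd SD (days) of an additional per-year, per-sex
#'   phenology shift (default 0). Non-zero values emulate interannual
#'   variation in sex-specific life-history timing — the mechanism that
#'   makes the female-male median-date gap vary between years — at the
#'   cost of exchangeability, so leave at 0 for null-calibration runs.
#' @param plants Flowering community table; see [default_plants()].
#' @param ambiguous_pair Two congeneric species eligible for masking.
#' @param ambiguous_label Genus-level mask label.
#' @param ambiguous_rate Masking probability (default 0.25).
#' @return List of class `"season_config"`.
#' @export
season_config <- function(n_years = 21, first_year = 1998,
                          season = c(153L, 281L), survey_interval = 7,
                          male_peak_day = 180, female_peak_day = 194,
                          male_sd = 12, female_sd = 12,
                          visits_per_sex = 150, year_shift_sd = 5,
                          sex_shift_sd = 0,
                          plants = default_plants(),
                          ambiguous_pair = c("Cirsium pumilum",
                                             "Cirsium discolor"),
                          ambiguous_label = "Cirsium spp.",
                          ambiguous_rate = 0.25) {
  stopifnot(female_peak_day >= male_peak_day,
            all(plants$pref_f > 0), all(plants$pref_m > 0),
            season[1] >= 1, season[2] <= 366, season[1] < season[2])
  structure(list(
    n_years = n_years, first_year = first_year, season = as.integer(season),
    survey_interval = survey_interval, male_peak_day = male_peak_day,
    female_peak_day = female_peak_day, male_sd = male_sd,
    female_sd = female_sd, visits_per_sex = visits_per_sex,
    year_shift_sd = year_shift_sd, sex_shift_sd = sex_shift_sd,
    plants = plants,
    ambiguous_pair = ambiguous_pair, ambiguous_label = ambiguous_label,
    ambiguous_rate = ambiguous_rate
  ), class = "season_config")
}

# trapezoidal bloom availability at a vector of days for one plant row
bloom_availability <- function(day, p) {
  a <- numeric(length(day))
  up <- day >= p$bloom_start & day < p$full_start
  a[up] <- (day[up] - p$bloom_start) / max(p$full_start - p$bloom_start, 1)
  a[day >= p$full_start & day <= p$full_end] <- 1
  dn <- day > p$full_end & day <= p$bloom_end
  a[dn] <- (p$bloom_end - day[dn]) / max(p$bloom_end - p$full_end, 1)
  a
}

#' Simulate multi-year visitation seasons with known truth
#'
#' For each year and sex, visits per survey day are Poisson with intensity
#' proportional to a Gaussian flight curve truncated to the season
#' (normalized over survey days so the expected yearly total is
#' `visits_per_sex`). Each visit's plant is drawn multinomially with
#' probability proportional to bloom availability on that day times the
#' sex's preference weight. A fraction of the two congeners' records is
#' masked to the genus-level label; the pre-mask species is retained as
#' truth.
#'
#' @param cfg A [season_config()].
#' @param seed Optional integer seed.
#' @return List with `data` (a `"visitation"` data.frame, one row per
#'   visit) and `truth`: `counts` (per year-sex-plant true counts),
#'   `masked` (row index, true species for masked records), and
#'   `year_shift` (the shared per-year phenology shifts).
#' @export
simulate_season <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "season_config"))
  if (!is.null(seed)) set.seed(seed)
  survey_days <- seq(cfg$season[1], cfg$season[2], by = cfg$survey_interval)
  years <- cfg$first_year + seq_len(cfg$n_years) - 1L
  shifts <- stats::rnorm(cfg$n_years, 0, cfg$year_shift_sd)
  sex_shifts <- matrix(stats::rnorm(2 * cfg$n_years, 0, cfg$sex_shift_sd),
                       nrow = cfg$n_years, ncol = 2,
                       dimnames = list(NULL, c("F", "M")))
  avail <- sapply(seq_len(nrow(cfg$plants)), function(i) {
    bloom_availability(survey_days, cfg$plants[i, ])
  })  # days x plants

  rows <- list()
  for (yi in seq_len(cfg$n_years)) {
    for (sex in c("F", "M")) {
      peak <- (if (sex == "F") cfg$female_peak_day else cfg$male_peak_day) +
        shifts[yi] + sex_shifts[yi, sex]
      sdv <- if (sex == "F") cfg$female_sd else cfg$male_sd
      w <- stats::dnorm(survey_days, peak, sdv)
      if (sum(w) <= 0) next
      lambda <- cfg$visits_per_sex * w / sum(w)
      n_day <- stats::rpois(length(survey_days), lambda)
      pref <- if (sex == "F") cfg$plants$pref_f else cfg$plants$pref_m
      for (di in which(n_day > 0)) {
        prob <- avail[di, ] * pref
        if (sum(prob) <= 0) next  # nothing blooming: visits unrealized
        picks <- sample.int(nrow(cfg$plants), n_day[di], replace = TRUE,
                            prob = prob)
        rows[[length(rows) + 1L]] <- data.frame(
          year = years[yi], ordinal_day = survey_days[di], sex = sex,
          plant_species = cfg$plants$species[picks], count = 1L,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0) {
    ds <- visitation_dataset(integer(0), integer(0), character(0),
                             character(0))
    return(list(data = ds,
                truth = list(counts = data.frame(year = integer(0),
                                                 sex = character(0),
                                                 plant_species = character(0),
                                                 count = integer(0)),
                             masked = data.frame(row = integer(0),
                                                 true_species = character(0)),
                             year_shift = shifts)))
  }
  df <- do.call(rbind, rows)
  truth_counts <- stats::aggregate(count ~ year + sex + plant_species,
                                   data = df, sum)
  truth_counts <- truth_counts[order(truth_counts$year, truth_counts$sex,
                                     truth_counts$plant_species), ]
  rownames(truth_counts) <- NULL

  maskable <- which(df$plant_species %in% cfg$ambiguous_pair)
  masked_idx <- maskable[stats::runif(length(maskable)) < cfg$ambiguous_rate]
  masked <- data.frame(row = masked_idx,
                       true_species = df$plant_species[masked_idx],
                       stringsAsFactors = FALSE)
  df$plant_species[masked_idx] <- cfg$ambiguous_label

  ds <- visitation_dataset(df$year, df$ordinal_day, df$sex,
                           df$plant_species, df$count)
  list(data = ds,
       truth = list(counts = truth_counts, masked = masked,
                    year_shift = shifts))
}

#' Simulate a nectar metabolite panel with known truth
#'
#' Draws per-replicate concentrations log-normally with species- and
#' compound-specific moments (the log-normal is moment-matched so `mean`
#' and `sd` are on the concentration scale; `sd = 0` yields constant
#' replicates). An optional additive `shift` raises the mean of every
#' compound for species in `female_species`, giving a known
#' female-minus-male group effect for recovery tests.
#'
#' @param profiles Data.frame with columns `species`, `compound`, `mean`,
#'   `sd` (one row per species x compound).
#' @param n_reps Replicates per species: a single number or a named vector
#'   per species (e.g. 13 for most species, 8 for one with limited
#'   nectar).
#' @param shift Additive mean shift for `female_species` (default 0).
#' @param female_species Species receiving the shift.
#' @param seed Optional integer seed.
#' @return List with `samples` (a `"nectar"` data.frame) and `truth`
#'   (profiles with the effective, post-shift means).
#' @export
simulate_nectar_panel <- function(profiles, n_reps = 13, shift = 0,
                                  female_species = character(0),
                                  seed = NULL) {
  stopifnot(all(c("species", "compound", "mean", "sd") %in% names(profiles)),
            all(profiles$sd >= 0))
  if (!is.null(seed)) set.seed(seed)
  species <- unique(profiles$species)
  reps <- if (length(n_reps) == 1 && is.null(names(n_reps))) {
    stats::setNames(rep(n_reps, length(species)), species)
  } else {
    stopifnot(all(species %in% names(n_reps)))
    n_reps[species]
  }
  truth <- profiles
  truth$mean <- truth$mean + ifelse(truth$species %in% female_species,
                                    shift, 0)
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    sp <- truth$species[i]
    n <- reps[[sp]]
    m <- truth$mean[i]; s <- truth$sd[i]
    conc <- if (s == 0) {
      rep(m, n)
    } else {
      sdlog <- sqrt(log(1 + s^2 / m^2))
      meanlog <- log(m) - sdlog^2 / 2
      stats::rlnorm(n, meanlog, sdlog)
    }
    data.frame(species = sp, sample_id = paste0(sp, "_", seq_len(n)),
               compound = truth$compound[i], concentration = conc,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  samples <- nectar_table(df$species, df$sample_id, df$compound,
                          df$concentration)
  list(samples = samples, truth = truth)
}
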