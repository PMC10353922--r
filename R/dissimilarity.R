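#' Sex-by-plant contingency table for one year
#'
#' @param ds A `"visitation"` data.frame.
#' @param year Year to tabulate.
#' @return Integer matrix with rows `F`, `M` and one column per plant
#'   species visited that year (species unvisited by both sexes are
#'   absent).
#' @export
year_table <- function(ds, year) {
  sub <- ds[ds$year == year, , drop = FALSE]
  if (nrow(sub) == 0) stop("no records for year ", year, call. = FALSE)
  if (length(unique(sub$sex)) < 2) {
    stop("year ", year, " has records for only one sex; ",
         "dissimilarity is not computable",
         call. = FALSE)
  }
  sex_plant_table(sub)
}

# shared tabulation for year_table() and pooled_table()
sex_plant_table <- function(sub) {
  species <- sort(unique(sub$plant_species))
  tab <- matrix(0L, nrow = 2, ncol = length(species),
                dimnames = list(c("F", "M"), species))
  agg <- tapply(sub$count, list(sub$sex, sub$plant_species), sum, default = 0L)
  tab[rownames(agg), colnames(agg)] <- agg
  tab[, colSums(tab) > 0, drop = FALSE]
}

#' Morisita-Horn dissimilarity between two assemblages
#'
#' Abundance-based Horn modification of Morisita's index:
#' `d = 1 - 2 * sum(x_i y_i) / ((sum(x_i^2)/X^2 + sum(y_i^2)/Y^2) * X * Y)`
#' with totals `X = sum(x)`, `Y = sum(y)`. It compares the probability that
#' two draws, one from each assemblage, are the same species against the
#' within-assemblage analogue, so 0 means identical relative composition
#' and 1 means no shared species. The value is invariant to proportional
#' scaling of either assemblage and symmetric in its arguments; rounding
#' is clamped to the unit interval.
#'
#' @param x,y Non-negative count vectors. If both are named, they are
#'   aligned on the union of names; otherwise they are matched by position
#'   and must have equal length.
#' @return Dissimilarity in \[0, 1\].
#' @export
morisita_horn <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    sp <- union(names(x), names(y))
    x <- ifelse(is.na(x[sp]), 0, x[sp])
    y <- ifelse(is.na(y[sp]), 0, y[sp])
  } else if (length(x) != length(y)) {
    stop("unnamed count vectors must have equal length", call. = FALSE)
  }
  x <- as.numeric(x); y <- as.numeric(y)
  X <- sum(x); Y <- sum(y)
  if (X <= 0 || Y <= 0) {
    stop("Morisita-Horn is undefined for an empty assemblage", call. = FALSE)
  }
  C <- 2 * sum(x * y) / ((sum(x^2) / X^2 + sum(y^2) / Y^2) * X * Y)
  min(max(1 - C, 0), 1)
}

#' Sample a random contingency table with fixed margins
#'
#' Patefield's algorithm: draws a table uniformly from the permutation
#' (generalized hypergeometric) null — the distribution obtained by
#' randomly re-pairing individual visits' row labels with column labels —
#' by filling each row cell-by-cell from the conditional hypergeometric
#' distribution given what remains of the margins.
#'
#' @param row_margins,col_margins Non-negative integer margins with equal
#'   sums.
#' @return Integer matrix with exactly the given margins.
#' @export
patefield_sample <- function(row_margins, col_margins) {
  r <- as.integer(row_margins); cc <- as.integer(col_margins)
  if (sum(r) != sum(cc)) stop("margin sums differ", call. = FALSE)
  R <- length(r); C <- length(cc)
  out <- matrix(0L, R, C, dimnames = list(names(row_margins),
                                          names(col_margins)))
  remaining_cols <- cc
  total <- sum(r)
  for (i in seq_len(max(R - 1L, 0L))) {
    left <- r[i]
    Trem <- total
    for (j in seq_len(C)) {
      # draw this cell from Hypergeom(col remainder, rest, row remainder)
      x <- stats::rhyper(1, remaining_cols[j], Trem - remaining_cols[j], left)
      out[i, j] <- x
      left <- left - x
      Trem <- Trem - remaining_cols[j]
    }
    remaining_cols <- remaining_cols - out[i, ]
    total <- total - r[i]
  }
  if (R >= 1) out[R, ] <- remaining_cols
  out
}

# vectorized sampler for 2-row tables: returns an n x C matrix of row-1
# cells; row 2 is col_margins minus the result. Same distribution as
# patefield_sample(), drawn for n replicate tables at once.
patefield_row1 <- function(row1_total, col_margins, n) {
  C <- length(col_margins)
  left <- rep(row1_total, n)
  Trem <- sum(col_margins)
  out <- matrix(0L, n, C)
  for (j in seq_len(C)) {
    x <- stats::rhyper(n, col_margins[j], Trem - col_margins[j], left)
    out[, j] <- x
    left <- left - x
    Trem <- Trem - col_margins[j]
  }
  out
}

# Morisita-Horn for each row pair (A[i, ], B[i, ]) of two count matrices
morisita_horn_rows <- function(A, B) {
  X <- rowSums(A); Y <- rowSums(B)
  C <- 2 * rowSums(A * B) / ((rowSums(A^2) / X^2 + rowSums(B^2) / Y^2) * X * Y)
  pmin(pmax(1 - C, 0), 1)
}

#' Permutation test of sex-specific foraging dissimilarity
#'
#' Scores the observed female/male Morisita-Horn dissimilarity of a
#' sex-by-plant table against `n_reps` random tables with identical
#' margins (Patefield swap: the same number of female and male visits and
#' the same per-plant totals, with sex-plant links randomized). The null
#' band is the central `ci_level` percentile interval of the null values
#' (linear-interpolation quantiles, type 7); `ci_type = "sd"` uses a
#' normal-theory band (mean +/- z * SD) instead. Observed values above the
#' band indicate the sexes forage more dissimilarly than random
#' re-pairing allows; below, more similarly.
#'
#' @param table 2-row matrix from [year_table()] or [pooled_table()].
#' @param n_reps Number of null tables (default 1000).
#' @param ci_level Null band coverage (default 0.95).
#' @param ci_type `"percentile"` (default) or `"sd"`.
#' @param seed Optional integer seed for a self-contained, reproducible
#'   draw.
#' @return List of class `"null_test"`: `observed_dmh`, `null_values`,
#'   `ci_lower`, `ci_upper`, `classification` (`"above"`, `"within"`,
#'   `"below"`), `n_reps`, `ci_level`, `ci_type`, `seed`.
#' @export
null_test <- function(table, n_reps = 1000, ci_level = 0.95,
                      ci_type = c("percentile", "sd"), seed = NULL) {
  ci_type <- match.arg(ci_type)
  stopifnot(nrow(table) == 2, n_reps >= 1)
  if (any(rowSums(table) <= 0)) {
    stop("both row margins must be positive", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  obs <- morisita_horn(table[1, ], table[2, ])
  if (ncol(table) == 1) {
    # a single plant species: every table (and the observed one) has d = 0
    out <- list(observed_dmh = obs, null_values = rep(0, n_reps),
                ci_lower = 0, ci_upper = 0, classification = "within",
                n_reps = n_reps, ci_level = ci_level, ci_type = ci_type,
                seed = seed)
    class(out) <- "null_test"
    return(out)
  }
  cm <- as.integer(colSums(table))
  A <- patefield_row1(as.integer(sum(table[1, ])), cm, n_reps)
  B <- matrix(cm, nrow = n_reps, ncol = length(cm), byrow = TRUE) - A
  nulls <- morisita_horn_rows(A, B)
  alpha <- (1 - ci_level) / 2
  if (ci_type == "percentile") {
    ci <- stats::quantile(nulls, c(alpha, 1 - alpha), names = FALSE, type = 7)
  } else {
    z <- stats::qnorm(1 - alpha)
    ci <- mean(nulls) + c(-1, 1) * z * stats::sd(nulls)
  }
  classification <- if (obs > ci[2]) "above" else if (obs < ci[1]) "below"
    else "within"
  out <- list(observed_dmh = obs, null_values = nulls,
              ci_lower = ci[1], ci_upper = ci[2],
              classification = classification, n_reps = n_reps,
              ci_level = ci_level, ci_type = ci_type, seed = seed)
  class(out) <- "null_test"
  out
}

#' @export
print.null_test <- function(x, ...) {
  cat(sprintf(
    "Morisita-Horn null test: observed d = %.3f, null %g%% CI [%.3f, %.3f] -> %s (%d reps)\n",
    x$observed_dmh, 100 * x$ci_level, x$ci_lower, x$ci_upper,
    x$classification, x$n_reps))
  invisible(x)
}

#' Per-year dissimilarity null tests for a dataset
#'
#' Runs [null_test()] on every year's sex-by-plant table. Years with only
#' one sex are reported as non-computable (`NA` dissimilarity,
#' classification `"not_computable"`). A master seed spawns one stream per
#' year so results do not depend on year ordering.
#'
#' @param ds A `"visitation"` data.frame.
#' @param n_reps,ci_level,ci_type Passed to [null_test()].
#' @param seed Optional master seed.
#' @return Data.frame with columns `year`, `observed_dmh`, `ci_lower`,
#'   `ci_upper`, `classification`, plus the list of full `"null_test"`
#'   objects as attribute `"tests"`.
#' @export
yearly_null_tests <- function(ds, n_reps = 1000, ci_level = 0.95,
                              ci_type = c("percentile", "sd"), seed = NULL) {
  ci_type <- match.arg(ci_type)
  years <- sort(unique(ds$year))
  tests <- vector("list", length(years))
  names(tests) <- years
  yseeds <- if (is.null(seed)) NULL else year_seeds(seed, length(years))
  rows <- lapply(seq_along(years), function(i) {
    y <- years[i]
    yseed <- if (is.null(seed)) NULL else yseeds[i]
    res <- tryCatch(
      null_test(year_table(ds, y), n_reps = n_reps, ci_level = ci_level,
                ci_type = ci_type, seed = yseed),
      error = function(e) NULL
    )
    tests[[i]] <<- res
    if (is.null(res)) {
      data.frame(year = y, observed_dmh = NA_real_, ci_lower = NA_real_,
                 ci_upper = NA_real_, classification = "not_computable",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(year = y, observed_dmh = res$observed_dmh,
                 ci_lower = res$ci_lower, ci_upper = res$ci_upper,
                 classification = res$classification,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "tests") <- tests
  out
}

# spawn well-scattered per-year seeds from a master seed; the i-th sorted
# year always receives the i-th seed, so results are order-independent
year_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(2147483646L, n)
}
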