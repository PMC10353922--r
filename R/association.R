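#' Pooled sex-by-plant table across years
#'
#' Individual years rarely support a chi-squared test cell-wise, so visits
#' are pooled over years (optionally a subset, e.g. only years with
#' significant dissimilarity) before testing for sex-plant association.
#'
#' @param ds A `"visitation"` data.frame.
#' @param years Optional vector of years to pool; default all.
#' @return Integer matrix with rows `F`, `M` (a missing sex yields a zero
#'   row) and one column per visited plant species.
#' @export
pooled_table <- function(ds, years = NULL) {
  sub <- if (is.null(years)) ds else ds[ds$year %in% years, , drop = FALSE]
  if (nrow(sub) == 0) stop("no records to pool", call. = FALSE)
  sex_plant_table(sub)
}

#' Chi-squared test of sex-plant visitation association
#'
#' Pearson's chi-squared test of independence on a 2 x S sex-by-plant
#' table (no continuity correction), with per-cell Pearson residuals
#' `(O - E) / sqrt(E)`. Species are labeled by the female-row residual:
#' greater than `residual_threshold` is female-associated, less than its
#' negative is male-associated, otherwise neutral; the default threshold 2
#' approximates a standard-normal criterion.
#'
#' @param table 2 x S matrix from [pooled_table()] or [year_table()].
#' @param min_expected Cells with expected counts below this (default 5)
#'   are listed in a warning; the test is still computed.
#' @param residual_threshold Association labeling cutoff (default 2).
#' @return List of class `"sex_association"`: `table`, `chi2`, `df`,
#'   `p_value`, `expected`, `pearson_residuals`, `species_labels` (named
#'   character: `"female_associated"`, `"male_associated"`, `"neutral"`).
#' @export
chi_squared_association <- function(table, min_expected = 5,
                                    residual_threshold = 2) {
  stopifnot(is.matrix(table), nrow(table) == 2)
  if (is.null(rownames(table))) rownames(table) <- c("F", "M")
  if (is.null(colnames(table))) {
    colnames(table) <- paste0("sp", seq_len(ncol(table)))
  }
  if (sum(table) <= 0 || any(rowSums(table) <= 0)) {
    stop("both sexes need at least one visit", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  low <- which(ht$expected < min_expected, arr.ind = TRUE)
  if (nrow(low)) {
    warning("expected count < ", min_expected, " in cell(s): ",
            paste(sprintf("(%s, %s)", rownames(table)[low[, 1]],
                          colnames(table)[low[, 2]]), collapse = ", "),
            call. = FALSE)
  }
  resid_f <- ht$residuals["F", ]
  labels <- ifelse(resid_f > residual_threshold, "female_associated",
                   ifelse(resid_f < -residual_threshold, "male_associated",
                          "neutral"))
  out <- list(
    table = table,
    chi2 = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    expected = ht$expected,
    pearson_residuals = ht$residuals,
    species_labels = stats::setNames(labels, colnames(table)),
    residual_threshold = residual_threshold
  )
  class(out) <- "sex_association"
  out
}

#' @export
print.sex_association <- function(x, ...) {
  cat(sprintf("Sex-plant association: chi2 = %.2f, df = %d, p = %.3g\n",
              x$chi2, x$df, x$p_value))
  fa <- names(x$species_labels)[x$species_labels == "female_associated"]
  ma <- names(x$species_labels)[x$species_labels == "male_associated"]
  if (length(fa)) cat("  female-associated:", paste(fa, collapse = ", "), "\n")
  if (length(ma)) cat("  male-associated:  ", paste(ma, collapse = ", "), "\n")
  invisible(x)
}
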