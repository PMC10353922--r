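#' Pipeline configuration
#'
#' Houses the analysis constants: overlap-window thresholds (0.25/0.75
#' female) and minimum observation days, the number of null-model
#' replicates (1000) and null-band coverage (0.95), the association
#' residual threshold, and the nectar outlier rule (4 SD) and Bonferroni
#' families.
#'
#' @param overlap_lower,overlap_upper Female-proportion window thresholds.
#' @param min_days Minimum distinct observation days in a window.
#' @param overlap_rule `"caption"` or `"methods"`; see
#'   [detect_overlap_window()].
#' @param n_reps Null-model replicates per year.
#' @param ci_level Null-band coverage.
#' @param ci_type `"percentile"` or `"sd"`.
#' @param seed Master seed; per-year streams are derived from it.
#' @param residual_threshold Association labeling cutoff.
#' @param nectar_k Outlier SD multiplier.
#' @param nectar_families Named list of compound vectors (Bonferroni
#'   families).
#' @param ambiguous_label Genus-level label to resolve before analysis.
#' @param out_dir Optional output directory for TSV/JSON reports.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(overlap_lower = 0.25, overlap_upper = 0.75,
                            min_days = 4,
                            overlap_rule = c("caption", "methods"),
                            n_reps = 1000, ci_level = 0.95,
                            ci_type = c("percentile", "sd"),
                            seed = 1L, residual_threshold = 2,
                            nectar_k = 4,
                            nectar_families = list(
                              carbohydrates = c("glucose", "fructose",
                                                "sucrose", "maltose",
                                                "total_carbohydrates"),
                              amino_acids = c("proline", "glycine",
                                              "leucine",
                                              "total_amino_acids")
                            ),
                            ambiguous_label = "Cirsium spp.",
                            out_dir = NULL) {
  stopifnot(0 < overlap_lower, overlap_lower < overlap_upper,
            overlap_upper < 1, n_reps >= 1)
  structure(list(
    overlap_lower = overlap_lower, overlap_upper = overlap_upper,
    min_days = min_days, overlap_rule = match.arg(overlap_rule),
    n_reps = n_reps, ci_level = ci_level, ci_type = match.arg(ci_type),
    seed = as.integer(seed), residual_threshold = residual_threshold,
    nectar_k = nectar_k, nectar_families = nectar_families,
    ambiguous_label = ambiguous_label, out_dir = out_dir
  ), class = "pipeline_config")
}

#' Run the full sex-specific foraging analysis
#'
#' End-to-end orchestration: validate, resolve ambiguous congener labels,
#' full-season analyses (per-year dissimilarity null tests, diversity
#' mixed-model comparisons, pooled chi-squared association), overlap
#' window detection and the same analyses on the overlap-restricted
#' dataset, the dissimilarity-vs-median-gap regression, and (when a
#' nectar table is supplied) the nectar contrast analysis using the
#' full-season association labels. When `cfg$out_dir` is set, writes
#' per-year TSV tables and a JSON bundle.
#'
#' @param ds A `"visitation"` data.frame or path to a visitation CSV.
#' @param nectar Optional `"nectar"` data.frame or path to a nectar CSV.
#' @param cfg A [pipeline_config()].
#' @return List of class `"report_bundle"`; see the elements in the
#'   source ordering: `validation`, `classifier`, `windows`,
#'   `full` / `overlap` (each with `dissimilarity`, `diversity`,
#'   `comparisons`, `association`), `gap_regression`, `nectar`,
#'   `provenance`.
#' @export
run_pipeline <- function(ds, nectar = NULL, cfg = pipeline_config()) {
  if (is.character(ds)) ds <- read_visitation(ds)
  if (is.character(nectar)) nectar <- read_nectar(nectar)

  validation <- validate_dataset(ds, ambiguous_label = cfg$ambiguous_label)
  clf <- NULL
  if (validation$n_ambiguous > 0) {
    clf <- fit_phenology_classifier(ds)
    ds <- assign_ambiguous(ds, clf, ambiguous_label = cfg$ambiguous_label)
  }

  analyse <- function(data, seed_offset) {
    if (nrow(data) == 0) return(NULL)
    dis <- yearly_null_tests(data, n_reps = cfg$n_reps,
                             ci_level = cfg$ci_level, ci_type = cfg$ci_type,
                             seed = cfg$seed + seed_offset)
    div <- diversity_table(data)
    comparisons <- lapply(
      stats::setNames(nm = c("richness", "effective_species_number")),
      function(m) tryCatch(paired_sex_comparison(div, m),
                           error = function(e) NULL)
    )
    assoc <- tryCatch(
      chi_squared_association(pooled_table(data),
                              residual_threshold = cfg$residual_threshold),
      error = function(e) NULL
    )
    list(dissimilarity = dis, diversity = div, comparisons = comparisons,
         association = assoc)
  }

  full <- analyse(ds, 0L)
  windows <- overlap_windows(ds, min_days = cfg$min_days,
                             lower = cfg$overlap_lower,
                             upper = cfg$overlap_upper,
                             rule = cfg$overlap_rule)
  ds_overlap <- restrict_to_overlap(ds, windows)
  overlap <- analyse(ds_overlap, 1000000L)

  gap <- tryCatch({
    dmh <- stats::setNames(full$dissimilarity$observed_dmh,
                           full$dissimilarity$year)
    median_gap_regression(dmh, ds)
  }, error = function(e) NULL)

  nectar_res <- NULL
  if (!is.null(nectar)) {
    nectar_res <- nectar_contrasts(nectar, full$association$species_labels,
                                   families = cfg$nectar_families,
                                   k = cfg$nectar_k)
  }

  bundle <- structure(list(
    validation = validation, classifier = clf, windows = windows,
    full = full, overlap = overlap, gap_regression = gap,
    nectar = nectar_res,
    provenance = list(seed = cfg$seed, n_reps = cfg$n_reps,
                      ci_level = cfg$ci_level, ci_type = cfg$ci_type,
                      overlap_rule = cfg$overlap_rule,
                      package_version = as.character(
                        utils::packageVersion("sexforage")))
  ), class = "report_bundle")

  if (!is.null(cfg$out_dir)) write_report_bundle(bundle, cfg$out_dir)
  bundle
}

#' Write a report bundle to TSV and JSON
#'
#' @param bundle A `"report_bundle"` from [run_pipeline()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  if (!is.null(bundle$full)) {
    tsv(bundle$full$dissimilarity, "dissimilarity_full.tsv")
    tsv(bundle$full$diversity, "diversity_full.tsv")
  }
  if (!is.null(bundle$overlap)) {
    tsv(bundle$overlap$dissimilarity, "dissimilarity_overlap.tsv")
    tsv(bundle$overlap$diversity, "diversity_overlap.tsv")
  }
  tsv(as.data.frame(bundle$windows), "overlap_windows.tsv")
  jsonlite::write_json(report_bundle_json(bundle),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# JSON-serializable summary of a bundle (drops model objects)
report_bundle_json <- function(bundle) {
  comp_json <- function(cmp) {
    if (is.null(cmp)) return(NULL)
    cmp[c("metric", "sex_effect", "se", "t_stat", "df", "p_value",
          "n_years", "method")]
  }
  sec_json <- function(sec) {
    if (is.null(sec)) return(NULL)
    list(
      dissimilarity = sec$dissimilarity,
      mean_dmh = mean(sec$dissimilarity$observed_dmh, na.rm = TRUE),
      n_above = sum(sec$dissimilarity$classification == "above"),
      comparisons = lapply(sec$comparisons, comp_json),
      association = list(chi2 = sec$association$chi2,
                         df = sec$association$df,
                         p_value = sec$association$p_value,
                         species_labels = as.list(
                           sec$association$species_labels))
    )
  }
  list(
    full = sec_json(bundle$full),
    overlap = sec_json(bundle$overlap),
    windows = as.data.frame(bundle$windows),
    gap_regression = if (is.null(bundle$gap_regression)) NULL else
      bundle$gap_regression[c("slope", "intercept", "r_squared",
                              "adj_r_squared", "p_value", "n")],
    nectar = if (is.null(bundle$nectar)) NULL else
      lapply(bundle$nectar$contrasts, function(fam) {
        lapply(fam, function(r) {
          r[c("compound", "estimate", "se", "f_stat", "num_df", "den_df",
              "p_value", "alpha_adjusted", "significant")]
        })
      }),
    provenance = bundle$provenance
  )
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("== Sex-specific foraging report ==\n")
  print(x$validation)
  if (!is.null(x$full)) {
    cat("\nFull season:\n")
    cat(sprintf("  mean d_mh = %.3f; above-null years: %d of %d\n",
                mean(x$full$dissimilarity$observed_dmh, na.rm = TRUE),
                sum(x$full$dissimilarity$classification == "above"),
                nrow(x$full$dissimilarity)))
    if (!is.null(x$full$comparisons$effective_species_number)) {
      print(x$full$comparisons$effective_species_number)
    }
    print(x$full$association)
  }
  if (!is.null(x$overlap)) {
    cat("\nOverlap period (", sum(!x$windows$excluded), "of",
        nrow(x$windows), "years retained):\n")
    cat(sprintf("  mean d_mh = %.3f; above-null years: %d of %d\n",
                mean(x$overlap$dissimilarity$observed_dmh, na.rm = TRUE),
                sum(x$overlap$dissimilarity$classification == "above"),
                nrow(x$overlap$dissimilarity)))
    print(x$overlap$association)
  }
  if (!is.null(x$gap_regression)) print(x$gap_regression)
  if (!is.null(x$nectar)) print(x$nectar)
  invisible(x)
}
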