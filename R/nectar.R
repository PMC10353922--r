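#' Screen nectar concentration outliers
#'
#' Removes individual concentration values lying more than `k` standard
#' deviations from the mean of their species x compound group. The mean and
#' SD for each candidate are computed from the other members of its group
#' (leave-one-out): with the candidate included, the largest attainable
#' deviation in a group of n values is (n - 1)/sqrt(n) SDs — about 3.3 at
#' n = 13 — so a 4-SD rule would be unsatisfiable by construction. Groups
#' with fewer than 3 values are left unscreened. A candidate identical to a
#' zero-spread remainder is never removed.
#'
#' @param samples A `"nectar"` data.frame (see [read_nectar()]).
#' @param k SD multiplier (default 4).
#' @return List with `samples` (filtered table) and `report`, a data.frame
#'   of removals (`species`, `sample_id`, `compound`, `value`, `z_score`)
#'   of class `"outlier_report"` carrying the rule as attribute `"k"`.
#' @export
remove_outliers <- function(samples, k = 4) {
  grp <- interaction(samples$species, samples$compound, drop = TRUE)
  z <- rep(0, nrow(samples))
  drop <- rep(FALSE, nrow(samples))
  for (g in levels(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 3) next
    v <- samples$concentration[idx]
    for (j in seq_along(idx)) {
      rest <- v[-j]
      s <- stats::sd(rest)
      dev <- v[j] - mean(rest)
      z[idx[j]] <- if (s > 0) dev / s else if (dev == 0) 0 else
        sign(dev) * Inf
      drop[idx[j]] <- abs(dev) > k * s
    }
  }
  report <- data.frame(
    species = samples$species[drop],
    sample_id = samples$sample_id[drop],
    compound = samples$compound[drop],
    value = samples$concentration[drop],
    z_score = z[drop],
    stringsAsFactors = FALSE
  )
  attr(report, "k") <- k
  class(report) <- c("outlier_report", "data.frame")
  out <- samples[!drop, , drop = FALSE]
  rownames(out) <- NULL
  list(samples = out, report = report)
}

#' Total concentration per sample over a compound family
#'
#' Adds a derived "total" compound per (species, sample_id), summing over
#' `compounds` (default: every compound present, i.e. totals over all
#' detected compounds in the panel).
#'
#' @param samples A `"nectar"` data.frame.
#' @param name Name for the derived compound, e.g.
#'   `"total_carbohydrates"`.
#' @param compounds Optional character vector restricting the sum.
#' @return The input with the derived rows appended.
#' @export
total_concentration <- function(samples, name, compounds = NULL) {
  sub <- if (is.null(compounds)) samples else
    samples[samples$compound %in% compounds, , drop = FALSE]
  if (nrow(sub) == 0) stop("no compounds to total", call. = FALSE)
  tot <- stats::aggregate(concentration ~ species + sample_id, data = sub, sum)
  tot$compound <- name
  out <- rbind(samples, tot[, c("species", "sample_id", "compound",
                                "concentration")])
  rownames(out) <- NULL
  class(out) <- class(samples)
  out
}

#' Planned contrast of female- vs male-associated species nectar
#'
#' Compares one compound's concentration between the female- and
#' male-associated species groups under a heterogeneous-variance model:
#' each species has its own mean and its own residual variance (variances
#' among species differ strongly for most nectar metabolites, so a pooled
#' variance would mis-weight the contrast). The planned contrast is the
#' mean of female-associated species means minus the mean of
#' male-associated species means, with
#' `Var(L) = sum(c_i^2 s_i^2 / n_i)`, `F = (L / SE)^2` on 1 numerator df,
#' and Welch-Satterthwaite denominator df. The pooled residual df
#' `sum(n_i - 1)` is reported alongside for comparison.
#'
#' @param samples A `"nectar"` data.frame.
#' @param labels Named character vector mapping species to
#'   `"female_associated"` / `"male_associated"` (e.g. `species_labels`
#'   from [chi_squared_association()]); other labels are ignored.
#' @param compound Compound to test.
#' @return List of class `"contrast_result"`: `compound`, `estimate`
#'   (female minus male group average, concentration units), `se`,
#'   `f_stat`, `num_df`, `den_df` (Satterthwaite), `den_df_pooled`,
#'   `p_value`, `group_means`, `n_species`, plus `alpha_adjusted` and
#'   `significant` set to `NA` until [bonferroni_family()] is applied.
#' @export
group_contrast <- function(samples, labels, compound) {
  sub <- samples[samples$compound == compound &
                   samples$species %in% names(labels)[labels %in%
                     c("female_associated", "male_associated")], ,
                 drop = FALSE]
  if (nrow(sub) == 0) stop("no samples for compound ", compound, call. = FALSE)
  n <- tapply(sub$concentration, sub$species, length)
  single <- names(n)[n < 2]
  if (length(single)) {
    warning("species with a single replicate excluded from ", compound, ": ",
            paste(single, collapse = ", "), call. = FALSE)
    sub <- sub[!sub$species %in% single, , drop = FALSE]
    n <- n[!names(n) %in% single]
  }
  grp <- labels[names(n)]
  if (sum(grp == "female_associated") < 2 || sum(grp == "male_associated") < 2) {
    stop("need >= 2 species per group for ", compound, call. = FALSE)
  }
  m <- tapply(sub$concentration, sub$species, mean)[names(n)]
  s2 <- tapply(sub$concentration, sub$species, stats::var)[names(n)]
  w <- ifelse(grp == "female_associated",
              1 / sum(grp == "female_associated"),
              -1 / sum(grp == "male_associated"))
  L <- sum(w * m)
  comp <- w^2 * s2 / n
  se <- sqrt(sum(comp))
  den_df <- sum(comp)^2 / sum(comp^2 / (n - 1))  # Welch-Satterthwaite
  f_stat <- (L / se)^2
  p <- stats::pf(f_stat, 1, den_df, lower.tail = FALSE)
  out <- list(
    compound = compound, estimate = L, se = se, f_stat = f_stat,
    num_df = 1L, den_df = den_df, den_df_pooled = sum(n - 1),
    p_value = p,
    group_means = c(female = mean(m[grp == "female_associated"]),
                    male = mean(m[grp == "male_associated"])),
    n_species = stats::setNames(as.integer(table(grp)[c("female_associated",
                                                        "male_associated")]),
                                c("female", "male")),
    alpha_adjusted = NA_real_, significant = NA
  )
  class(out) <- "contrast_result"
  out
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf(
    "%s: F - M = %.3f (SE %.3f), F(1, %.1f) = %.2f, p = %.3g",
    x$compound, x$estimate, x$se, x$den_df, x$f_stat, x$p_value))
  if (!is.na(x$alpha_adjusted)) {
    cat(sprintf(" [alpha = %.4g: %s]", x$alpha_adjusted,
                if (isTRUE(x$significant)) "significant" else "ns"))
  }
  cat("\n")
  invisible(x)
}

#' Bonferroni correction over a compound family
#'
#' Divides the family-wise alpha by the family size and marks each
#' contrast significant when its p-value beats the adjusted level (e.g. a
#' five-carbohydrate family tests each at 0.05 / 5 = 0.01).
#'
#' @param results List of `"contrast_result"` objects forming one family.
#' @param family_alpha Family-wise alpha (default 0.05).
#' @return The list with `alpha_adjusted` and `significant` filled in.
#' @export
bonferroni_family <- function(results, family_alpha = 0.05) {
  if (length(results) == 0) stop("empty contrast family", call. = FALSE)
  alpha <- family_alpha / length(results)
  lapply(results, function(r) {
    r$alpha_adjusted <- alpha
    r$significant <- r$p_value < alpha
    r
  })
}

#' Full nectar contrast analysis over compound families
#'
#' Runs [remove_outliers()], then [group_contrast()] for every compound in
#' each family, then [bonferroni_family()] within family. Compounds
#' missing in more than `max_missing` of samples (never detected for that
#' fraction of replicates relative to the panel's fullest compound) are
#' excluded with a message, mirroring the a-priori exclusion of sparsely
#' detected metabolites.
#'
#' @param samples A `"nectar"` data.frame.
#' @param labels Species association labels (see [group_contrast()]).
#' @param families Named list of compound character vectors, each one
#'   Bonferroni family, e.g.
#'   `list(carbohydrates = c("glucose", ...), amino_acids = c(...))`.
#' @param k Outlier SD multiplier (default 4).
#' @param family_alpha Family-wise alpha (default 0.05).
#' @param max_missing Exclusion threshold on the missing fraction
#'   (default 0.5).
#' @return List of class `"nectar_analysis"` with `contrasts` (named list
#'   of `"contrast_result"` per family), `outliers` (report), and
#'   `excluded_compounds`.
#' @export
nectar_contrasts <- function(samples, labels, families, k = 4,
                             family_alpha = 0.05, max_missing = 0.5) {
  screened <- remove_outliers(samples, k = k)
  x <- screened$samples
  n_expected <- max(table(x$compound))
  excluded <- character(0)
  fam_results <- lapply(families, function(comps) {
    present <- comps[comps %in% x$compound]
    keep <- present[vapply(present, function(cm) {
      sum(x$compound == cm) >= (1 - max_missing) * n_expected
    }, logical(1))]
    dropped <- setdiff(comps, keep)
    if (length(dropped)) {
      message("excluding sparsely detected compound(s): ",
              paste(dropped, collapse = ", "))
      excluded <<- c(excluded, dropped)
    }
    if (length(keep) == 0) return(list())
    res <- lapply(keep, function(cm) group_contrast(x, labels, cm))
    names(res) <- keep
    bonferroni_family(res, family_alpha = family_alpha)
  })
  out <- list(contrasts = fam_results, outliers = screened$report,
              excluded_compounds = excluded)
  class(out) <- "nectar_analysis"
  out
}

#' @export
print.nectar_analysis <- function(x, ...) {
  for (fam in names(x$contrasts)) {
    cat(fam, "(family of", length(x$contrasts[[fam]]), "compounds):\n")
    for (r in x$contrasts[[fam]]) {
      cat("  "); print(r)
    }
  }
  if (nrow(x$outliers)) {
    cat("outliers removed (|z| >", attr(x$outliers, "k"), "):",
        nrow(x$outliers), "\n")
  }
  invisible(x)
}
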