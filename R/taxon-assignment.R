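#' Fit a phenology classifier for a congeneric species pair
#'
#' Some field records are identified only to genus (e.g. `"Cirsium spp."`
#' for the early-season pasture thistle and late-season field thistle).
#' Because the two species' flight-availability windows barely overlap, the
#' observation date alone separates them well. This fits a one-dimensional
#' maximum-margin threshold on ordinal day from unambiguous records of the
#' two species, pooled across years: with a single feature any linear
#' support-vector rule reduces to a day threshold, which keeps the stage
#' auditable.
#'
#' The threshold is chosen among midpoints of adjacent observed days (and the
#' days themselves) to minimize count-weighted training misclassification;
#' among minimizers the one with the largest margin (distance to the nearest
#' training day) wins. For perfectly separable classes this is the midpoint
#' of the closest cross-class pair. Records falling exactly on the boundary
#' are assigned to the class with the greater training weight within +/- 7
#' days of the boundary (deterministic local-frequency tie rule).
#'
#' @param ds A `"visitation"` data.frame containing unambiguous records of
#'   both target species (other species are ignored).
#' @param species_pair Character vector of the two species labels.
#' @return An object of class `"pheno_classifier"`: list with
#'   `boundary` (ordinal day), `early_species`, `late_species`,
#'   `tie_class`, and `training_summary` (per-class day mean/SD/support).
#' @export
fit_phenology_classifier <- function(ds,
                                     species_pair = c("Cirsium pumilum",
                                                      "Cirsium discolor")) {
  stopifnot(length(species_pair) == 2)
  sub <- ds[ds$plant_species %in% species_pair, , drop = FALSE]
  present <- unique(sub$plant_species)
  if (length(present) < 2) {
    stop("need >= 1 record of each of ", paste(species_pair, collapse = " and "),
         " to fit the classifier", call. = FALSE)
  }
  days <- rep(sub$ordinal_day, sub$count)
  labs <- rep(sub$plant_species, sub$count)
  mu <- tapply(days, labs, mean)
  early <- names(mu)[which.min(mu)]
  late <- setdiff(names(mu), early)

  ud <- sort(unique(days))
  if (length(ud) == 1L) {
    warning("degenerate margin: both species observed only on day ", ud,
            "; using that day as the boundary", call. = FALSE)
    boundary <- as.numeric(ud)
  } else {
    cand <- sort(unique(c(ud, (ud[-1] + ud[-length(ud)]) / 2)))
    err <- vapply(cand, function(b) {
      pred <- ifelse(days < b, early, ifelse(days > b, late, NA))
      pred[is.na(pred)] <- tie_class_at(days, labs, b)
      sum(pred != labs)
    }, numeric(1))
    best <- cand[err == min(err)]
    margin <- vapply(best, function(b) min(abs(days - b)), numeric(1))
    boundary <- best[which.max(margin)]
    if (max(margin) == 0 && min(err) > 0) {
      warning("degenerate margin: day distributions overlap at the boundary",
              call. = FALSE)
    }
  }

  summ <- data.frame(
    species = names(mu),
    mean_day = as.numeric(mu),
    sd_day = as.numeric(tapply(days, labs, stats::sd)),
    n = as.integer(tapply(days, labs, length)),
    role = ifelse(names(mu) == early, "early", "late"),
    row.names = NULL
  )
  structure(
    list(boundary = boundary, early_species = early, late_species = late,
         tie_class = tie_class_at(days, labs, boundary),
         training_summary = summ),
    class = "pheno_classifier"
  )
}

# class with greater training weight within +/-7 days of b; falls back to
# the globally more frequent class, then to the early species
tie_class_at <- function(days, labs, b, halfwidth = 7) {
  near <- abs(days - b) <= halfwidth
  tab <- if (any(near)) table(labs[near]) else table(labs)
  winners <- names(tab)[tab == max(tab)]
  sort(winners)[1]
}

#' @export
print.pheno_classifier <- function(x, ...) {
  cat("Phenology day-threshold classifier\n")
  cat("  boundary: day", format(x$boundary), "\n")
  cat("  early:", x$early_species, " late:", x$late_species, "\n")
  print(x$training_summary)
  invisible(x)
}

#' Predict species from ordinal day
#'
#' @param object A `"pheno_classifier"`.
#' @param days Integer ordinal days.
#' @param ... Unused.
#' @return Character vector of predicted species labels.
#' @export
predict.pheno_classifier <- function(object, days, ...) {
  out <- ifelse(days < object$boundary, object$early_species,
                object$late_species)
  out[days == object$boundary] <- object$tie_class
  out
}

#' Assign ambiguous genus-level records to species
#'
#' Relabels every record carrying the ambiguous genus label to one of the
#' classifier's two species by observation day. Non-ambiguous records are
#' untouched; record count and all other fields are conserved. An
#' `assigned` logical column records provenance of the relabeling.
#'
#' @param ds A `"visitation"` data.frame.
#' @param clf A fitted `"pheno_classifier"`.
#' @param ambiguous_label Label to resolve (default `"Cirsium spp."`).
#' @return The dataset with ambiguous records relabeled and an `assigned`
#'   column added.
#' @export
assign_ambiguous <- function(ds, clf, ambiguous_label = "Cirsium spp.") {
  amb <- tolower(ds$plant_species) == tolower(ambiguous_label)
  ds$assigned <- amb
  if (any(amb)) {
    ds$plant_species[amb] <- predict(clf, ds$ordinal_day[amb])
  }
  ds
}
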