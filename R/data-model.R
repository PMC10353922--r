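#' Construct a visitation dataset
#'
#' A visitation dataset is a long-format table of individual nectaring
#' observations: one row per feeding event (or per pre-aggregated group of
#' events when `count > 1`). Rows are never deduplicated — two butterflies on
#' the same plant on the same day are two legitimate records.
#'
#' @param year Integer calendar years.
#' @param ordinal_day Integer day-of-year (January 1 = day 1), in 1..366.
#' @param sex Character, `"F"` or `"M"` (case-insensitive; `"female"` and
#'   `"male"` are also accepted).
#' @param plant_species Plant species labels. Labels are whitespace-squished;
#'   labels differing only in case are unified to the first-seen spelling
#'   (two decades of hand-entered field data motivate this).
#' @param count Positive integer visit counts; defaults to 1 per row.
#'
#' @return A `data.frame` of class `"visitation"` with columns
#'   `year`, `ordinal_day`, `sex`, `plant_species`, `count`.
#' @seealso [read_visitation()], [validate_dataset()]
#' @export
visitation_dataset <- function(year, ordinal_day, sex, plant_species,
                               count = NULL) {
  n <- length(year)
  if (is.null(count)) count <- rep(1L, n)
  ds <- data.frame(
    year = as.integer(year),
    ordinal_day = as.integer(ordinal_day),
    sex = normalize_sex(sex),
    plant_species = normalize_species(plant_species),
    count = as.integer(count),
    stringsAsFactors = FALSE
  )
  check_visitation(ds)
  class(ds) <- c("visitation", "data.frame")
  ds
}

normalize_sex <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[x == "FEMALE"] <- "F"
  x[x == "MALE"] <- "M"
  x
}

squish <- function(x) gsub("[[:space:]]+", " ", trimws(as.character(x)))

#' @keywords internal
normalize_species <- function(x) {
  x <- squish(x)
  # unify case variants to the first-seen spelling
  key <- tolower(x)
  first <- x[!duplicated(key)]
  names(first) <- key[!duplicated(key)]
  unname(first[key])
}

check_visitation <- function(ds) {
  bad_sex <- which(!ds$sex %in% c("F", "M"))
  if (length(bad_sex)) {
    stop("invalid sex value(s) in row(s): ", paste(bad_sex, collapse = ", "),
         call. = FALSE)
  }
  bad_day <- which(is.na(ds$ordinal_day) | ds$ordinal_day < 1L |
                     ds$ordinal_day > 366L)
  if (length(bad_day)) {
    stop("ordinal_day outside 1..366 in row(s): ",
         paste(bad_day, collapse = ", "), call. = FALSE)
  }
  bad_count <- which(is.na(ds$count) | ds$count < 1L)
  if (length(bad_count)) {
    stop("count must be a positive integer in row(s): ",
         paste(bad_count, collapse = ", "), call. = FALSE)
  }
  bad_year <- which(is.na(ds$year))
  if (length(bad_year)) {
    stop("missing/unparsable year in row(s): ",
         paste(bad_year, collapse = ", "), call. = FALSE)
  }
  invisible(ds)
}

#' Read visitation records from CSV
#'
#' Expects columns `year, ordinal_day, sex, plant_species` and optionally
#' `count` (UTF-8, header required). A `dialect` map absorbs alternative
#' column spellings in deposited data.
#'
#' @param path Path to a CSV file.
#' @param dialect Optional named character vector mapping standard column
#'   names to the file's column names, e.g.
#'   `c(ordinal_day = "doy", plant_species = "plant")`.
#' @return A `"visitation"` data.frame; see [visitation_dataset()].
#' @export
read_visitation <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  std <- c("year", "ordinal_day", "sex", "plant_species", "count")
  cols <- stats::setNames(std, std)
  if (!is.null(dialect)) cols[names(dialect)] <- dialect
  required <- std[std != "count"]
  missing <- required[!cols[required] %in% names(raw)]
  if (length(missing)) {
    stop("missing required column(s): ",
         paste(cols[missing], collapse = ", "), call. = FALSE)
  }
  count <- if (cols[["count"]] %in% names(raw)) raw[[cols[["count"]]]] else NULL
  visitation_dataset(
    year = raw[[cols[["year"]]]],
    ordinal_day = raw[[cols[["ordinal_day"]]]],
    sex = raw[[cols[["sex"]]]],
    plant_species = raw[[cols[["plant_species"]]]],
    count = count
  )
}

#' Write visitation records to CSV
#'
#' Inverse of [read_visitation()]: `read_visitation(write_visitation(ds, f))`
#' reproduces the record multiset exactly.
#'
#' @param ds A `"visitation"` data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_visitation <- function(ds, path) {
  utils::write.csv(
    ds[, c("year", "ordinal_day", "sex", "plant_species", "count")],
    path, row.names = FALSE, quote = TRUE
  )
  invisible(path)
}

#' Species catalog of a visitation dataset
#'
#' @param ds A `"visitation"` data.frame.
#' @return Sorted character vector of distinct plant labels.
#' @export
species_catalog <- function(ds) sort(unique(ds$plant_species))

#' Year range of a visitation dataset
#' @param ds A `"visitation"` data.frame.
#' @return Integer vector `c(min, max)`, or `c(NA, NA)` when empty.
#' @export
year_range <- function(ds) {
  if (nrow(ds) == 0) return(c(NA_integer_, NA_integer_))
  range(ds$year)
}

#' Validate a visitation dataset
#'
#' Report-only validation: counts by sex and year, ambiguous genus-level
#' labels awaiting assignment, and duplicated rows (flagged, never removed).
#'
#' @param ds A `"visitation"` data.frame.
#' @param ambiguous_label Genus-level label treated as unassigned
#'   (default `"Cirsium spp."`).
#' @return A list of class `"visitation_report"` with elements
#'   `n_records`, `total_count`, `counts` (sex x year table of summed counts),
#'   `n_ambiguous`, `n_duplicate_rows`, `species`.
#' @export
validate_dataset <- function(ds, ambiguous_label = "Cirsium spp.") {
  counts <- if (nrow(ds)) {
    tapply(ds$count, list(sex = ds$sex, year = ds$year), sum, default = 0L)
  } else {
    matrix(integer(0), nrow = 0, ncol = 0)
  }
  dup <- duplicated(ds[, c("year", "ordinal_day", "sex", "plant_species")])
  rep <- list(
    n_records = nrow(ds),
    total_count = sum(ds$count),
    counts = counts,
    n_ambiguous = sum(ds$count[tolower(ds$plant_species) ==
                                 tolower(ambiguous_label)]),
    n_duplicate_rows = sum(dup),
    species = species_catalog(ds)
  )
  class(rep) <- "visitation_report"
  rep
}

#' @export
print.visitation_report <- function(x, ...) {
  cat("Visitation dataset:", x$n_records, "records,",
      x$total_count, "total visits,",
      length(x$species), "plant species\n")
  if (x$n_ambiguous > 0)
    cat("  unassigned ambiguous records:", x$n_ambiguous, "\n")
  if (x$n_duplicate_rows > 0)
    cat("  duplicated rows (legal, kept):", x$n_duplicate_rows, "\n")
  if (length(x$counts)) {
    cat("  visits by sex and year:\n")
    print(x$counts)
  }
  invisible(x)
}

#' Read a nectar concentration table from CSV
#'
#' Long format: `species, sample_id, compound, concentration` with one row
#' per metabolite measurement on one biological replicate (one plant
#' individual). Concentrations are normalized units and must be >= 0;
#' (species, sample_id, compound) must be unique.
#'
#' @param path Path to a CSV file.
#' @return A data.frame of class `"nectar"`.
#' @export
read_nectar <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("species", "sample_id", "compound", "concentration")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  nectar_table(x$species, x$sample_id, x$compound, x$concentration)
}

#' Construct a nectar concentration table
#'
#' @param species,sample_id,compound,concentration Column vectors; see
#'   [read_nectar()].
#' @return A data.frame of class `"nectar"`.
#' @export
nectar_table <- function(species, sample_id, compound, concentration) {
  x <- data.frame(
    species = squish(species),
    sample_id = as.character(sample_id),
    compound = squish(compound),
    concentration = as.numeric(concentration),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(x$concentration) | x$concentration < 0)
  if (length(bad)) {
    stop("negative or unparsable concentration in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  key <- paste(x$species, x$sample_id, x$compound, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (species, sample_id, compound) measurement(s) in row(s): ",
         paste(which(duplicated(key)), collapse = ", "), call. = FALSE)
  }
  class(x) <- c("nectar", "data.frame")
  x
}
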