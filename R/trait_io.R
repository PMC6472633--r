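#' Read long-format trait records
#'
#' Reads a CSV of individual trait measurements into a `trait_dataset`.
#' Canonical columns are `species_name`, `trait_name`, `value`, `unit`,
#' `latitude`, `longitude`, `site`, `year`, `source_id`; only the first three
#' are required. Non-canonical headers are mapped via `column_map`.
#'
#' Rows whose value does not parse as a finite number, and rows whose trait is
#' not in `vocabulary`, are skipped (not fatal) and counted in the provenance
#' report. Latitudes outside [-90, 90] are set to `NA` and counted.
#'
#' @param path CSV file path (UTF-8, header row required).
#' @param column_map named character vector mapping canonical column names to
#'   the file's column names, e.g. `c(species_name = "SpeciesName")`.
#' @param vocabulary allowed trait names; `NULL` accepts any trait.
#' @return A `trait_dataset`: list with `records` (data frame) and
#'   `provenance` (named list of counts and flagged rows).
#' @export
read_trait_records <- function(path, column_map = NULL,
                               vocabulary = trait_vocabulary()) {
  if (!file.exists(path)) stop2("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  canonical <- c("species_name", "trait_name", "value", "unit", "latitude",
                 "longitude", "site", "year", "source_id")
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw))
        stop2("column_map refers to missing column '", src, "'")
      names(raw)[names(raw) == src] <- canon
    }
  }
  required <- c("species_name", "trait_name", "value")
  miss <- setdiff(required, names(raw))
  if (length(miss))
    stop2("missing required column(s): ", paste(miss, collapse = ", "))
  if (nrow(raw) == 0L) {
    warning("empty trait file: ", path, call. = FALSE)
    return(new_trait_dataset(empty_records(), list(n_read = 0L)))
  }
  for (col in setdiff(canonical, names(raw))) raw[[col]] <- NA
  rec <- raw[canonical]
  rec$value <- suppressWarnings(as.numeric(rec$value))
  rec$latitude <- suppressWarnings(as.numeric(rec$latitude))
  rec$longitude <- suppressWarnings(as.numeric(rec$longitude))
  rec$year <- suppressWarnings(as.integer(rec$year))
  bad_value <- !is.finite(rec$value)
  bad_trait <- if (is.null(vocabulary)) rep(FALSE, nrow(rec)) else
    !(rec$trait_name %in% vocabulary)
  keep <- !(bad_value | bad_trait)
  bad_lat <- !is.na(rec$latitude) & (rec$latitude < -90 | rec$latitude > 90)
  rec$latitude[bad_lat] <- NA
  prov <- list(
    n_read = nrow(raw),
    n_skipped_unparsable_value = sum(bad_value),
    n_skipped_unknown_trait = sum(bad_trait & !bad_value),
    n_invalid_latitude = sum(bad_lat))
  new_trait_dataset(rec[keep, , drop = FALSE], prov)
}

empty_records <- function() {
  data.frame(species_name = character(), trait_name = character(),
             value = numeric(), unit = character(), latitude = numeric(),
             longitude = numeric(), site = character(), year = integer(),
             source_id = character(), stringsAsFactors = FALSE)
}

new_trait_dataset <- function(records, provenance = list()) {
  rownames(records) <- NULL
  structure(list(records = records, provenance = provenance),
            class = "trait_dataset")
}

#' Construct a trait dataset from a records data frame
#'
#' @param records data frame with at least `species_name`, `trait_name`,
#'   `value`; missing optional columns are added as `NA`.
#' @return A `trait_dataset`.
#' @export
trait_dataset <- function(records) {
  required <- c("species_name", "trait_name", "value")
  miss <- setdiff(required, names(records))
  if (length(miss)) stop2("missing column(s): ", paste(miss, collapse = ", "))
  canonical <- names(empty_records())
  for (col in setdiff(canonical, names(records))) records[[col]] <- NA
  new_trait_dataset(records[canonical], list(n_read = nrow(records)))
}

#' @export
print.trait_dataset <- function(x, ...) {
  r <- x$records
  cat("Trait dataset: ", nrow(r), " records, ",
      length(unique(r$species_name)), " species, ",
      length(unique(r$trait_name)), " traits\n", sep = "")
  p <- x$provenance
  counts <- p[vapply(p, function(e) is.numeric(e) && length(e) == 1L, TRUE)]
  if (length(counts)) {
    cat("Provenance:\n")
    for (nm in names(counts)) cat("  ", nm, ": ", counts[[nm]], "\n", sep = "")
  }
  invisible(x)
}

#' Resolve taxonomic synonyms
#'
#' Replaces every species name that appears as a synonym with its accepted
#' name. Names not in the table pass through unchanged. The synonym table must
#' be chain-free: an accepted name may not itself be a synonym key.
#'
#' @param ds a `trait_dataset`.
#' @param synonyms named character vector (`names` = synonym, values =
#'   accepted name) or data frame with columns `synonym`, `accepted`.
#' @return The dataset with names resolved; `provenance$n_synonyms_applied`
#'   counts renamed records.
#' @export
apply_synonyms <- function(ds, synonyms) {
  if (is.data.frame(synonyms))
    synonyms <- stats::setNames(as.character(synonyms$accepted),
                                synonyms$synonym)
  chained <- intersect(unname(synonyms), names(synonyms))
  if (length(chained))
    stop2("synonym table has chains via: ", paste(chained, collapse = ", "))
  rec <- ds$records
  hit <- rec$species_name %in% names(synonyms)
  rec$species_name[hit] <- unname(synonyms[rec$species_name[hit]])
  prov <- ds$provenance
  prov$n_synonyms_applied <- sum(hit)
  new_trait_dataset(rec, prov)
}

#' Read a synonym table
#'
#' @param path CSV with columns `synonym`, `accepted`.
#' @return Named character vector mapping synonym to accepted name.
#' @export
read_synonym_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("synonym", "accepted"), names(tab))
  if (length(miss)) stop2("missing column(s): ", paste(miss, collapse = ", "))
  syn <- stats::setNames(as.character(tab$accepted), tab$synonym)
  chained <- intersect(unname(syn), names(syn))
  if (length(chained))
    stop2("synonym table has chains via: ", paste(chained, collapse = ", "))
  syn
}

#' Clean a trait dataset
#'
#' Applies the standard trait-database quality filters, itemizing every
#' removal in the provenance report:
#'
#' 1. exact duplicates (same species, trait, value, unit, source) collapsed;
#' 2. non-positive values removed (traits here are strictly positive);
#' 3. per species-by-trait cell with at least `min_n` records, values whose
#'    log lies more than `sd_threshold` sample standard deviations from the
#'    cell mean are removed (single pass; each point contributes to its own
#'    mean and SD; skipped when the SD is zero);
#' 4. seed-mass records beyond `seed_mass_sd` SDs are *flagged* for manual
#'    review in `provenance$seed_mass_flagged`, never silently dropped.
#'
#' The SD filter operates on the log scale because trait values are treated
#' as log-normal throughout. Cleaning is idempotent.
#'
#' @param ds a `trait_dataset`.
#' @param sd_threshold removal threshold in SD units (default 4).
#' @param seed_mass_sd flag threshold for seed mass (default 3).
#' @param seed_mass_trait trait name carrying the seed-mass flag rule.
#' @param min_n minimum records per species-by-trait cell for the SD filter.
#' @param log_base base of the log transform used by the SD filter.
#' @return The cleaned `trait_dataset`; `provenance` gains counts
#'   `n_duplicates_removed`, `n_nonpositive_removed`, `n_sd_outliers_removed`,
#'   plus data frames `removed_records` and `seed_mass_flagged`.
#' @export
clean_dataset <- function(ds, sd_threshold = 4, seed_mass_sd = 3,
                          seed_mass_trait = "seed_mass", min_n = 3L,
                          log_base = 10) {
  rec <- ds$records
  removed <- list()

  dup <- duplicated(rec[c("species_name", "trait_name", "value", "unit",
                          "source_id")])
  if (any(dup)) {
    removed$duplicate <- cbind(rec[dup, , drop = FALSE], rule = "duplicate")
    rec <- rec[!dup, , drop = FALSE]
  }
  n_dup <- sum(dup)

  nonpos <- rec$value <= 0
  if (any(nonpos)) {
    removed$nonpositive <- cbind(rec[nonpos, , drop = FALSE],
                                 rule = "nonpositive")
    rec <- rec[!nonpos, , drop = FALSE]
  }
  n_nonpos <- sum(nonpos)

  logv <- log(rec$value, base = log_base)
  cell <- interaction(rec$species_name, rec$trait_name, drop = TRUE)
  mu <- stats::ave(logv, cell, FUN = mean)
  sdv <- stats::ave(logv, cell, FUN = stats::sd)
  n_cell <- stats::ave(logv, cell, FUN = length)
  z <- ifelse(n_cell >= min_n & sdv > 0, abs(logv - mu) / sdv, 0)
  out <- z > sd_threshold
  flagged <- rec$trait_name == seed_mass_trait & z > seed_mass_sd & !out
  seed_flag <- rec[flagged, , drop = FALSE]
  if (nrow(seed_flag)) seed_flag$z_score <- z[flagged]
  if (any(out)) {
    removed$sd_outlier <- cbind(rec[out, , drop = FALSE], rule = "sd_outlier")
    rec <- rec[!out, , drop = FALSE]
  }

  prov <- ds$provenance
  prov$n_duplicates_removed <- n_dup
  prov$n_nonpositive_removed <- n_nonpos
  prov$n_sd_outliers_removed <- sum(out)
  prov$removed_records <- if (length(removed))
    do.call(rbind, unname(removed)) else NULL
  prov$seed_mass_flagged <- if (nrow(seed_flag)) seed_flag else NULL
  prov$cleaned <- TRUE
  new_trait_dataset(rec, prov)
}

#' Subset a trait dataset
#'
#' Filters records by minimum latitude (dropping non-georeferenced records),
#' site membership, species membership, or any combination (applied
#' conjunctively).
#'
#' @param ds a `trait_dataset`.
#' @param min_latitude keep only georeferenced records at or above this
#'   latitude (degrees north).
#' @param sites character vector of sites to keep.
#' @param species character vector of species to keep.
#' @return The filtered `trait_dataset`; warns if nothing matches.
#' @export
subset_dataset <- function(ds, min_latitude = NULL, sites = NULL,
                           species = NULL) {
  rec <- ds$records
  keep <- rep(TRUE, nrow(rec))
  if (!is.null(min_latitude))
    keep <- keep & !is.na(rec$latitude) & rec$latitude >= min_latitude
  if (!is.null(sites)) keep <- keep & !is.na(rec$site) & rec$site %in% sites
  if (!is.null(species)) keep <- keep & rec$species_name %in% species
  if (!any(keep)) warning("subset filter matched no records", call. = FALSE)
  prov <- ds$provenance
  prov$subset <- list(min_latitude = min_latitude, sites = sites,
                      species = species, n_kept = sum(keep))
  new_trait_dataset(rec[keep, , drop = FALSE], prov)
}

#' Read a plot-level vegetation cover table
#'
#' @param path CSV with columns `site`, `plot`, `year`, `species_name`,
#'   `cover` (non-negative; one row per site/plot/year/species).
#' @return Validated data frame of class `cover_table`.
#' @export
read_cover_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_cover_table(tab)
}

#' @rdname read_cover_table
#' @param tab data frame with the cover-table columns.
#' @export
as_cover_table <- function(tab) {
  required <- c("site", "plot", "year", "species_name", "cover")
  miss <- setdiff(required, names(tab))
  if (length(miss)) stop2("missing column(s): ", paste(miss, collapse = ", "))
  tab$cover <- as.numeric(tab$cover)
  if (anyNA(tab$cover) || any(tab$cover < 0))
    stop2("cover values must be non-negative numbers")
  key <- tab[c("site", "plot", "year", "species_name")]
  if (anyDuplicated(key))
    stop2("duplicated (site, plot, year, species) rows in cover table")
  structure(tab[required], class = c("cover_table", "data.frame"))
}

#' Read a functional-group classification scheme
#'
#' The group CSV carries one `species_name` column plus one column per scheme;
#' `scheme_name` selects which scheme column to read.
#'
#' @param path CSV file path.
#' @param scheme_name the scheme column to use (e.g. `"traditional_4"`).
#' @return A `partition` with `method = "a_priori"`. A species listed twice
#'   with conflicting labels is a validation error.
#' @export
read_group_scheme <- function(path, scheme_name) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"species_name" %in% names(tab)) stop2("missing column 'species_name'")
  if (!scheme_name %in% names(tab))
    stop2("scheme column '", scheme_name, "' not found; available: ",
          paste(setdiff(names(tab), "species_name"), collapse = ", "))
  lab <- tab[[scheme_name]]
  conflict <- tapply(lab, tab$species_name,
                     function(v) length(unique(v)) > 1L)
  if (any(conflict))
    stop2("conflicting labels in scheme '", scheme_name, "' for: ",
          paste(names(conflict)[conflict], collapse = ", "))
  first <- !duplicated(tab$species_name)
  partition(stats::setNames(lab[first], tab$species_name[first]),
            method = "a_priori", scheme_name = scheme_name)
}
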