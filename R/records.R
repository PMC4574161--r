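#' Marker categories
#'
#' The six genetic-marker categories used throughout the package. The first
#' level, allozyme, is the dummy-coding reference in all design matrices
#' (it is the most frequent category in the kind of database the package
#' targets).
#'
#' @return Character vector of the six marker levels.
#' @export
marker_levels <- function() {
  c("allozyme", "microsatellite", "mtDNA_sequence",
    "mtDNA_restriction", "nuclear_sequence", "other")
}

#' Default column dialect for diversity record files
#'
#' Maps the canonical internal column names to the column names expected in
#' an input CSV. Override individual entries to read files with different
#' headers, e.g. `default_dialect(diversity = "He")`.
#'
#' @param ... named overrides, `internal_name = "file_column_name"`.
#' @return Named character vector mapping internal names to file columns.
#' @export
default_dialect <- function(...) {
  d <- c(data_id = "dataID", class = "class", order = "order",
         family = "family", genus = "genus", species = "species",
         marker = "marker", latitude = "lat", longitude = "lon",
         region = "region", n = "n", diversity = "H")
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(d))
    if (length(bad)) stop("unknown dialect field(s): ", paste(bad, collapse = ", "))
    d[names(over)] <- over
  }
  d
}

rank_cols <- c("class", "order", "family", "genus", "species")

record_cols <- c("data_id", rank_cols, "marker", "latitude", "longitude",
                 "region", "n", "diversity")

#' Construct a validated diversity dataset
#'
#' A dataset is one row per sampled population: a study-by-marker
#' identifier (`data_id`), the species' full Linnaean classification,
#' the marker category, coordinates, a region label, the per-population
#' sample size `n` and a diversity value (expected heterozygosity or
#' haplotype diversity) in \[0, 1\].
#'
#' Validation enforces: diversity in \[0, 1\]; `n >= 5` (the minimum
#' per-population sample size admitted to the database); marker in
#' [marker_levels()]; all five taxonomic ranks non-empty; and taxonomic
#' rank consistency (a genus cannot sit in two families, and so on).
#'
#' @param records data.frame with columns `data_id`, `class`, `order`,
#'   `family`, `genus`, `species`, `marker`, `latitude`, `longitude`,
#'   `region`, `n`, `diversity`.
#' @return An object of class `diversity_dataset`: a list with `records`
#'   (the validated data.frame) and deterministic, sorted index vectors
#'   `regions`, `species` and `data_ids`.
#' @export
diversity_dataset <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing <- setdiff(record_cols, names(records))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  records <- records[record_cols]
  for (col in c("data_id", rank_cols, "marker", "region"))
    records[[col]] <- as.character(records[[col]])
  for (col in c("latitude", "longitude", "n", "diversity"))
    records[[col]] <- as.numeric(records[[col]])

  problems <- validate_records(records)
  if (length(problems))
    stop("invalid records:\n", paste(problems, collapse = "\n"))

  structure(
    list(records = records,
         regions = sort(unique(records$region)),
         species = sort(unique(records$species)),
         data_ids = sort(unique(records$data_id))),
    class = "diversity_dataset")
}

validate_records <- function(records) {
  problems <- character()
  flag <- function(bad, what) {
    if (any(bad, na.rm = TRUE)) {
      rows <- which(bad | is.na(bad))
      problems <<- c(problems, sprintf(
        "  row %s: %s", paste(utils::head(rows, 10), collapse = ","), what))
    }
  }
  flag(is.na(records$diversity) | records$diversity < 0 | records$diversity > 1,
       "diversity outside [0, 1]")
  flag(is.na(records$n) | records$n < 5, "sample size below 5")
  flag(!records$marker %in% marker_levels(),
       paste0("marker not one of {", paste(marker_levels(), collapse = ", "), "}"))
  for (rc in rank_cols)
    flag(is.na(records[[rc]]) | !nzchar(records[[rc]]),
         paste0("empty taxonomic rank '", rc, "'"))
  flag(is.na(records$latitude) | records$latitude < -90 | records$latitude > 90,
       "latitude outside [-90, 90]")
  # rank consistency across the whole table
  if (!length(problems)) {
    paths <- unique(records[rank_cols])
    for (i in seq_along(rank_cols)[-1]) {
      child <- rank_cols[i]; parent <- rank_cols[i - 1L]
      tab <- unique(paths[c(child, parent)])
      dup <- tab[[child]][duplicated(tab[[child]])]
      if (length(dup))
        problems <- c(problems, sprintf(
          "  %s '%s' assigned to more than one %s", child, dup[1], parent))
    }
  }
  problems
}

#' @export
print.diversity_dataset <- function(x, ...) {
  cat("diversity dataset:", nrow(x$records), "populations,",
      length(x$species), "species,", length(x$regions), "regions,",
      length(x$data_ids), "dataIDs\n")
  invisible(x)
}

#' Read a diversity record CSV
#'
#' @param path path to a UTF-8 CSV with a header row.
#' @param dialect column-name map from [default_dialect()].
#' @return A validated [diversity_dataset()].
#' @export
read_dataset <- function(path, dialect = default_dialect()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(unname(dialect), names(raw))
  if (length(missing))
    stop("input file lacks required column(s): ",
         paste(missing, collapse = ", "))
  records <- raw[unname(dialect)]
  names(records) <- names(dialect)
  diversity_dataset(records)
}

#' Write a diversity dataset to CSV
#'
#' Inverse of [read_dataset()]: writes one row per population using the
#' supplied dialect's column names, so that a write/read round trip is
#' lossless.
#'
#' @param ds a `diversity_dataset`.
#' @param path output path.
#' @param dialect column-name map, see [default_dialect()].
#' @export
write_dataset <- function(ds, path, dialect = default_dialect()) {
  out <- ds$records
  names(out) <- unname(dialect[names(out)])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarise a dataset as a manifest
#'
#' Counts of populations per region, per species and per marker category,
#' suitable for JSON export alongside a written dataset.
#'
#' @param ds a `diversity_dataset`.
#' @return A list of named count vectors.
#' @export
dataset_manifest <- function(ds) {
  r <- ds$records
  list(n_populations = nrow(r),
       n_species = length(ds$species),
       n_regions = length(ds$regions),
       n_data_ids = length(ds$data_ids),
       populations_per_region = as.list(table(r$region)),
       populations_per_marker = as.list(table(r$marker)),
       populations_per_species = as.list(table(r$species)))
}

#' Restrict a dataset to a set of regions
#'
#' Keeps only populations in `keep`; afterwards any dataID left with
#' fewer than `min_pops_per_data_id` populations is dropped entirely, so
#' every retained study still contributes a minimum number of populations
#' (three, by default — the threshold used when restricting to coastal
#' regions).
#'
#' @param ds a `diversity_dataset`.
#' @param keep regions to keep (character or coercible).
#' @param min_pops_per_data_id minimum populations per retained dataID.
#' @return A filtered `diversity_dataset`.
#' @export
filter_regions <- function(ds, keep, min_pops_per_data_id = 3) {
  keep <- as.character(keep)
  if (!length(keep)) stop("'keep' must name at least one region")
  r <- ds$records[ds$records$region %in% keep, , drop = FALSE]
  cnt <- table(r$data_id)
  r <- r[r$data_id %in% names(cnt)[cnt >= min_pops_per_data_id], , drop = FALSE]
  if (!nrow(r)) stop("no records remain after region filtering")
  rownames(r) <- NULL
  diversity_dataset(r)
}

#' Restrict a dataset to a set of taxonomic classes
#'
#' Used for taxon-specific reruns (e.g. ray-finned plus cartilaginous
#' fish, or molluscs only). DataIDs are study-by-marker units within a
#' species, so no dataID can straddle the filter.
#'
#' @param ds a `diversity_dataset`.
#' @param classes class labels to keep.
#' @return A filtered `diversity_dataset`.
#' @export
filter_taxa <- function(ds, classes) {
  r <- ds$records[ds$records$class %in% classes, , drop = FALSE]
  if (!nrow(r)) stop("no records remain after taxon filtering")
  rownames(r) <- NULL
  diversity_dataset(r)
}

#' Squeeze unit-interval values into the open interval
#'
#' A beta likelihood has support on (0, 1), but reported diversity values
#' can be exactly 0 or 1. The transform `(y * (n - 1) + 0.5) / n` pulls
#' boundary values inside the interval by half an observation's weight
#' while leaving interior values almost unchanged for large `n`; it is
#' monotone in `y` for fixed `n`. Applied only when fitting the beta
#' model — stored datasets keep raw values.
#'
#' @param y diversity values in \[0, 1\].
#' @param n per-population sample sizes (>= 1).
#' @return Values strictly inside (0, 1).
#' @export
squeeze_unit_interval <- function(y, n) {
  stopifnot(all(y >= 0 & y <= 1), all(n >= 1))
  (y * (n - 1) + 0.5) / n
}
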