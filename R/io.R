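#' Read and write specimen tables
#'
#' Specimen CSVs are comma-separated UTF-8 with a header row and columns
#' `specimen_id`, `species`, `family`, `site`, `date` (ISO 8601),
#' `forewing_length_mm` (integer millimetres) and `dry_mass_mg` (2 decimal
#' places). An individual below the 0.005 mg balance detection limit is
#' written with the sentinel value `"<0.005"` in `dry_mass_mg` and read back
#' as `NA` mass with `below_detection = TRUE`, so the exclusion filter is
#' testable from files. Unidentified individuals have an empty `species`
#' field.
#'
#' @param path Path to a CSV file.
#' @param records Specimen table to write.
#' @return `read_specimens()` returns the specimen data frame (with a
#'   logical `below_detection` column); `write_specimens()` returns `path`
#'   invisibly. Malformed rows are reported with their line numbers.
#' @export
read_specimens <- function(path) {
  df <- read_schema_csv(path, c("specimen_id", "species", "family", "site",
                                "date", "forewing_length_mm", "dry_mass_mg"))
  below <- trimws(df$dry_mass_mg) == "<0.005"
  mass <- suppressWarnings(as.numeric(df$dry_mass_mg))
  mass[below] <- NA_real_
  bad <- which(is.na(mass) & !below & trimws(df$dry_mass_mg) != "")
  if (length(bad)) {
    stop("non-numeric dry_mass_mg at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path, call. = FALSE)
  }
  len <- suppressWarnings(as.numeric(df$forewing_length_mm))
  bad <- which(is.na(len))
  if (length(bad)) {
    stop("non-numeric forewing_length_mm at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path, call. = FALSE)
  }
  d <- as.Date(df$date, format = "%Y-%m-%d")
  bad <- which(is.na(d))
  if (length(bad)) {
    stop("date not in ISO 8601 (YYYY-MM-DD) at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path, call. = FALSE)
  }
  data.frame(specimen_id = df$specimen_id,
             species = df$species,
             family = df$family,
             site = df$site,
             date = format(d),
             forewing_length_mm = len,
             dry_mass_mg = mass,
             below_detection = below)
}

#' @rdname read_specimens
#' @export
write_specimens <- function(records, path) {
  out <- records
  below <- if ("below_detection" %in% names(out)) out$below_detection
           else rep(FALSE, nrow(out))
  mass <- ifelse(below, "<0.005", sprintf("%.2f", out$dry_mass_mg))
  out <- data.frame(specimen_id = out$specimen_id, species = out$species,
                    family = out$family, site = out$site, date = out$date,
                    forewing_length_mm = out$forewing_length_mm,
                    dry_mass_mg = mass)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read field-guide and abundance tables
#'
#' The field-guide CSV has columns `species`, `family`, `forewing_min_mm`,
#' `forewing_max_mm` (published minimum and maximum forewing lengths). The
#' abundance CSV has columns `site`, `date`, `species`, `count`, one row per
#' species per sample.
#'
#' @param path Path to a CSV file.
#' @return A typed data frame in the corresponding schema.
#' @export
read_guide <- function(path) {
  df <- read_schema_csv(path, c("species", "family", "forewing_min_mm",
                                "forewing_max_mm"))
  df$forewing_min_mm <- as_numeric_col(df$forewing_min_mm, "forewing_min_mm",
                                       path)
  df$forewing_max_mm <- as_numeric_col(df$forewing_max_mm, "forewing_max_mm",
                                       path)
  if (any(df$forewing_min_mm <= 0) ||
      any(df$forewing_max_mm < df$forewing_min_mm)) {
    stop("field-guide ranges must satisfy 0 < min <= max in ", path,
         call. = FALSE)
  }
  df
}

#' @rdname read_guide
#' @export
read_abundance <- function(path) {
  df <- read_schema_csv(path, c("site", "date", "species", "count"))
  df$count <- as_numeric_col(df$count, "count", path)
  if (any(df$count < 0)) stop("counts must be non-negative in ", path,
                              call. = FALSE)
  df
}

read_schema_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  assert_columns(df, required, what = basename(path))
  df
}

as_numeric_col <- function(x, name, path) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & trimws(x) != "")
  if (length(bad)) {
    stop("non-numeric ", name, " at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path, call. = FALSE)
  }
  v
}

#' Apply the standard record-exclusion filters
#'
#' Excludes (1) individuals not identified to species or species-aggregate
#' level (empty or missing `species` field), and (2) individuals below the
#' 0.005 mg balance detection limit (flagged `below_detection`, or with a
#' recorded mass under 0.005 mg). Everything else is retained for analysis.
#'
#' @param records Specimen table, possibly containing excluded-class rows.
#' @return A list of class `filter_report` with elements `retained` (the
#'   filtered specimen table), `n_input`, `n_excluded_unidentified`,
#'   `n_excluded_below_detection`, `n_retained`, and `excluded_ids`.
#' @export
filter_records <- function(records) {
  validate_specimens(records, require_mass = FALSE)
  sp <- records$species
  unident <- is.na(sp) | trimws(sp) == ""
  below <- if ("below_detection" %in% names(records)) {
    records$below_detection %in% TRUE
  } else rep(FALSE, nrow(records))
  below <- below | is.na(records$dry_mass_mg) |
    records$dry_mass_mg < 0.005
  below <- below & !unident
  keep <- !unident & !below
  out <- list(
    retained = records[keep, , drop = FALSE],
    n_input = nrow(records),
    n_excluded_unidentified = sum(unident),
    n_excluded_below_detection = sum(below),
    n_retained = sum(keep),
    excluded_ids = records$specimen_id[!keep]
  )
  class(out) <- "filter_report"
  out
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "Record filter: %d in -> %d retained (%d unidentified, %d below 0.005 mg excluded)\n",
    x$n_input, x$n_retained, x$n_excluded_unidentified,
    x$n_excluded_below_detection))
  invisible(x)
}
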