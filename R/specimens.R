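#' Specimen record tables
#'
#' A specimen table holds one row per measured moth with columns
#' `specimen_id`, `species`, `family`, `site`, `date`,
#' `forewing_length_mm` (integer millimetres, measured to the nearest 1 mm)
#' and `dry_mass_mg` (milligrams, measured to 0.01 mg; `NA` together with
#' `below_detection = TRUE` marks an individual lighter than the 0.005 mg
#' balance detection limit). Most functions in the package accept and return
#' plain data frames in this schema.
#'
#' @param records A data frame of specimen measurements.
#' @param require_mass If `TRUE` (default), every row must carry a usable
#'   positive mass; set to `FALSE` for tables that still contain
#'   below-detection or unidentified rows awaiting [filter_records()].
#' @return The validated data frame, invisibly usable in pipelines.
#' @seealso [read_specimens()], [filter_records()], [simulate_community()]
#' @export
validate_specimens <- function(records, require_mass = TRUE) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("specimen table is empty: no data to analyse", call. = FALSE)
  }
  assert_columns(records,
                 c("specimen_id", "species", "family", "site", "date",
                   "forewing_length_mm", "dry_mass_mg"),
                 what = "specimen table")
  if (any(records$forewing_length_mm < 1, na.rm = TRUE)) {
    stop("forewing_length_mm must be >= 1 mm for every specimen", call. = FALSE)
  }
  if (require_mass) {
    m <- records$dry_mass_mg
    if (anyNA(m) || any(m <= 0)) {
      stop("dry_mass_mg must be positive for every specimen; ",
           "run filter_records() first to drop below-detection rows",
           call. = FALSE)
    }
  }
  fam <- tapply(records$family, records$species,
                function(f) length(unique(f)))
  if (any(fam > 1L)) {
    bad <- names(fam)[fam > 1L]
    stop("species mapped to more than one family: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(records)
}

sample_key <- function(records) paste(records$site, records$date, sep = "\r")
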