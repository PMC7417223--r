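#' Predict the dry body mass of a moth from its forewing length
#'
#' Evaluates the allometric prediction
#' `mass = exp((b0 + b0_f) + (b1 + b1_f) * ln(length))` for each moth, where
#' the family is resolved to a parameter group through the grouping carried
#' by `params`. Families that the parameters were not trained on fall back to
#' the pooled "other families" prediction with a warning (historical
#' abundance datasets routinely contain such families).
#'
#' @param forewing_length_mm Forewing length(s) in millimetres, positive.
#' @param family Taxonomic family name(s), recycled against the lengths.
#' @param params An [allometric_parameters()] object; defaults to the
#'   packaged reference parameters.
#' @return Predicted dry mass in milligrams (vectorised).
#' @examples
#' predict_mass(1, "Psychidae", moth_reference_params())   # exp(-5.016)
#' predict_mass(15, "Noctuidae", moth_reference_params())  # ~34.3 mg
#' @export
predict_mass <- function(forewing_length_mm, family,
                         params = moth_reference_params()) {
  stopifnot(inherits(params, "allometric_parameters"))
  if (length(forewing_length_mm) == 0L) return(numeric(0))
  if (any(!is.finite(forewing_length_mm)) || any(forewing_length_mm <= 0)) {
    stop("forewing_length_mm must be positive and finite", call. = FALSE)
  }
  n <- max(length(forewing_length_mm), length(family))
  len <- rep_len(as.numeric(forewing_length_mm), n)
  fam <- rep_len(as.character(family), n)
  grp <- resolve_group(fam, params$grouping)
  tab <- params_table(params)
  idx <- match(grp, tab$group)
  idx[is.na(idx)] <- 1L # pooled reference row
  exp(tab$effective_intercept[idx] + tab$effective_slope[idx] * log(len))
}

#' Expected species mass from a field-guide forewing-length range
#'
#' Predicts a species' expected dry mass from the arithmetic midpoint of its
#' published minimum and maximum forewing lengths (the midpoint is taken on
#' the mm scale, before any logging).
#'
#' @param guide Data frame with columns `species`, `family`,
#'   `forewing_min_mm`, `forewing_max_mm` (see [read_guide()]).
#' @inheritParams predict_mass
#' @return `species_expected_mass()` returns a numeric vector of masses (mg)
#'   aligned with the rows of `guide`; [species_mass_table()] returns a data
#'   frame with columns `species`, `family_group`, `expected_forewing_mm`
#'   and `predicted_mass_mg`.
#' @export
species_expected_mass <- function(guide, params = moth_reference_params()) {
  assert_columns(guide, c("species", "family", "forewing_min_mm",
                          "forewing_max_mm"), what = "field-guide table")
  if (any(guide$forewing_min_mm <= 0) ||
      any(guide$forewing_max_mm < guide$forewing_min_mm)) {
    stop("field-guide ranges must satisfy 0 < min <= max", call. = FALSE)
  }
  mid <- (guide$forewing_min_mm + guide$forewing_max_mm) / 2
  predict_mass(mid, guide$family, params)
}

#' @rdname species_expected_mass
#' @export
species_mass_table <- function(guide, params = moth_reference_params()) {
  mass <- species_expected_mass(guide, params)
  data.frame(
    species = guide$species,
    family_group = resolve_group(guide$family, params$grouping,
                                 warn_unknown = FALSE),
    expected_forewing_mm = (guide$forewing_min_mm + guide$forewing_max_mm) / 2,
    predicted_mass_mg = mass
  )
}

as_mass_lookup <- function(masses) {
  if (is.data.frame(masses)) {
    assert_columns(masses, c("species", "predicted_mass_mg"),
                   what = "species-mass table")
    stats::setNames(masses$predicted_mass_mg, masses$species)
  } else if (is.numeric(masses) && !is.null(names(masses))) {
    masses
  } else {
    stop("masses must be a species_mass_table() data frame or a named ",
         "numeric vector", call. = FALSE)
  }
}

#' Estimated biomass of a mixed-species sample
#'
#' Total predicted dry biomass of one sample (all moths captured at the same
#' site on the same day): the abundance-weighted sum of per-species predicted
#' masses. Biomass is additive, so disjoint splits of a sample sum to the
#' same total.
#'
#' @param counts Named numeric vector of abundances (species -> count), or a
#'   data frame with columns `species` and `count`.
#' @param masses A [species_mass_table()] data frame or named numeric vector
#'   of per-species predicted masses (mg).
#' @return Total biomass in milligrams.
#' @export
sample_biomass <- function(counts, masses) {
  if (is.data.frame(counts)) {
    assert_columns(counts, c("species", "count"), what = "abundance table")
    counts <- stats::setNames(counts$count, counts$species)
  }
  if (length(counts) == 0L) return(0)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  lookup <- as_mass_lookup(masses)
  missing <- setdiff(names(counts), names(lookup))
  if (length(missing)) {
    stop("species missing from the mass table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sum(counts * lookup[names(counts)])
}

#' Whole-dataset prediction offset
#'
#' Percentage difference between the total predicted and total measured
#' biomass of a set of measured moths, using each individual's species-level
#' predicted mass. Negative values mean the predictions under-estimate total
#' biomass. This offset is the normalising constant for [prediction_error()].
#'
#' @param records Specimen table with measured masses.
#' @param masses Per-species predicted masses, as in [sample_biomass()].
#' @return Signed percentage, `100 * (sum(pred) - sum(meas)) / sum(meas)`.
#' @export
dataset_prediction_offset <- function(records, masses) {
  validate_specimens(records)
  lookup <- as_mass_lookup(masses)
  missing <- setdiff(unique(records$species), names(lookup))
  if (length(missing)) {
    stop("species missing from the mass table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  measured <- sum(records$dry_mass_mg)
  if (measured <= 0) stop("total measured biomass is zero", call. = FALSE)
  predicted <- sum(lookup[records$species])
  100 * (predicted - measured) / measured
}
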