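#' Allometric prediction parameters
#'
#' Container for the parameters of the log-log predictive model:
#' `ln(mass mg) = (b0 + b0_f) + (b1 + b1_f) * ln(forewing length mm)`, where
#' `b1`/`b0` are the reference slope and intercept for the pooled "other
#' families" group and `b1_f`/`b0_f` are per-family adjustments added to them
#' for families retained by the grouping. Families without an adjustment
#' entry receive the plain reference prediction.
#'
#' @param reference_slope Slope for the reference group, ln(mg) per ln(mm).
#' @param reference_intercept Intercept for the reference group, ln(mg).
#' @param family_adjustments Named list, one entry per refined family group,
#'   each a list with elements `slope` and `intercept` (adjustments to add to
#'   the reference values). May be empty.
#' @param grouping A `family_grouping` mapping raw family names to groups.
#' @return An object of class `allometric_parameters`.
#' @seealso [moth_reference_params()], [extract_parameters()], [predict_mass()]
#' @export
allometric_parameters <- function(reference_slope, reference_intercept,
                                  family_adjustments = list(), grouping) {
  stopifnot(is.numeric(reference_slope), is.numeric(reference_intercept),
            inherits(grouping, "family_grouping"))
  for (g in names(family_adjustments)) {
    a <- family_adjustments[[g]]
    if (!all(c("slope", "intercept") %in% names(a))) {
      stop("adjustment for group '", g,
           "' must have elements 'slope' and 'intercept'", call. = FALSE)
    }
    eff <- reference_slope + a$slope
    if (eff <= 0) {
      stop("effective slope for group '", g, "' is not positive (",
           format(eff), "); mass must increase with forewing length",
           call. = FALSE)
    }
  }
  if (reference_slope <= 0) {
    stop("reference slope must be positive", call. = FALSE)
  }
  structure(list(reference_slope = reference_slope,
                 reference_intercept = reference_intercept,
                 family_adjustments = family_adjustments,
                 grouping = grouping),
            class = "allometric_parameters")
}

#' @export
print.allometric_parameters <- function(x, ...) {
  cat("Allometric prediction parameters (ln mg ~ ln mm)\n")
  tab <- params_table(x)
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

# One row per group: the effective slope/intercept actually used to predict.
params_table <- function(params) {
  groups <- c(params$grouping$other_label, names(params$family_adjustments))
  do.call(rbind, lapply(groups, function(g) {
    a <- params$family_adjustments[[g]] %||% list(slope = 0, intercept = 0)
    data.frame(group = g,
               slope_adjustment = a$slope,
               intercept_adjustment = a$intercept,
               effective_slope = params$reference_slope + a$slope,
               effective_intercept = params$reference_intercept + a$intercept)
  }))
}

#' Packaged reference parameters for British moths
#'
#' Returns the published predictive parameters shipped with the package:
#' reference slope 3.056 and intercept -5.016 (ln mg vs ln mm) for the pooled
#' "other families" group, with refinements for the four families that were
#' sampled with five or more species (Crambidae, Erebidae, Geometridae,
#' Noctuidae). These parameters were trained on 600 field-sampled moths of 94
#' species and are the package's default for predicting body mass in
#' abundance-only datasets.
#'
#' @return An [allometric_parameters()] object.
#' @examples
#' p <- moth_reference_params()
#' predict_mass(15, "Noctuidae", p) # about 34.3 mg
#' @export
moth_reference_params <- function() {
  path <- system.file("extdata", "reference_params.yaml", package = "mothmass")
  read_params(path)
}

#' Read and write allometric parameter files
#'
#' Parameters are serialized as a structured YAML key-value file holding the
#' reference slope and intercept, per-family adjustment entries, the family
#' grouping (threshold, pooled label, family -> group map) and an optional
#' provenance block (seed, fit diagnostics, package version).
#'
#' @param path File path.
#' @param params An [allometric_parameters()] object.
#' @param provenance Optional named list stored verbatim under `provenance`.
#' @return `read_params()` returns an `allometric_parameters` object (with
#'   any provenance attached as attribute `"provenance"`);
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  req <- c("reference_slope", "reference_intercept", "grouping")
  missing <- setdiff(req, names(y))
  if (length(missing)) {
    stop("parameter file is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  g <- y$grouping
  map <- unlist(g$families) %||% character(0)
  grouping <- structure(
    list(map = map,
         retained = sort(unique(unname(map[map != g$other_label]))),
         threshold = as.integer(g$threshold %||% 5L),
         other_label = g$other_label %||% "other",
         species_counts = NULL),
    class = "family_grouping"
  )
  adj <- lapply(y$family_adjustments %||% list(), function(a) {
    list(slope = as.numeric(a$slope), intercept = as.numeric(a$intercept))
  })
  params <- allometric_parameters(
    reference_slope = as.numeric(y$reference_slope),
    reference_intercept = as.numeric(y$reference_intercept),
    family_adjustments = adj,
    grouping = grouping
  )
  attr(params, "provenance") <- y$provenance
  params
}

#' @rdname read_params
#' @export
write_params <- function(params, path, provenance = NULL) {
  stopifnot(inherits(params, "allometric_parameters"))
  y <- list(
    reference_slope = params$reference_slope,
    reference_intercept = params$reference_intercept,
    family_adjustments = params$family_adjustments,
    grouping = list(
      threshold = params$grouping$threshold,
      other_label = params$grouping$other_label,
      families = as.list(params$grouping$map)
    )
  )
  if (!is.null(provenance)) y$provenance <- provenance
  yaml::write_yaml(y, path, precision = 15L)
  invisible(path)
}
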