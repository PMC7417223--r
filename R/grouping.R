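#' Simplify the family variable by pooling species-poor families
#'
#' Families represented by fewer than `threshold` distinct species in the
#' data are pooled into a single reference group (default label `"other"`),
#' so that family-specific slope and intercept refinements are only estimated
#' where the data can support them. With the default threshold of 5 this
#' reduces a typical light-trap sample of 11 families to 5 groups.
#'
#' @param records Specimen table (see [validate_specimens()]).
#' @param threshold Minimum number of distinct species a family needs to keep
#'   its own group label. Default 5.
#' @param other_label Label of the pooled group. Default `"other"`.
#' @return An object of class `family_grouping`: a list with `map` (named
#'   character vector, family -> group), `retained` (families keeping their
#'   label), `threshold`, `other_label` and `species_counts`.
#' @examples
#' rec <- data.frame(
#'   specimen_id = 1:6,
#'   species = c("a", "b", "c", "d", "e", "f"),
#'   family  = c("Noctuidae", "Noctuidae", "Noctuidae", "Noctuidae",
#'               "Noctuidae", "Psychidae"),
#'   site = "S1", date = "2018-06-11",
#'   forewing_length_mm = 10, dry_mass_mg = 5
#' )
#' group_families(rec, threshold = 5)
#' @export
group_families <- function(records, threshold = 5L, other_label = "other") {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("specimen table is empty: no data to group", call. = FALSE)
  }
  if (threshold < 1L) stop("threshold must be >= 1", call. = FALSE)
  assert_columns(records, c("species", "family"), what = "specimen table")
  sp <- unique(records[, c("species", "family")])
  counts <- table(sp$family)
  retained <- sort(names(counts)[counts >= threshold])
  map <- stats::setNames(
    ifelse(names(counts) %in% retained, names(counts), other_label),
    names(counts)
  )
  structure(
    list(map = map, retained = retained, threshold = as.integer(threshold),
         other_label = other_label,
         species_counts = as.integer(counts) |> stats::setNames(names(counts))),
    class = "family_grouping"
  )
}

#' @export
print.family_grouping <- function(x, ...) {
  n_groups <- length(unique(x$map))
  cat(sprintf(
    "Family grouping: %d famil%s -> %d group%s (threshold %d species)\n",
    length(x$map), if (length(x$map) == 1) "y" else "ies",
    n_groups, if (n_groups == 1) "" else "s", x$threshold))
  cat("Retained:", if (length(x$retained)) paste(x$retained, collapse = ", ")
      else "(none)", "\n")
  cat("Pooled label:", x$other_label, "\n")
  invisible(x)
}

# Resolve family names to group labels; families never seen in training fall
# back to the pooled reference group (with one consolidated warning).
resolve_group <- function(family, grouping, warn_unknown = TRUE) {
  out <- unname(grouping$map[family])
  unknown <- is.na(out)
  if (any(unknown)) {
    # a caller may already pass group labels (e.g. "other")
    lbls <- c(grouping$other_label, unique(grouping$map))
    direct <- unknown & family %in% lbls
    out[direct] <- family[direct]
    unknown <- is.na(out)
  }
  if (any(unknown)) {
    if (warn_unknown) {
      warning("family not in grouping, predicted as '", grouping$other_label,
              "': ", paste(unique(family[unknown]), collapse = ", "),
              call. = FALSE)
    }
    out[unknown] <- grouping$other_label
  }
  out
}

group_levels <- function(grouping) c(grouping$other_label, grouping$retained)
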