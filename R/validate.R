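#' Species- and sample-level validation of biomass predictions
#'
#' Compares predicted against measured biomass with a Major Axis model II
#' regression on the natural-log scale (masses span several orders of
#' magnitude, and on the raw scale the largest species would dominate the
#' fit entirely).
#'
#' At species level each point is one species: measured value = arithmetic
#' mean dry mass of its individuals, predicted value = its entry in the
#' species-mass table. `min_mass_mg` restricts the fit to species whose
#' measured mean is strictly greater than the threshold (e.g. 15 mg, the
#' subset on which a 1:1 slope is expected to be recovered when small
#' species are over-predicted).
#'
#' At sample level each point is one sample (all moths captured at one site
#' on one day): measured value = summed dry mass, predicted value = summed
#' per-species predictions over the same individuals.
#'
#' @param records Specimen table with measured masses.
#' @param masses Per-species predicted masses ([species_mass_table()] data
#'   frame or named vector).
#' @param min_mass_mg Optional threshold (mg): keep only species with
#'   measured mean mass strictly above it.
#' @param n_perm Permutations for the significance test (default 100).
#' @param seed Optional seed for the permutation test.
#' @return A [major_axis_fit()] object (predicted regressed on measured,
#'   both on the ln scale).
#' @export
species_level_validation <- function(records, masses, min_mass_mg = NULL,
                                     n_perm = 100L, seed = NULL) {
  validate_specimens(records)
  lookup <- as_mass_lookup(masses)
  measured <- tapply(records$dry_mass_mg, records$species, mean)
  sp <- names(measured)
  missing <- setdiff(sp, names(lookup))
  if (length(missing)) {
    stop("species missing from the mass table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.null(min_mass_mg)) {
    sp <- sp[measured[sp] > min_mass_mg]
  }
  if (length(sp) < 3L) {
    stop("fewer than 3 species available for validation", call. = FALSE)
  }
  major_axis_fit(log(as.numeric(measured[sp])), log(as.numeric(lookup[sp])),
                 n_perm = n_perm, seed = seed)
}

#' @rdname species_level_validation
#' @export
sample_level_validation <- function(records, masses, n_perm = 100L,
                                    seed = NULL) {
  validate_specimens(records)
  lookup <- as_mass_lookup(masses)
  missing <- setdiff(unique(records$species), names(lookup))
  if (length(missing)) {
    stop("species missing from the mass table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  key <- sample_key(records)
  measured <- tapply(records$dry_mass_mg, key, sum)
  predicted <- tapply(as.numeric(lookup[records$species]), key, sum)
  if (length(measured) < 3L) {
    stop("fewer than 3 samples available for validation", call. = FALSE)
  }
  major_axis_fit(log(as.numeric(measured)), log(as.numeric(predicted)),
                 n_perm = n_perm, seed = seed)
}

ci_excludes_1 <- function(fit) {
  is.finite(fit$slope_ci95[1]) && is.finite(fit$slope_ci95[2]) &&
    (fit$slope_ci95[1] > 1 || fit$slope_ci95[2] < 1)
}

#' Bootstrap train/test validation of the whole prediction pipeline
#'
#' Repeatedly splits the measured dataset into a training subset (`train_n`
#' individuals drawn without replacement) and an independent testing subset
#' (the remainder). Each replicate refits the simplified log-log model on the
#' training subset — re-deriving the family grouping from that subset, so no
#' information leaks from test to train — predicts the testing individuals'
#' species from their field-guide forewing midpoints, and validates the
#' predictions at species and sample level with Major Axis regressions and
#' one-tailed permutation tests. Replicates whose model fit or validation
#' degenerates (e.g. too few testing species) are logged and redrawn, never
#' silently dropped.
#'
#' @param records Specimen table (the full measured dataset).
#' @param guide Field-guide table with forewing ranges for every species.
#' @param n_replicates Number of bootstrap replicates.
#' @param train_n Training-subset size (individuals); default 480, i.e. 80%
#'   of a 600-moth dataset.
#' @param min_mass_mg Threshold for the large-species subset (measured mean
#'   strictly above; default 15 mg).
#' @param n_perm Permutations per significance test (default 100).
#' @param seed Master seed; per-replicate substreams are derived from it so
#'   results are reproducible.
#' @param p_threshold Significance level used for the "% replicates
#'   significant" summary (default 0.05).
#' @return An object of class `bootstrap_summary`: a data frame with one row
#'   per level (`sample`, `species`, `species_gt15`) and columns
#'   `n_replicates`, `pct_significant`, `pct_slope_not_1`, `mean_r2`,
#'   `se_r2`, plus attributes `n_failed` (redrawn replicates) and
#'   `failure_log`.
#' @export
bootstrap_validation <- function(records, guide, n_replicates = 10000L,
                                 train_n = 480L, min_mass_mg = 15,
                                 n_perm = 100L, seed = NULL,
                                 p_threshold = 0.05) {
  validate_specimens(records)
  n <- nrow(records)
  if (n < train_n + 3L) {
    stop("need at least train_n + 3 records for a train/test split",
         call. = FALSE)
  }
  max_draws <- n_replicates * 2L + 50L
  seeds <- spawn_seeds(seed %||% sample.int(1e6, 1), max_draws)

  res <- vector("list", n_replicates)
  failures <- character(0)
  done <- 0L
  draw <- 0L
  while (done < n_replicates && draw < max_draws) {
    draw <- draw + 1L
    rep_out <- with_seed(seeds[draw], {
      tryCatch(
        bootstrap_replicate(records, guide, train_n, min_mass_mg, n_perm),
        error = function(e) conditionMessage(e)
      )
    })
    if (is.character(rep_out)) {
      failures <- c(failures, sprintf("replicate draw %d: %s", draw, rep_out))
      next
    }
    done <- done + 1L
    res[[done]] <- rep_out
  }
  if (done < n_replicates) {
    stop("bootstrap exhausted its redraw budget; last failure: ",
         utils::tail(failures, 1L), call. = FALSE)
  }

  get <- function(field) vapply(res, `[[`, numeric(1), field)
  summarise_level <- function(prefix) {
    p <- get(paste0(prefix, "_p"))
    excl <- get(paste0(prefix, "_slope_not_1"))
    r2 <- get(paste0(prefix, "_r2"))
    data.frame(
      level = prefix,
      n_replicates = n_replicates,
      pct_significant = 100 * mean(p <= p_threshold, na.rm = TRUE),
      pct_slope_not_1 = 100 * mean(excl, na.rm = TRUE),
      mean_r2 = mean(r2, na.rm = TRUE),
      se_r2 = stats::sd(r2, na.rm = TRUE) / sqrt(sum(!is.na(r2)))
    )
  }
  out <- rbind(summarise_level("sample"),
               summarise_level("species"),
               summarise_level("species_gt15"))
  attr(out, "n_failed") <- length(failures)
  attr(out, "failure_log") <- failures
  class(out) <- c("bootstrap_summary", "data.frame")
  out
}

# One train/test replicate; runs inside its own RNG substream.
bootstrap_replicate <- function(records, guide, train_n, min_mass_mg, n_perm) {
  n <- nrow(records)
  idx <- sample.int(n, train_n, replace = FALSE)
  train <- records[idx, , drop = FALSE]
  test <- records[-idx, , drop = FALSE]

  grouping <- group_families(train, threshold = 5L)
  fit <- suppressWarnings(fit_mixed_allometry(train, "loglog", grouping))
  params <- extract_parameters(fit)

  test_guide <- guide[guide$species %in% unique(test$species), , drop = FALSE]
  missing <- setdiff(unique(test$species), test_guide$species)
  if (length(missing)) {
    stop("testing species missing from the field guide: ",
         paste(missing, collapse = ", "))
  }
  masses <- suppressWarnings(species_mass_table(test_guide, params))

  sp <- suppressWarnings(
    species_level_validation(test, masses, n_perm = n_perm))
  sa <- suppressWarnings(
    sample_level_validation(test, masses, n_perm = n_perm))
  gt <- tryCatch(
    suppressWarnings(species_level_validation(test, masses,
                                              min_mass_mg = min_mass_mg,
                                              n_perm = 0L)),
    error = function(e) NULL
  )
  list(
    species_p = sp$permutation_p,
    species_slope_not_1 = as.numeric(ci_excludes_1(sp)),
    species_r2 = sp$r_squared,
    sample_p = sa$permutation_p,
    sample_slope_not_1 = as.numeric(ci_excludes_1(sa)),
    sample_r2 = sa$r_squared,
    species_gt15_p = NA_real_, # permutation test not run on the subset
    species_gt15_slope_not_1 = if (is.null(gt)) NA_real_
                               else as.numeric(ci_excludes_1(gt)),
    species_gt15_r2 = if (is.null(gt)) NA_real_ else gt$r_squared
  )
}

#' Normalised biomass prediction error
#'
#' Percentage deviation of predicted from measured biomass, re-centred by the
#' whole-dataset prediction offset so that the expected error of a large
#' random sample is zero:
#' `100 * (predicted - measured) / measured - offset_pct`.
#'
#' @param predicted_mg,measured_mg Biomass totals in mg (vectorised);
#'   `measured_mg` must be positive.
#' @param offset_pct The full-dataset offset as computed by
#'   [dataset_prediction_offset()] (a signed percentage).
#' @return Normalised prediction error(s), %.
#' @export
prediction_error <- function(predicted_mg, measured_mg, offset_pct) {
  if (any(measured_mg <= 0)) {
    stop("measured biomass must be positive", call. = FALSE)
  }
  100 * (predicted_mg - measured_mg) / measured_mg - offset_pct
}

#' Prediction error as a function of sample size
#'
#' Draws random samples of individuals (with replacement from the measured
#' dataset) over a grid of sample sizes, computes each sample's measured and
#' predicted biomass and its normalised [prediction_error()], and aggregates
#' the errors in sample-size windows (default width 100). The offset used for
#' normalisation is the whole-dataset offset of `records` against `masses`,
#' computed here rather than hard-coded.
#'
#' @param records Specimen table with measured masses.
#' @param masses Per-species predicted masses.
#' @param sizes Sample sizes to draw (default 10 to 1000 in steps of 10).
#' @param reps_per_size Replicates at each size (default 1000).
#' @param window Window width for aggregation (default 100).
#' @param seed Optional master seed.
#' @return A data frame of class `error_curve`, one row per window:
#'   `window_low`, `window_high`, `n_replicates`, `mean_error`, `se_error`,
#'   `min_error`, `max_error` (all errors in %), with the offset used stored
#'   as attribute `"offset_pct"`.
#' @export
error_vs_sample_size <- function(records, masses,
                                 sizes = seq(10L, 1000L, by = 10L),
                                 reps_per_size = 1000L, window = 100L,
                                 seed = NULL) {
  validate_specimens(records)
  lookup <- as_mass_lookup(masses)
  offset <- dataset_prediction_offset(records, lookup)
  meas <- records$dry_mass_mg
  pred <- as.numeric(lookup[records$species])
  n <- length(meas)

  errs <- with_seed(seed, {
    lapply(sizes, function(sz) {
      idx <- matrix(sample.int(n, sz * reps_per_size, replace = TRUE),
                    nrow = sz)
      m <- colSums(matrix(meas[idx], nrow = sz))
      p <- colSums(matrix(pred[idx], nrow = sz))
      prediction_error(p, m, offset)
    })
  })

  bin <- ceiling(sizes / window)
  rows <- lapply(sort(unique(bin)), function(b) {
    e <- unlist(errs[bin == b], use.names = FALSE)
    in_bin <- sizes[bin == b]
    data.frame(window_low = min(in_bin), window_high = max(in_bin),
               n_replicates = length(e),
               mean_error = mean(e),
               se_error = stats::sd(e) / sqrt(length(e)),
               min_error = min(e), max_error = max(e))
  })
  out <- do.call(rbind, rows)
  attr(out, "offset_pct") <- offset
  class(out) <- c("error_curve", "data.frame")
  out
}
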