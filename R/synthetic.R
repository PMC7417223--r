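#' Configuration for the synthetic moth-community generator
#'
#' Bundles every knob of [simulate_community()] with defaults emulating the
#' study conditions the reference parameters were trained under: 94 species
#' in 11 families (four of them rich enough to retain their own label at the
#' 5-species grouping threshold), 600 measured individuals, generating
#' parameters equal to the packaged reference parameters, species-intercept
#' SD 0.2 and residual SD 0.3 on the ln scale, species mean forewing lengths
#' log-uniform on 7-35 mm, and a 3-site by 15-date sampling grid.
#'
#' @param species_per_family Named integer vector: family -> number of
#'   species.
#' @param individuals Total number of measured individuals (each species is
#'   guaranteed at least one; the remainder is allocated by a multinomial
#'   draw over lognormal species abundances).
#' @param true_reference_slope,true_reference_intercept Generating
#'   parameters of the pooled group on the ln-ln scale.
#' @param true_family_adjustments Named list of `list(slope=, intercept=)`
#'   adjustments for families that deviate from the reference relationship.
#' @param species_intercept_sd SD of the species-level random intercept
#'   (ln scale).
#' @param residual_sd SD of the individual residual (ln scale).
#' @param species_mean_length_range_mm Range the species mean forewing
#'   lengths are drawn from (log-uniformly).
#' @param within_species_length_cv Coefficient of variation of individual
#'   lengths around the species mean (lognormal).
#' @param guide_halfwidth_mm Half-width of the synthetic field-guide range
#'   around the species mean length.
#' @param guide_mean_shift_mm Systematic shift of guide ranges relative to
#'   the true species means (default 0; positive values emulate guides based
#'   on larger historical specimens).
#' @param n_sites,n_dates Sampling grid; individuals are spread uniformly
#'   over the `n_sites * n_dates` site-by-date cells.
#' @param abundance_sdlog `sdlog` of the lognormal species-abundance
#'   distribution (skewed counts typical of light-trap catches).
#' @param quantize Apply measurement quantization: lengths to 1 mm (floor
#'   1 mm), masses to 0.01 mg with individuals below the 0.005 mg detection
#'   limit emitted as below-detection rows. Set `FALSE` for exact noiseless
#'   checks.
#' @param n_unidentified Number of additional family-level-only records
#'   (empty species field) to emit, for exercising the record filters.
#' @param seed Seed used by [simulate_community()].
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    species_per_family = c(Noctuidae = 36L, Geometridae = 22L,
                           Crambidae = 11L, Erebidae = 10L,
                           Sphingidae = 3L, Tortricidae = 3L,
                           Pyralidae = 3L, Lasiocampidae = 2L,
                           Drepanidae = 2L, Pterophoridae = 1L,
                           Psychidae = 1L),
    individuals = 600L,
    true_reference_slope = 3.056,
    true_reference_intercept = -5.016,
    true_family_adjustments = list(
      Crambidae = list(slope = -0.904, intercept = 1.361),
      Erebidae = list(slope = -0.601, intercept = 1.294),
      Geometridae = list(slope = -0.492, intercept = 0.344),
      Noctuidae = list(slope = -1.297, intercept = 3.788)
    ),
    species_intercept_sd = 0.2,
    residual_sd = 0.3,
    species_mean_length_range_mm = c(7, 35),
    within_species_length_cv = 0.05,
    guide_halfwidth_mm = 2,
    guide_mean_shift_mm = 0,
    n_sites = 3L,
    n_dates = 15L,
    abundance_sdlog = 1,
    quantize = TRUE,
    n_unidentified = 0L,
    seed = 1L) {
  if (length(species_per_family) == 0L || any(species_per_family < 1L)) {
    stop("species_per_family must give every family at least one species",
         call. = FALSE)
  }
  if (is.null(names(species_per_family))) {
    stop("species_per_family must be a named vector", call. = FALSE)
  }
  if (individuals < sum(species_per_family)) {
    stop("need at least one individual per species", call. = FALSE)
  }
  if (species_intercept_sd < 0 || residual_sd < 0) {
    stop("noise SDs must be non-negative", call. = FALSE)
  }
  if (any(species_mean_length_range_mm <= 0)) {
    stop("length range must be positive", call. = FALSE)
  }
  cfg <- as.list(environment())
  class(cfg) <- "synthetic_config"
  cfg
}

#' Simulate a moth community with known allometric truth
#'
#' Generates a specimen table, a matching synthetic field guide, and the
#' generating truth, under the allometric mixed model
#' `ln M = b0_g + b1_g ln L + u_s + e` with species random intercepts
#' `u_s ~ N(0, sigma_s^2)` and residuals `e ~ N(0, sigma_e^2)`. Masses are
#' computed from the quantized (measured) lengths, so noiseless
#' configurations lie exactly on the generating line. Measurement
#' quantization reproduces field resolution: lengths to the nearest 1 mm,
#' masses to 0.01 mg with a 0.005 mg detection floor (below-floor
#' individuals are emitted with `below_detection = TRUE` and `NA` mass so
#' the record filters can be exercised).
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `records` (specimen table, including any
#'   below-detection or unidentified rows), `guide` (field-guide table) and
#'   `truth` (list: `params` — the generating [allometric_parameters()];
#'   `species` — data frame of per-species family, true mean length and
#'   random intercept; `config`).
#' @export
simulate_community <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, simulate_community_impl(config))
}

simulate_community_impl <- function(cfg) {
  families <- rep(names(cfg$species_per_family), cfg$species_per_family)
  n_sp <- length(families)
  species <- sprintf("sp%03d", seq_len(n_sp))

  rng <- log(cfg$species_mean_length_range_mm)
  mean_len <- exp(stats::runif(n_sp, rng[1], rng[2]))
  u_s <- stats::rnorm(n_sp, 0, cfg$species_intercept_sd)

  # abundances: one guaranteed individual per species, remainder multinomial
  # over lognormal weights
  w <- stats::rlnorm(n_sp, meanlog = 0, sdlog = cfg$abundance_sdlog)
  extra <- cfg$individuals - n_sp
  counts <- rep(1L, n_sp) +
    if (extra > 0L) as.integer(stats::rmultinom(1, extra, prob = w)) else 0L

  sp_idx <- rep.int(seq_len(n_sp), counts)
  n_ind <- length(sp_idx)

  sdlog <- sqrt(log(1 + cfg$within_species_length_cv^2))
  len_raw <- stats::rlnorm(n_ind, meanlog = log(mean_len[sp_idx]),
                           sdlog = sdlog)
  len <- if (cfg$quantize) pmax(1, round(len_raw)) else len_raw

  slopes <- stats::setNames(rep(cfg$true_reference_slope, n_sp), species)
  ints <- stats::setNames(rep(cfg$true_reference_intercept, n_sp), species)
  for (fam in names(cfg$true_family_adjustments)) {
    a <- cfg$true_family_adjustments[[fam]]
    hit <- families == fam
    slopes[hit] <- slopes[hit] + a$slope
    ints[hit] <- ints[hit] + a$intercept
  }
  ln_mass <- ints[sp_idx] + slopes[sp_idx] * log(len) + u_s[sp_idx] +
    stats::rnorm(n_ind, 0, cfg$residual_sd)
  mass_raw <- exp(ln_mass)
  if (cfg$quantize) {
    below <- mass_raw < 0.005
    mass <- round(mass_raw, 2)
    mass[below] <- NA_real_
  } else {
    below <- rep(FALSE, n_ind)
    mass <- mass_raw
  }

  sites <- sprintf("site%d", seq_len(cfg$n_sites))
  dates <- format(as.Date("2018-06-11") + seq_len(cfg$n_dates) - 1L)
  cell <- sample.int(cfg$n_sites * cfg$n_dates, n_ind, replace = TRUE)

  records <- data.frame(
    specimen_id = sprintf("m%05d", seq_len(n_ind)),
    species = species[sp_idx],
    family = families[sp_idx],
    site = sites[(cell - 1L) %% cfg$n_sites + 1L],
    date = dates[(cell - 1L) %/% cfg$n_sites + 1L],
    forewing_length_mm = len,
    dry_mass_mg = unname(mass),
    below_detection = below
  )

  if (cfg$n_unidentified > 0L) {
    k <- cfg$n_unidentified
    fam_u <- sample(names(cfg$species_per_family), k, replace = TRUE)
    len_u <- pmax(1, round(exp(stats::runif(k, rng[1], rng[2]))))
    mass_u <- round(exp(cfg$true_reference_intercept +
                          cfg$true_reference_slope * log(len_u)), 2)
    cell_u <- sample.int(cfg$n_sites * cfg$n_dates, k, replace = TRUE)
    records <- rbind(records, data.frame(
      specimen_id = sprintf("u%05d", seq_len(k)),
      species = "",
      family = fam_u,
      site = sites[(cell_u - 1L) %% cfg$n_sites + 1L],
      date = dates[(cell_u - 1L) %/% cfg$n_sites + 1L],
      forewing_length_mm = len_u,
      dry_mass_mg = mass_u,
      below_detection = FALSE
    ))
  }

  shift <- cfg$guide_mean_shift_mm
  guide <- data.frame(
    species = species,
    family = families,
    forewing_min_mm = pmax(1, mean_len + shift - cfg$guide_halfwidth_mm),
    forewing_max_mm = mean_len + shift + cfg$guide_halfwidth_mm
  )

  truth_grouping <- structure(
    list(map = stats::setNames(
           ifelse(names(cfg$species_per_family) %in%
                    names(cfg$true_family_adjustments),
                  names(cfg$species_per_family), "other"),
           names(cfg$species_per_family)),
         retained = sort(names(cfg$true_family_adjustments)),
         threshold = 5L, other_label = "other", species_counts = NULL),
    class = "family_grouping"
  )
  truth <- list(
    params = allometric_parameters(cfg$true_reference_slope,
                                   cfg$true_reference_intercept,
                                   cfg$true_family_adjustments,
                                   truth_grouping),
    species = data.frame(species = species, family = families,
                         mean_length_mm = mean_len,
                         random_intercept = unname(u_s)),
    config = cfg
  )
  list(records = records, guide = guide, truth = truth)
}

#' Parameter-recovery experiment on simulated communities
#'
#' Simulates `n_datasets` communities from one configuration, refits the
#' simplified log-log model to each (deriving the family grouping from the
#' simulated records), extracts the prediction parameters, and summarises
#' how well each generating fixed effect is recovered: bias, RMSE, and the
#' fraction of Wald 95% intervals (estimate +/- 1.96 SE) covering the truth.
#'
#' @param config A [synthetic_config()]; its `seed` is replaced per dataset
#'   by substreams of `seed`.
#' @param n_datasets Number of simulated datasets (at least 2).
#' @param seed Master seed for the experiment.
#' @return A data frame of class `recovery_report`, one row per fixed-effect
#'   parameter (`reference_intercept`, `reference_slope`, and per-family
#'   `intercept_adj:`/`slope_adj:` terms): columns `true_value`,
#'   `mean_estimate`, `bias`, `sem` (standard error of the mean estimate),
#'   `rmse`, `ci_coverage`, `n_fits`. Attribute
#'   `"n_failed"` counts datasets whose fit failed (they are reported, not
#'   silently dropped).
#' @export
recovery_experiment <- function(config = synthetic_config(), n_datasets = 200L,
                                seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"), n_datasets >= 2L)
  seeds <- spawn_seeds(seed, n_datasets)
  ests <- list()
  ses <- list()
  n_failed <- 0L
  for (i in seq_len(n_datasets)) {
    cfg <- config
    cfg$seed <- seeds[i]
    sim <- simulate_community(cfg)
    rec <- filter_records(sim$records)$retained
    out <- tryCatch({
      grouping <- group_families(rec, threshold = 5L)
      fit <- suppressWarnings(fit_mixed_allometry(rec, "loglog", grouping))
      named_fixed_effects(fit)
    }, error = function(e) NULL)
    if (is.null(out)) {
      n_failed <- n_failed + 1L
      next
    }
    ests[[length(ests) + 1L]] <- out$estimate
    ses[[length(ses) + 1L]] <- out$se
  }
  if (length(ests) == 0L) stop("every simulated fit failed", call. = FALSE)

  truth <- truth_fixed_effects(config)
  terms <- names(truth)
  report <- do.call(rbind, lapply(terms, function(tm) {
    e <- vapply(ests, function(v) v[tm] %||% NA_real_, numeric(1))
    s <- vapply(ses, function(v) v[tm] %||% NA_real_, numeric(1))
    ok <- !is.na(e)
    cover <- mean(abs(e[ok] - truth[tm]) <= 1.96 * s[ok])
    data.frame(parameter = tm,
               true_value = unname(truth[tm]),
               mean_estimate = mean(e[ok]),
               bias = mean(e[ok]) - unname(truth[tm]),
               sem = stats::sd(e[ok]) / sqrt(sum(ok)),
               rmse = sqrt(mean((e[ok] - truth[tm])^2)),
               ci_coverage = cover,
               n_fits = sum(ok))
  }))
  attr(report, "n_failed") <- n_failed
  class(report) <- c("recovery_report", "data.frame")
  report
}

# Map a loglog fit's coefficients onto the generator's parameter names.
named_fixed_effects <- function(fit) {
  fe <- fit$fixed_effects
  nm <- fe$term
  nm[nm == "(Intercept)"] <- "reference_intercept"
  nm[nm == "ln_length"] <- "reference_slope"
  nm <- sub("^ln_length:group", "slope_adj:", nm)
  nm <- sub("^group", "intercept_adj:", nm)
  list(estimate = stats::setNames(fe$estimate, nm),
       se = stats::setNames(fe$std_error, nm))
}

truth_fixed_effects <- function(cfg) {
  out <- c(reference_intercept = cfg$true_reference_intercept,
           reference_slope = cfg$true_reference_slope)
  for (fam in names(cfg$true_family_adjustments)) {
    a <- cfg$true_family_adjustments[[fam]]
    out[paste0("intercept_adj:", fam)] <- a$intercept
    out[paste0("slope_adj:", fam)] <- a$slope
  }
  out
}
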