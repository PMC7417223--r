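#' Fit a forewing-length to body-mass mixed-effects model
#'
#' Fits a linear mixed model for ln(dry mass) with a species-level random
#' intercept and fixed effects for forewing length, family group, and their
#' interaction, by maximum likelihood (not REML, so that BIC and likelihood
#' ratio comparisons across fixed-effect structures are valid). Three
#' candidate predictor structures are supported:
#'
#' * `"linear"`: ln(M) ~ L x group, length entering on the raw mm scale;
#' * `"loglog"`: ln(M) ~ ln(L) x group, the classical allometric power law;
#' * `"segmented"`: ln(M) ~ (L + (L - psi)+) x group, a single breakpoint
#'   `psi` shared across groups, estimated by profile-likelihood grid search
#'   over the observed unique lengths (excluding the 3 smallest and largest)
#'   and counted as one extra parameter in the BIC.
#'
#' Group effects use treatment coding with the pooled `"other"` group as the
#' reference level, so family coefficients are adjustments to be added to the
#' reference slope and intercept. With a single group the group terms are
#' dropped. All logarithms are natural.
#'
#' @param records Specimen table with positive masses (see
#'   [validate_specimens()]).
#' @param structure One of `"loglog"`, `"linear"`, `"segmented"`.
#' @param grouping A [group_families()] result; defaults to grouping
#'   `records` at the 5-species threshold.
#' @return An object of class `mixed_allometry_fit`: list with elements
#'   `structure`, `model` (the underlying `merMod`), `fixed_effects`
#'   (data frame of estimates and standard errors),
#'   `random_intercept_variance`, `residual_variance`, `log_likelihood`,
#'   `bic`, `n_obs`, `n_species`, `n_groups`, `breakpoint_mm` (segmented
#'   only), `grouping` and `data_ids`.
#'
#'   The BIC is `-2 logLik + k ln(n_obs)` with `k` counting all fixed
#'   effects, both variance components, and the breakpoint when present.
#' @export
fit_mixed_allometry <- function(records,
                                structure = c("loglog", "linear", "segmented"),
                                grouping = group_families(records)) {
  structure <- match.arg(structure)
  validate_specimens(records)
  if (any(records$dry_mass_mg <= 0) || any(records$forewing_length_mm <= 0)) {
    stop("masses and lengths must be strictly positive", call. = FALSE)
  }

  dat <- data.frame(
    ln_mass = log(records$dry_mass_mg),
    length_mm = as.numeric(records$forewing_length_mm),
    ln_length = log(as.numeric(records$forewing_length_mm)),
    species = factor(records$species),
    group = factor(resolve_group(records$family, grouping),
                   levels = group_levels(grouping))
  )
  dat$group <- droplevels(dat$group)

  if (structure == "segmented") {
    fit <- fit_segmented(dat)
    model <- fit$model
    breakpoint <- fit$breakpoint
    extra_par <- 1L
  } else {
    pred <- if (structure == "loglog") "ln_length" else "length_mm"
    model <- fit_one_lmm(dat, pred)
    breakpoint <- NULL
    extra_par <- 0L
  }

  new_allometry_fit(model, structure, grouping, dat,
                    ids = sort(as.character(records$specimen_id)),
                    breakpoint = breakpoint, extra_par = extra_par)
}

build_formula <- function(pred, dat) {
  rhs <- if (nlevels(dat$group) > 1L) paste0(pred, " * group") else pred
  stats::as.formula(paste0("ln_mass ~ ", rhs, " + (1 | species)"))
}

fit_one_lmm <- function(dat, pred) {
  form <- build_formula(pred, dat)
  ctrl <- lme4::lmerControl(optimizer = "bobyqa",
                            check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  model <- withCallingHandlers(
    lme4::lmer(form, data = dat, REML = FALSE, control = ctrl),
    warning = function(w) {
      if (grepl("failed to converge", conditionMessage(w))) {
        stop("mixed-model fit failed to converge: ", conditionMessage(w),
             call. = FALSE)
      }
      invokeRestart("muffleWarning")
    }
  )
  if (lme4::isSingular(model)) {
    warning("species random-intercept variance estimated as 0 (singular fit)",
            call. = FALSE)
  }
  model
}

# Profile-likelihood grid search for the shared breakpoint of the segmented
# structure: candidate psi are observed unique lengths with the 3 smallest
# and 3 largest excluded, so both segments retain support.
fit_segmented <- function(dat) {
  u <- sort(unique(dat$length_mm))
  cand <- if (length(u) > 6L) u[4:(length(u) - 3L)] else u
  if (length(cand) == 0L) {
    stop("too few distinct forewing lengths for a segmented fit", call. = FALSE)
  }
  best <- NULL
  for (psi in cand) {
    d <- dat
    d$hinge <- pmax(d$length_mm - psi, 0)
    rhs <- if (nlevels(d$group) > 1L) "(length_mm + hinge) * group"
           else "length_mm + hinge"
    form <- stats::as.formula(paste0("ln_mass ~ ", rhs, " + (1 | species)"))
    # extreme candidates can make the hinge collinear within a group; lme4
    # then drops columns, which is fine for the profile comparison
    m <- try(suppressMessages(suppressWarnings(
      lme4::lmer(form, data = d, REML = FALSE,
                 control = lme4::lmerControl(optimizer = "bobyqa",
                                             check.conv.singular = "ignore",
                                             calc.derivs = FALSE))
    )), silent = TRUE)
    if (inherits(m, "try-error")) next
    ll <- as.numeric(stats::logLik(m))
    if (is.null(best) || ll > best$ll) best <- list(model = m, psi = psi, ll = ll)
  }
  if (is.null(best)) {
    stop("segmented fit failed at every candidate breakpoint", call. = FALSE)
  }
  list(model = best$model, breakpoint = best$psi)
}

new_allometry_fit <- function(model, structure, grouping, dat, ids,
                              breakpoint = NULL, extra_par = 0L) {
  vc <- as.data.frame(lme4::VarCorr(model))
  sigma_s2 <- vc$vcov[vc$grp == "species"]
  sigma_e2 <- vc$vcov[vc$grp == "Residual"]
  beta <- lme4::fixef(model)
  se <- sqrt(diag(as.matrix(stats::vcov(model))))
  ll <- as.numeric(stats::logLik(model))
  n <- nrow(dat)
  k <- length(beta) + 2L + extra_par
  structure(
    list(structure = structure,
         model = model,
         fixed_effects = data.frame(term = names(beta),
                                    estimate = unname(beta),
                                    std_error = unname(se)),
         random_intercept_variance = sigma_s2,
         residual_variance = sigma_e2,
         log_likelihood = ll,
         bic = -2 * ll + k * log(n),
         n_parameters = k,
         n_obs = n,
         n_species = nlevels(dat$species),
         n_groups = nlevels(dat$group),
         breakpoint_mm = breakpoint,
         grouping = grouping,
         data = dat,
         data_ids = ids),
    class = "mixed_allometry_fit"
  )
}

#' @export
print.mixed_allometry_fit <- function(x, ...) {
  cat(sprintf("Allometric mixed model (%s structure)\n", x$structure))
  cat(sprintf("  %d moths, %d species, %d family group%s\n",
              x$n_obs, x$n_species, x$n_groups,
              if (x$n_groups == 1) "" else "s"))
  if (!is.null(x$breakpoint_mm)) {
    cat(sprintf("  breakpoint at %.1f mm\n", x$breakpoint_mm))
  }
  cat(sprintf("  logLik %.2f  BIC %.1f  (k = %d)\n",
              x$log_likelihood, x$bic, x$n_parameters))
  cat(sprintf("  sigma^2 species %.4f, residual %.4f\n",
              x$random_intercept_variance, x$residual_variance))
  print(x$fixed_effects, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Select the best-supported model structure by BIC
#'
#' Compares candidate fits of the same observations (the candidates must have
#' been fitted by maximum likelihood to identical records, which this
#' function checks via the specimen identifiers) and returns the fit with the
#' smallest BIC; ties are broken toward the fit with fewer parameters.
#'
#' @param fits A list of [fit_mixed_allometry()] results.
#' @return The selected `mixed_allometry_fit`.
#' @export
select_structure <- function(fits) {
  if (inherits(fits, "mixed_allometry_fit")) return(fits)
  stopifnot(length(fits) >= 1L)
  if (length(fits) == 1L) return(fits[[1L]])
  ids <- lapply(fits, `[[`, "data_ids")
  if (!all(vapply(ids[-1], identical, logical(1), ids[[1]]))) {
    stop("candidate fits were made on differing record sets; ",
         "BIC values are not comparable", call. = FALSE)
  }
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  k <- vapply(fits, `[[`, numeric(1), "n_parameters")
  fits[[order(bic, k)[1L]]]
}

#' Likelihood ratio test for the family-by-length interaction
#'
#' Refits the log-log model with and without the group-by-length interaction
#' (both by maximum likelihood) and compares them by a likelihood ratio test.
#' The chi-square statistic is twice the log-likelihood difference, with
#' degrees of freedom equal to the number of interaction coefficients
#' dropped. With a single group the two models coincide and the statistic is
#' exactly zero.
#'
#' @inheritParams fit_mixed_allometry
#' @return An object of class `lrt_result`: list with `chi_square`, `df`,
#'   `p_value`, and the two log-likelihoods.
#' @export
lrt_family_interaction <- function(records, grouping = group_families(records)) {
  validate_specimens(records)
  full <- fit_mixed_allometry(records, "loglog", grouping)
  dat <- full$data
  if (nlevels(dat$group) > 1L) {
    form_red <- ln_mass ~ ln_length + group + (1 | species)
  } else {
    form_red <- ln_mass ~ ln_length + (1 | species)
  }
  reduced <- suppressWarnings(
    lme4::lmer(form_red, data = dat, REML = FALSE,
               control = lme4::lmerControl(optimizer = "bobyqa",
                                           check.conv.singular = "ignore",
                                           calc.derivs = FALSE))
  )
  ll_full <- full$log_likelihood
  ll_red <- as.numeric(stats::logLik(reduced))
  df <- length(lme4::fixef(full$model)) - length(lme4::fixef(reduced))
  chi <- max(0, 2 * (ll_full - ll_red))
  p <- if (df >= 1L) stats::pchisq(chi, df = df, lower.tail = FALSE) else 1
  structure(list(chi_square = chi, df = df, p_value = p,
                 log_likelihood_full = ll_full,
                 log_likelihood_reduced = ll_red),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("Likelihood ratio test: chi^2 = %.3g, df = %d, p = %.3g\n",
              x$chi_square, x$df, x$p_value))
  invisible(x)
}

#' Marginal R-squared of a fitted allometric mixed model
#'
#' Proportion of variance on the ln(mass) scale explained by the fixed
#' effects alone: `var(fitted fixed-effect predictions)` divided by that
#' variance plus the species random-intercept variance and the residual
#' variance (the Nakagawa-Schielzeth variance partition for a Gaussian mixed
#' model).
#'
#' @param fit A [fit_mixed_allometry()] result.
#' @return A proportion in `[0, 1]`.
#' @export
marginal_r2 <- function(fit) {
  stopifnot(inherits(fit, "mixed_allometry_fit"))
  mu <- stats::predict(fit$model, re.form = NA)
  vf <- stats::var(mu)
  vf / (vf + fit$random_intercept_variance + fit$residual_variance)
}

#' Extract prediction parameters from a fitted log-log model
#'
#' Converts the fixed effects of a log-log mixed-model fit into the
#' prediction parameter layout used downstream: a reference slope and
#' intercept (the pooled "other families" group) plus per-family slope and
#' intercept adjustments to be added to the reference values. Because the
#' fits use treatment coding with the pooled group as reference, the
#' adjustments are literally the interaction and main-effect coefficients.
#'
#' @param fit A [fit_mixed_allometry()] result with `structure = "loglog"`.
#' @return An [allometric_parameters()] object. Predictions made from it
#'   reproduce the fit's fixed-effect predictions exactly.
#' @export
extract_parameters <- function(fit) {
  stopifnot(inherits(fit, "mixed_allometry_fit"))
  if (fit$structure != "loglog") {
    stop("prediction parameters are defined only for the loglog structure ",
         "(the formula is linear on the ln-ln scale)", call. = FALSE)
  }
  beta <- stats::setNames(fit$fixed_effects$estimate, fit$fixed_effects$term)
  ref_int <- unname(beta[["(Intercept)"]])
  ref_slope <- unname(beta[["ln_length"]])
  # treatment coding: reference is the first factor level (the pooled group
  # whenever it is present in the data)
  groups <- levels(fit$data$group)[-1L]
  adj <- lapply(groups, function(g) {
    list(slope = unname(beta[paste0("ln_length:group", g)]) %||% 0,
         intercept = unname(beta[paste0("group", g)]) %||% 0)
  })
  adj <- lapply(adj, function(a) lapply(a, function(v) ifelse(is.na(v), 0, v)))
  names(adj) <- groups
  allometric_parameters(reference_slope = ref_slope,
                        reference_intercept = ref_int,
                        family_adjustments = adj,
                        grouping = fit$grouping)
}
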