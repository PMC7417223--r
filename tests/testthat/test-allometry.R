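test_that("family grouping pools species-poor families at the threshold", {
  # 11 families, 4 of them with >= 5 species, as in a typical rich catch
  counts <- c(Noctuidae = 36L, Geometridae = 22L, Crambidae = 11L,
              Erebidae = 10L, Sphingidae = 3L, Tortricidae = 3L,
              Pyralidae = 3L, Lasiocampidae = 2L, Drepanidae = 2L,
              Pterophoridae = 1L, Psychidae = 1L)
  rec <- make_records(
    species = sprintf("sp%03d", seq_len(sum(counts))),
    family = rep(names(counts), counts),
    length_mm = 10, mass_mg = 5
  )
  g <- group_families(rec, threshold = 5L)
  expect_length(unique(g$map), 5L)
  expect_setequal(g$retained,
                  c("Crambidae", "Erebidae", "Geometridae", "Noctuidae"))
  expect_true(all(g$map[c("Sphingidae", "Psychidae")] == "other"))

  # exactly at the threshold a family keeps its own label
  rec5 <- make_records(sprintf("s%d", 1:5), "Hepialidae", 10, 5)
  expect_identical(group_families(rec5, 5L)$retained, "Hepialidae")

  # all families below the threshold collapse to a single pooled group
  rec_small <- make_records(sprintf("s%d", 1:4),
                            rep(c("FamA", "FamB"), each = 2), 10, 5)
  g_small <- group_families(rec_small, 5L)
  expect_length(g_small$retained, 0L)
  expect_length(unique(g_small$map), 1L)

  expect_error(group_families(rec[0, ]), "empty")
})

test_that("noiseless synthetic data recover the generating coefficients", {
  sim <- simulate_community(noiseless_config(seed = 11L))
  rec <- filter_records(sim$records)$retained
  fit <- suppressWarnings(
    fit_mixed_allometry(rec, "loglog", group_families(rec)))
  est <- mothmass:::named_fixed_effects(fit)$estimate
  truth <- mothmass:::truth_fixed_effects(sim$truth$config)
  rel <- abs(est[names(truth)] - truth) / abs(truth)
  expect_lt(max(rel), 1e-3)
})

test_that("reference slope is recovered within its standard error", {
  hits <- vapply(1:10, function(s) {
    sim <- simulate_community(small_config(seed = s))
    rec <- filter_records(sim$records)$retained
    fit <- suppressWarnings(
      fit_mixed_allometry(rec, "loglog", group_families(rec)))
    fe <- fit$fixed_effects
    i <- fe$term == "ln_length"
    abs(fe$estimate[i] - 3.056) <= 3 * fe$std_error[i]
  }, logical(1))
  expect_gte(sum(hits), 9L)
})

test_that("BIC is invariant to mass units on the ln scale and shifts by
           n ln(c^2) on the mass scale", {
  sim <- simulate_community(small_config(seed = 3L))
  rec <- filter_records(sim$records)$retained
  g <- group_families(rec)
  fit_mg <- suppressWarnings(fit_mixed_allometry(rec, "loglog", g))
  rec_g <- rec
  rec_g$dry_mass_mg <- rec$dry_mass_mg / 1000 # relabelled: masses in grams
  fit_g <- suppressWarnings(fit_mixed_allometry(rec_g, "loglog", g))

  # shifting the response by -ln(1000) is absorbed by the intercept
  expect_equal(fit_g$bic, fit_mg$bic, tolerance = 1e-6)

  # on the mass scale the Jacobian term moves the BIC by exactly n ln(c^2)
  mass_bic <- function(fit, masses) fit$bic + 2 * sum(log(masses))
  n <- fit_mg$n_obs
  expect_equal(
    mass_bic(fit_mg, rec$dry_mass_mg) - mass_bic(fit_g, rec_g$dry_mass_mg),
    n * log(1000^2),
    tolerance = 1e-6
  )
})

test_that("fitted values are invariant to the choice of reference level", {
  sim <- simulate_community(small_config(seed = 5L))
  rec <- filter_records(sim$records)$retained
  g <- group_families(rec)
  fit <- suppressWarnings(fit_mixed_allometry(rec, "loglog", g))

  dat <- fit$data
  dat$group <- stats::relevel(dat$group, ref = "Noctuidae")
  refit <- suppressWarnings(
    lme4::lmer(ln_mass ~ ln_length * group + (1 | species), data = dat,
               REML = FALSE,
               control = lme4::lmerControl(optimizer = "bobyqa",
                                           check.conv.singular = "ignore")))
  expect_lt(max(abs(stats::predict(fit$model, re.form = NA) -
                      stats::predict(refit, re.form = NA))), 1e-8)
})

test_that("structure selection minimises BIC and demands matched records", {
  sim <- simulate_community(small_config(seed = 21L))
  rec <- filter_records(sim$records)$retained
  g <- group_families(rec)
  fits <- suppressWarnings(list(
    loglog = fit_mixed_allometry(rec, "loglog", g),
    linear = fit_mixed_allometry(rec, "linear", g)
  ))
  best <- select_structure(fits)
  expect_identical(best$structure, "loglog")
  expect_lte(best$bic, fits$linear$bic)

  # a single candidate passes through unchanged
  expect_identical(select_structure(fits["loglog"]), fits$loglog)

  # differing record sets are not comparable
  fits$linear <- suppressWarnings(
    fit_mixed_allometry(rec[-1, ], "linear", g))
  expect_error(select_structure(fits), "differing record sets")
})

test_that("the loglog structure wins BIC on data generated under it", {
  wins <- vapply(1:5, function(s) {
    sim <- simulate_community(small_config(seed = 100L + s))
    rec <- filter_records(sim$records)$retained
    g <- group_families(rec)
    fits <- suppressWarnings(list(
      fit_mixed_allometry(rec, "loglog", g),
      fit_mixed_allometry(rec, "linear", g),
      fit_mixed_allometry(rec, "segmented", g)
    ))
    select_structure(fits)$structure == "loglog"
  }, logical(1))
  expect_gte(sum(wins), 4L)
})

test_that("likelihood ratio test matches the deviance difference", {
  sim <- simulate_community(small_config(seed = 9L))
  rec <- filter_records(sim$records)$retained
  g <- group_families(rec)
  lrt <- suppressWarnings(lrt_family_interaction(rec, g))
  expect_gte(lrt$chi_square, 0)
  expect_equal(lrt$chi_square,
               2 * (lrt$log_likelihood_full - lrt$log_likelihood_reduced),
               tolerance = 1e-10)
  expect_identical(lrt$df, 2L) # two retained families in the small community
  expect_true(lrt$p_value >= 0 && lrt$p_value <= 1)

  # one group: full and reduced models coincide
  one_fam <- rec[rec$family == "Noctuidae", , drop = FALSE]
  g1 <- group_families(one_fam, threshold = 99L)
  lrt1 <- suppressWarnings(lrt_family_interaction(one_fam, g1))
  expect_equal(lrt1$chi_square, 0, tolerance = 1e-6)
})

test_that("marginal R2 approaches its analytic limits", {
  sim <- simulate_community(noiseless_config(seed = 2L))
  rec <- filter_records(sim$records)$retained
  fit0 <- suppressWarnings(
    fit_mixed_allometry(rec, "loglog", group_families(rec)))
  expect_gt(marginal_r2(fit0), 0.999)

  # intercept-only generation: species mean masses unrelated to length
  set.seed(4)
  n_sp <- 12L
  sp <- sprintf("s%02d", seq_len(n_sp))
  idx <- rep(seq_len(n_sp), each = 20L)
  rec_flat <- make_records(
    species = sp[idx], family = "FamA",
    length_mm = sample(5:40, length(idx), replace = TRUE),
    mass_mg = exp(rnorm(n_sp, 2, 0.5))[idx] * exp(rnorm(length(idx), 0, 0.3))
  )
  fit_flat <- suppressWarnings(
    fit_mixed_allometry(rec_flat, "loglog", group_families(rec_flat)))
  expect_lt(marginal_r2(fit_flat), 0.15)
})

test_that("extracted parameters reproduce the fixed-effect predictions", {
  sim <- simulate_community(small_config(seed = 13L))
  rec <- filter_records(sim$records)$retained
  g <- group_families(rec)
  fit <- suppressWarnings(fit_mixed_allometry(rec, "loglog", g))
  params <- extract_parameters(fit)

  ln_pred <- log(predict_mass(rec$forewing_length_mm, rec$family, params))
  expect_lt(max(abs(ln_pred - stats::predict(fit$model, re.form = NA))),
            1e-10)

  # only defined on the ln-ln scale
  fit_lin <- suppressWarnings(fit_mixed_allometry(rec, "linear", g))
  expect_error(extract_parameters(fit_lin), "loglog")

  # pooled-only grouping carries no adjustments
  one <- rec[rec$family == "Pyralidae" | rec$family == "Crambidae", ]
  g1 <- group_families(one, threshold = 99L)
  fit1 <- suppressWarnings(fit_mixed_allometry(one, "loglog", g1))
  expect_length(extract_parameters(fit1)$family_adjustments, 0L)
})

test_that("segmented fits estimate a breakpoint inside the length range", {
  sim <- simulate_community(small_config(seed = 31L))
  rec <- filter_records(sim$records)$retained
  fit <- suppressWarnings(
    fit_mixed_allometry(rec, "segmented", group_families(rec)))
  expect_true(fit$breakpoint_mm > min(rec$forewing_length_mm) &&
                fit$breakpoint_mm < max(rec$forewing_length_mm))
  expect_identical(fit$n_parameters,
                   nrow(fit$fixed_effects) + 3L) # +sigma_s, sigma_e, psi
})
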