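table1 <- moth_reference_params()

test_that("packaged parameters evaluate the published prediction formula", {
  # hand evaluation of ln(mass) = (b1 + b1_f) ln(L) + (b0 + b0_f)
  expect_equal(predict_mass(1, "other", table1), exp(-5.016),
               tolerance = 1e-6)
  expect_equal(predict_mass(15, "Noctuidae", table1),
               exp(log(15) * (3.056 - 1.297) + (-5.016 + 3.788)),
               tolerance = 1e-6)
  expect_equal(predict_mass(10, "Geometridae", table1),
               exp(log(10) * (3.056 - 0.492) + (-5.016 + 0.344)),
               tolerance = 1e-6)
  # sanity on magnitude: a 15 mm noctuid weighs about 34.3 mg dry
  expect_equal(predict_mass(15, "Noctuidae", table1), 34.3, tolerance = 1e-2)
})

test_that("unknown families fall back to the pooled prediction with warning", {
  expect_warning(m <- predict_mass(12, "Saturniidae", table1),
                 "other")
  expect_equal(m, unname(exp(log(12) * 3.056 - 5.016)), tolerance = 1e-12)
  expect_error(predict_mass(0, "Noctuidae", table1), "positive")
  expect_error(predict_mass(-3, "Noctuidae", table1), "positive")
})

test_that("predictions are monotone and exactly log-linear per family", {
  for (fam in c("other", "Crambidae", "Erebidae", "Geometridae",
                "Noctuidae")) {
    lens <- c(5, 12, 29)
    m <- predict_mass(lens, rep(fam, 3), table1)
    expect_true(all(diff(m) > 0), info = fam)
    # three-point collinearity of ln(mass) in ln(length)
    s1 <- (log(m[2]) - log(m[1])) / (log(lens[2]) - log(lens[1]))
    s2 <- (log(m[3]) - log(m[2])) / (log(lens[3]) - log(lens[2]))
    expect_lt(abs(s1 - s2), 1e-12)
  }
})

test_that("species expected mass uses the arithmetic field-guide midpoint", {
  guide <- data.frame(species = c("a", "b"), family = "Noctuidae",
                      forewing_min_mm = c(10, 15), forewing_max_mm = c(20, 15))
  m <- species_expected_mass(guide, table1)
  expect_equal(m[1], predict_mass(15, "Noctuidae", table1))
  # degenerate range min = max = L
  expect_equal(m[2], predict_mass(15, "Noctuidae", table1))

  tab <- species_mass_table(guide, table1)
  expect_named(tab, c("species", "family_group", "expected_forewing_mm",
                      "predicted_mass_mg"))
  expect_equal(tab$expected_forewing_mm, c(15, 15))

  bad <- guide
  bad$forewing_min_mm[1] <- 25
  expect_error(species_expected_mass(bad, table1), "min <= max")
})

test_that("guide midpoints at the true species means give accurate species
           predictions", {
  sim <- simulate_community(small_config(seed = 17L))
  rec <- filter_records(sim$records)$retained
  fit <- suppressWarnings(
    fit_mixed_allometry(rec, "loglog", group_families(rec)))
  masses <- species_mass_table(sim$guide, extract_parameters(fit))
  measured <- species_mean_masses(rec)
  common <- intersect(names(measured), masses$species)
  r2 <- cor(log(as.numeric(measured[common])),
            log(masses$predicted_mass_mg[match(common, masses$species)]))^2
  expect_gt(r2, 0.95)
})

test_that("sample biomass is an additive abundance-weighted sum", {
  masses <- c(A = 10, B = 20)
  expect_equal(sample_biomass(c(A = 2, B = 3), masses), 80)
  expect_equal(sample_biomass(numeric(0), masses), 0)

  # conservation under splitting a sample
  full <- c(A = 5, B = 7)
  half1 <- c(A = 2, B = 3)
  half2 <- c(A = 3, B = 4)
  expect_equal(sample_biomass(half1, masses) + sample_biomass(half2, masses),
               sample_biomass(full, masses))

  expect_error(sample_biomass(c(A = 1, C = 2), masses), "C")
})

test_that("the dataset offset is a signed percentage of measured biomass", {
  rec <- make_records(c("A", "A", "B"), "FamX", c(10, 10, 12), c(5, 7, 10))
  # predictions equal to measured species means: offset exactly zero
  expect_equal(dataset_prediction_offset(rec, species_mean_masses(rec)), 0)
  # doubling every mass: +100%
  expect_equal(dataset_prediction_offset(rec, c(A = 12, B = 20)), 100)
  # under-prediction is negative
  expect_lt(dataset_prediction_offset(rec, c(A = 3, B = 8)), 0)
})
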