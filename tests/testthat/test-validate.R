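test_that("prediction error normalises by the dataset offset", {
  expect_equal(prediction_error(96.6, 100, -3.4), 0, tolerance = 1e-12)
  expect_equal(prediction_error(100, 100, 0), 0)
  expect_equal(prediction_error(90, 100, -3.4), -6.6, tolerance = 1e-12)
  expect_error(prediction_error(10, 0, 0), "positive")
})

test_that("validation against a self-derived mass table is the identity", {
  sim <- simulate_community(small_config(seed = 23L))
  rec <- filter_records(sim$records)$retained
  masses <- species_mean_masses(rec)

  sp <- species_level_validation(rec, masses, n_perm = 100, seed = 1)
  expect_equal(sp$slope, 1, tolerance = 1e-12)
  expect_equal(sp$intercept, 0, tolerance = 1e-10)
  expect_equal(sp$permutation_p, 1 / 101)

  # per-individual masses equal to the species value: samples also identical
  rec_const <- rec
  rec_const$dry_mass_mg <- as.numeric(masses[rec_const$species])
  sa <- sample_level_validation(rec_const, masses)
  expect_equal(sa$slope, 1, tolerance = 1e-12)
})

test_that("species-level validation respects the mass threshold", {
  sim <- simulate_community(synthetic_config(seed = 29L))
  rec <- filter_records(sim$records)$retained
  masses <- species_mass_table(sim$guide, sim$truth$params)

  full <- species_level_validation(rec, masses)
  measured <- species_mean_masses(rec)
  big <- species_level_validation(rec, masses, min_mass_mg = 15)
  expect_identical(big$n_points, sum(measured > 15))
  expect_lt(big$n_points, full$n_points)

  # a threshold keeping fewer than 3 species is an error
  expect_error(
    species_level_validation(rec, masses, min_mass_mg = max(measured)),
    "fewer than 3")
})

test_that("merging two samples removes one point and leaves others fixed", {
  sim <- simulate_community(small_config(seed = 41L))
  rec <- filter_records(sim$records)$retained
  masses <- species_mean_masses(rec)
  keys <- unique(paste(rec$site, rec$date))
  n0 <- sample_level_validation(rec, masses)$n_points
  expect_identical(n0, length(keys))

  merged <- rec
  from <- merged$site == merged$site[1] & merged$date == merged$date[1]
  merged$site[from] <- merged$site[which(!from)[1]]
  merged$date[from] <- merged$date[which(!from)[1]]
  expect_identical(sample_level_validation(merged, masses)$n_points, n0 - 1L)
})

test_that("bootstrap summaries are reproducible and well-formed", {
  sim <- simulate_community(synthetic_config(seed = 37L))
  rec <- filter_records(sim$records)$retained

  s1 <- bootstrap_validation(rec, sim$guide, n_replicates = 3, train_n = 480,
                             n_perm = 20, seed = 202)
  s2 <- bootstrap_validation(rec, sim$guide, n_replicates = 3, train_n = 480,
                             n_perm = 20, seed = 202)
  expect_identical(as.data.frame(s1), as.data.frame(s2))

  expect_setequal(s1$level, c("sample", "species", "species_gt15"))
  num <- s1[s1$level != "species_gt15", ]
  expect_true(all(num$pct_significant >= 0 & num$pct_significant <= 100))
  expect_true(all(num$mean_r2 >= 0 & num$mean_r2 <= 1))
  expect_true(all(num$se_r2 >= 0))

  expect_error(
    bootstrap_validation(rec[1:100, ], sim$guide, n_replicates = 1,
                         train_n = 99),
    "train_n")
})

test_that("error curve centres on zero with exact masses and zero offset", {
  sim <- simulate_community(small_config(seed = 43L))
  rec <- filter_records(sim$records)$retained
  masses <- species_mean_masses(rec) # offset is exactly 0 by construction

  curve <- error_vs_sample_size(rec, masses, sizes = seq(10, 200, 10),
                                reps_per_size = 200, window = 100, seed = 5)
  expect_equal(attr(curve, "offset_pct"), 0, tolerance = 1e-12)
  expect_true(all(curve$min_error <= curve$mean_error &
                    curve$mean_error <= curve$max_error))
  expect_identical(curve$n_replicates, c(2000L, 2000L))
  # law of large numbers: the larger window is tightly centred
  expect_lt(abs(curve$mean_error[2]), 1)
  expect_lt(curve$se_error[2], curve$se_error[1])
})

test_that("error curve is reproducible under a fixed seed", {
  sim <- simulate_community(small_config(seed = 47L))
  rec <- filter_records(sim$records)$retained
  masses <- species_mean_masses(rec)
  c1 <- error_vs_sample_size(rec, masses, sizes = c(10, 20), reps_per_size = 50,
                             seed = 8)
  c2 <- error_vs_sample_size(rec, masses, sizes = c(10, 20), reps_per_size = 50,
                             seed = 8)
  expect_identical(c1, c2)
})
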