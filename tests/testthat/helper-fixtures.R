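# Shared builders for small synthetic communities and hand-made tables.

# Small community: two retained families, two pooled, ~120 moths.
small_config <- function(..., individuals = 120L) {
  synthetic_config(
    species_per_family = c(Noctuidae = 6L, Geometridae = 6L,
                           Crambidae = 2L, Pyralidae = 2L),
    individuals = individuals,
    true_family_adjustments = list(
      Noctuidae = list(slope = -1.297, intercept = 3.788),
      Geometridae = list(slope = -0.492, intercept = 0.344)
    ),
    n_sites = 2L, n_dates = 5L,
    ...
  )
}

# Exact data on the generating surface: no species or residual noise, no
# measurement quantization.
noiseless_config <- function(...) {
  small_config(species_intercept_sd = 0, residual_sd = 0, quantize = FALSE,
               ...)
}

# Hand-made specimen table (identified, above detection limit).
make_records <- function(species, family, length_mm, mass_mg,
                         site = "site1", date = "2018-06-11") {
  n <- length(species)
  data.frame(
    specimen_id = sprintf("t%04d", seq_len(n)),
    species = species,
    family = family,
    site = rep_len(site, n),
    date = rep_len(date, n),
    forewing_length_mm = rep_len(length_mm, n),
    dry_mass_mg = rep_len(mass_mg, n)
  )
}

# Mass lookup straight from per-species measured means.
species_mean_masses <- function(records) {
  tapply(records$dry_mass_mg, records$species, mean)
}
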