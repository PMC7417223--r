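# Packaged predictive parameters for estimating moth dry body mass (mg) from
# forewing length (mm) on the natural-log scale:
#   ln(mass) = (reference_intercept + intercept adj) +
#              (reference_slope + slope adj) * ln(length)
# Trained on 600 field-sampled moths (94 species, 11 families); families
# sampled with >= 5 species carry their own adjustments, all others use the
# pooled reference parameters.
reference_slope: 3.056
reference_intercept: -5.016
family_adjustments:
  Crambidae:
    slope: -0.904
    intercept: 1.361
  Erebidae:
    slope: -0.601
    intercept: 1.294
  Geometridae:
    slope: -0.492
    intercept: 0.344
  Noctuidae:
    slope: -1.297
    intercept: 3.788
grouping:
  threshold: 5
  other_label: other
  families:
    Crambidae: Crambidae
    Erebidae: Erebidae
    Geometridae: Geometridae
    Noctuidae: Noctuidae
provenance:
  source: published reference fit (600 moths, 94 species, 2018 UK field sample)
  n_obs: 600
  n_species: 94
  n_families: 11
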