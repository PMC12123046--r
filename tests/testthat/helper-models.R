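# Shared fixtures, built in code.

# Reference decay model: published coefficients over CAG 17-55, pool 7578.
ref_model <- function() {
  decay_model(decay_fit(5.552482, -0.13925, fit_range = c(18, 35)),
              model_range = c(17, 55), allele_pool = 7578)
}

# One calibration per test run (deterministic, cheap to build).
CAL <- hd_calibration()

# Noiseless allele table following an exact decay law.
law_table <- function(intercept, slope, cags) {
  allele_table(cags, 10^(intercept + slope * cags))
}
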