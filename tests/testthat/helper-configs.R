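# Small, fast study configurations used across the test files.

small_config <- function(seed = 7, panel = default_panel(6), ...) {
  synthetic_config(
    seed = seed, panel = panel,
    n_probands = 12, n_controls = 6, n_parents = 12,
    n_mother_father_pairs = 5, n_father_proband_pairs = 5,
    n_mother_proband_pairs = 4,
    n_batches = 2, n_low_spikes_per_batch = 5,
    ...
  )
}

# Every stochastic instrument term switched off: areas are exactly
# slope * conc * batch_effect + intercept (batch effects stay on unless
# overridden; per-batch calibration cancels them exactly).
noiseless_config <- function(seed = 7, panel = default_panel(6), ...) {
  small_config(
    seed = seed, panel = panel,
    response_cv = 0, noise_floor = 0, rt_jitter_sd = 0,
    qual_ratio_cv = 0, shape_cv = 0,
    ...
  )
}

# A bare peak/target pair for scalar detection-call tests.
reference_peak <- function(rt = 10, quant = 1000, qual = 500,
                           width = 0.05, asym = 1) {
  list(rt_min = rt, quant_area = quant, qual_area = qual,
       width_half_height = width, asymmetry = asym)
}

reference_target <- function(rt = 10, ratio = 0.5, qual = TRUE) {
  list(expected_rt = rt, reference_qual_ratio = ratio,
       qual_transition = if (qual) "256>150" else NA_character_)
}

ref_shape <- list(width = 0.05, asymmetry = 1)
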