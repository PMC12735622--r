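# Shared fixture builders: everything is generated in code, noiseless unless
# a noise model is passed explicitly.

noiseless_noise <- function() noise_model(background_rate = 0,
                                          shot_noise = FALSE,
                                          drift_amplitude = 0)

# Noiseless aligned-geometry scan (axis || B along lab Z), secular mode.
aligned_scan <- function(B_mag, shape = line_shape_params(),
                         sweep = sweep_config(), hyperfine = FALSE) {
  m <- ensemble_spectrum(c(0, 0, B_mag), single_ensemble(c(0, 0, 1)),
                         shape = shape, sweep = sweep,
                         mode = "secular", hyperfine = hyperfine)
  generate_scan(m, shape, noiseless_noise())
}

# Spectrum sampled from an explicit double-Lorentzian parameter set.
dlor_counts <- function(f, baseline, c1, c2, a1, a2, w1, w2) {
  baseline * (1 - a1 * lorentzian_dip(f, c1, w1)
                - a2 * lorentzian_dip(f, c2, w2))
}
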