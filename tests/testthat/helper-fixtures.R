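# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# small noise-free lookup table from the closed-form forward model,
# 8.5..10.5 1/cm in steps of 0.1 on the default time axis
small_diffusion_lut <- function() {
  if (is.null(fixture_env$lutd))
    fixture_env$lutd <- build_lut(8.5, 10.5, 0.1, slab_geometry(2),
                                  model = "diffusion")
  fixture_env$lutd
}

# standard study conditions: mu_sp = 9.5, mu_a = 0.08, 2-cm slab, n = 1.54
study_truth <- function() {
  phantom_truth(optical_properties(mu_a = 0.08, mu_sp = 9.5),
                geom = slab_geometry(2))
}

# triangular test pulse with a unique peak
triangle_dtof <- function(n = 101, peak_at = 51) {
  v <- pmax(0, 1 - abs(seq_len(n) - peak_at) / (peak_at - 1))
  dtof(seq(0, by = 10, length.out = n + 1), v, kind = "measured",
       meta = list(n_in = 1.54))
}
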