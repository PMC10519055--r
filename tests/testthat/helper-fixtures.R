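# Shared fixtures: a deterministic noise-free knee (exact textbook values)
# and small parameter helpers.

noise_free_params <- function(seed = 1L, ...) {
  generator_params(tttg_sd = 0, groove_tuberosity_dz_sd = 0,
                   hka_sd = 0, condyle_dz_jitter_sd = 0, seed = seed, ...)
}

noise_free_knee <- function() sample_knee(noise_free_params(), 1L)

# reference per-angle means the generator is calibrated against
REF_MEANS <- c(21.0, 19.2, 16.3, 15.2, 13.7, 11.5, 10.8)
REF_ANGLES <- seq(0, 12, by = 2)
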