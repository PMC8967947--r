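# Shared fixtures, built in code at test time.

# Small 8-target codebook on the 0.2 Hz flicker grid (adjacent targets,
# the hard case for unpadded spectra).
codebook8 <- function() {
  make_codebook("custom", f_min = 8, f_max = 9.4, step = 0.2,
                phase0 = 0, phase_step = 0.5 * pi, name = "beta8")
}

# Low-rate generator config used by classifier-level tests; keeps the
# time-domain variant's dense layer small.
cfg8 <- function(...) {
  args <- utils::modifyList(
    list(preset = "custom", fs = 64, n_channels = 3, noise_snr_db = -5,
         n_blocks = 8, seed = 1),
    list(...))
  do.call(sim_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Direct O(N^2) evaluation of the DFT sum, the oracle for the fast
# transform.
direct_dft <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(m)
    sum(x * exp(-2i * pi * (0:(n - 1)) * m / n)), complex(1))
}

# Tiny trainable model spec used where the full-width network is overkill.
tiny_model <- function(rows, cols, k, variant = "zpfd", seed = 1) {
  build_model(model_config(rows, cols, k, variant,
                           conv_channels = c(4L, 8L), fc_width = 32L),
              seed = seed)
}
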