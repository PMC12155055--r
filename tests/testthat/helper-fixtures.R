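# Small fixtures built in code.

# fast generator config: fewer samples and a coarser axis than the defaults
quick_cfg <- function(seed = 1, ...) {
  synthetic_config(n_samples = 40, step_nm = 5, seed = seed, ...)
}

# config with every nuisance switched off: clean bilinear mixing only
clean_cfg <- function(seed = 1, ...) {
  synthetic_config(noise_sd = 0, scatter_slope_sd = 0, scatter_offset_sd = 0,
                   baseline_drift_amplitude = 0, seed = seed, ...)
}

# tiny literal spectra matrix for operator unit tests
tiny_spectra <- function(rows, wl = seq_len(ncol(rows))) {
  spectra_matrix(rows, wl)
}

# closed-form moments of the truncated normal (independent oracle)
truncnorm_mean <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd; b <- (upper - mean) / sd
  Z <- pnorm(b) - pnorm(a)
  mean + sd * (dnorm(a) - dnorm(b)) / Z
}
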