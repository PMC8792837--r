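# Compact synthetic sessions for fast tests: fewer channels and
# repetitions than the default protocol, same signal structure.
small_config <- function(seed = 1, n_repetitions = 6, n_channels = 4,
                         separability = 1, sensor_noise_sd = 0.02) {
  session_config(n_channels = n_channels, n_repetitions = n_repetitions,
                 separability = separability,
                 sensor_noise_sd = sensor_noise_sd, seed = seed)
}

small_session <- function(...) simulate_session(small_config(...))

# The full pipeline run quietly (the 50 Hz notch at fs = 100 Hz sits at
# Nyquist and legitimately warns once per call).
quiet_evaluate <- function(...) suppressWarnings(evaluate_session(...))

random_window <- function(n) stats::rnorm(n, sd = stats::runif(1, 0.1, 5))
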