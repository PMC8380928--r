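# Small in-code fixtures shared across test files.

# single-channel recording wrapper around a numeric vector
toy_recording <- function(x, fs = 1000, channels = "Cz") {
  structure(list(data = matrix(x, length(channels), byrow = TRUE),
                 sample_rate = fs, channels = channels),
            class = "eeg_recording")
}

# bare ERP object on a 300-Hz -100..800 ms axis
toy_erp <- function(values_fn, channels = "Fz", fs = 300,
                    stimulus = "stim", role = "difference", n_trials = 10) {
  time <- seq(round(-0.1 * fs), round(0.8 * fs) - 1) / fs * 1000
  data <- t(vapply(seq_along(channels), function(i) values_fn(time),
                   numeric(length(time))))
  structure(list(data = data, time = time, channels = channels,
                 sample_rate = fs, n_trials = n_trials, stimulus = stimulus,
                 role = role, n_deviant_trials = n_trials,
                 n_standard_trials = n_trials),
            class = "erp")
}

# the zero-noise rectangular-MMN configuration used by the analytic
# end-to-end checks: filtering and smoothing off so the injected waveform
# reaches the integrator untouched
analytic_config <- function(channels = c("F3", "Fz", "Cz", "Pz"),
                            amplitude = -2, seed = 3) {
  amps <- expand.grid(domain = c("speech", "tone"),
                      dimension = c("spectral", "durational"),
                      deviant = c("prominent", "non-prominent"),
                      stringsAsFactors = FALSE)
  amps$amplitude_uv <- amplitude
  run_config(n_per_domain = 1, lead_in = 2, train_lengths = 4:5,
             reps_per_length = 1, sample_rate = 3000, target_rate = 300,
             channels = channels, mmn_amplitudes = amps, mmn_shape = "rect",
             noise = noise_spec(1, 0), filter = FALSE, smooth = FALSE,
             seed = seed)
}
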