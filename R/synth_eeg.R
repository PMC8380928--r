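#' Electrode montage with topography weights
#'
#' The 31-channel Ag/AgCl montage used throughout, with a scalar topography
#' weight per channel that scales every injected ERP/MMN component. The
#' default weights encode the frontally maximal distribution of the auditory
#' MMN: frontal sites 1.0, central 0.75, parietal/posterior 0.45. No forward
#' head model is used; scalar weights are all the downstream pipeline needs.
#'
#' @param channels character vector of channel labels (unique).
#' @param weights named numeric vector of topography weights; channels not
#'   named default to 1.
#' @return a \code{montage_spec}.
#' @export
montage_spec <- function(channels = default_channels(),
                         weights = default_topography(channels)) {
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  w <- rep(1, length(channels)); names(w) <- channels
  w[names(weights)[names(weights) %in% channels]] <-
    weights[names(weights) %in% channels]
  if (any(!is.finite(w))) stop("topography weights must be finite")
  structure(list(channels = channels, weights = w), class = "montage_spec")
}

#' @rdname montage_spec
#' @export
default_channels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "CP4", "C3", "Cz", "C4",
    "TP8", "FT7", "P3", "Pz", "P4", "FC3", "FC4", "FT8", "M1", "M2", "OPz",
    "AFz", "P7", "P8", "T7", "T8", "CPz", "FCz", "TP7", "CP3")
}

#' @rdname montage_spec
#' @export
default_topography <- function(channels = default_channels()) {
  frontal <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "AFz",
               "FC3", "FCz", "FC4", "FT7", "FT8")
  central <- c("C3", "Cz", "C4", "T7", "T8", "CP3", "CPz", "CP4",
               "TP7", "TP8")
  w <- rep(0.45, length(channels)); names(w) <- channels
  w[channels %in% frontal] <- 1
  w[channels %in% central] <- 0.75
  w
}

#' The 3 x 3 channel grid entering the statistical model
#' @return character vector F3/Fz/F4, C3/Cz/C4, P3/Pz/P4.
#' @export
analysis_grid <- function() c("F3", "Fz", "F4", "C3", "Cz", "C4",
                              "P3", "Pz", "P4")

#' Generic event-locked ERP component
#'
#' A Gaussian-shaped deflection added at every stimulus, described by its
#' peak latency relative to carrier onset, temporal width (Gaussian SD) and
#' signed amplitude; channel weights come from the montage topography.
#'
#' @param latency peak latency in ms post carrier onset.
#' @param width Gaussian SD in ms (> 0).
#' @param amplitude peak amplitude in microvolts (signed).
#' @return an \code{erp_component}.
#' @export
erp_component <- function(latency = 100, width = 30, amplitude = 4) {
  if (width <= 0) stop("width must be positive")
  structure(list(latency = latency, width = width, amplitude = amplitude),
            class = "erp_component")
}

#' Condition-specific MMN injection spec
#'
#' Describes the deviance response added on deviant trials only. The MMN
#' occupies a 100-ms window starting 150 ms after change onset; change onset
#' is 0 ms for a spectral deviant (the stimuli differ from their very onset)
#' and the short-stimulus duration for a durational deviant (the deviance is
#' only detectable once the short stimulus would have ended).
#'
#' @param amplitude MMN amplitude in microvolts (negative = mismatch
#'   negativity); interpreted as the rectangle height (\code{shape="rect"})
#'   or Gaussian peak (\code{shape="gaussian"}).
#' @param change_onset ms after carrier onset at which the deviance begins.
#' @param shape \code{"gaussian"} (SD \code{width}, centred mid-window) or
#'   \code{"rect"} (flat over the window, making the window AUC exactly
#'   \code{amplitude * 100} microvolt-ms at weight-1 channels).
#' @param width Gaussian SD in ms.
#' @return an \code{mmn_component}.
#' @export
mmn_component <- function(amplitude = -2, change_onset = 0,
                          shape = c("gaussian", "rect"), width = 25) {
  shape <- match.arg(shape)
  structure(list(amplitude = amplitude, change_onset = change_onset,
                 shape = shape, width = width,
                 window = change_onset + c(150, 250)),
            class = "mmn_component")
}

#' 1/f background noise specification
#' @param exponent spectral exponent a of the 1/f^a power spectrum
#'   (0 = white).
#' @param rms target per-channel RMS in microvolts.
#' @return a \code{noise_spec}.
#' @export
noise_spec <- function(exponent = 1, rms = 10) {
  if (rms < 0) stop("rms must be non-negative")
  structure(list(exponent = exponent, rms = rms), class = "noise_spec")
}

#' Generate multichannel 1/f noise
#'
#' Per-channel independent Gaussian noise spectrally shaped so that power
#' falls as \eqn{1/f^a}: white noise is transformed to the frequency domain,
#' amplitudes are scaled by \eqn{f^{-a/2}} (DC removed), and the result is
#' rescaled to the exact target RMS per channel.
#'
#' @param n_channels,n_samples output dimensions.
#' @param spec a [noise_spec()].
#' @param seed integer seed.
#' @return matrix (channels x samples) in microvolts.
#' @export
generate_noise <- function(n_channels, n_samples, spec = noise_spec(),
                           seed = 1L) {
  set.seed(seed)
  out <- matrix(0, n_channels, n_samples)
  if (spec$rms == 0) return(out)
  k <- seq_len(n_samples) - 1
  f <- pmin(k, n_samples - k)             # symmetric frequency index
  shape <- ifelse(f == 0, 0, f^(-spec$exponent / 2))
  for (ch in seq_len(n_channels)) {
    w <- stats::rnorm(n_samples)
    x <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / n_samples
    out[ch, ] <- x / sqrt(mean(x^2)) * spec$rms
  }
  out
}

gauss_bump <- function(t_ms, latency, width) exp(-0.5 * ((t_ms - latency) / width)^2)

mmn_waveform <- function(t_ms, mmn) {
  if (mmn$shape == "rect") {
    mmn$amplitude * as.numeric(t_ms >= mmn$window[1] & t_ms <= mmn$window[2])
  } else {
    mmn$amplitude * gauss_bump(t_ms, mean(mmn$window), mmn$width)
  }
}

#' Simulate a continuous EEG recording for one block
#'
#' Renders an event list into a 31-channel (or custom montage) continuous
#' recording in microvolts: every event adds the base ERP components
#' time-locked to its carrier onset; every deviant event additionally adds
#' the MMN component configured for its stimulus; 1/f noise is added on top,
#' independent of event roles. A single seed fans out to independent child
#' seeds for noise and artifacts so enabling one does not shift the other's
#' stream.
#'
#' @param events an \code{event_list} from [generate_sequence()].
#' @param carrier_onsets named numeric (ms), carrier onset per stimulus
#'   label (150 for CV-syllable fixtures, 0 for tones).
#' @param erp list of [erp_component()]s added on every event.
#' @param mmn named list of [mmn_component()]s keyed by stimulus label;
#'   applied when that stimulus is the deviant. NULL entries or missing
#'   labels inject nothing.
#' @param noise a [noise_spec()].
#' @param montage a [montage_spec()].
#' @param sample_rate recording sampling rate in Hz.
#' @param seed integer master seed.
#' @param tail_s seconds of recording kept after the last event onset.
#' @return an \code{eeg_recording}: list with \code{data} (channels x
#'   samples matrix, microvolts), \code{sample_rate}, \code{channels},
#'   \code{events} (with per-event \code{sample} and \code{carrier_sample}).
#' @export
simulate_recording <- function(events, carrier_onsets, erp = list(),
                               mmn = list(), noise = noise_spec(),
                               montage = montage_spec(), sample_rate = 3000,
                               seed = 1L, tail_s = 1.2) {
  stopifnot(inherits(montage, "montage_spec"))
  n_ch <- length(montage$channels)
  n_samples <- ceiling((max(events$onset) + tail_s) * sample_rate)
  ev <- events
  ev$sample <- round(ev$onset * sample_rate) + 1L
  co <- carrier_onsets[ev$stimulus]
  if (any(is.na(co))) stop("carrier_onsets missing for stimulus: ",
                           paste(unique(ev$stimulus[is.na(co)]), collapse = ", "))
  ev$carrier_sample <- ev$sample + round(co / 1000 * sample_rate)
  # one channel-agnostic source trace, then broadcast via topography weights
  source <- numeric(n_samples)
  t_rel <- seq(0, 800, by = 1000 / sample_rate)       # ms post carrier onset
  n_rel <- length(t_rel)
  base_wave <- numeric(n_rel)
  for (cmp in erp) base_wave <- base_wave +
      cmp$amplitude * gauss_bump(t_rel, cmp$latency, cmp$width)
  mmn_waves <- lapply(mmn, function(m) if (is.null(m)) NULL
                      else mmn_waveform(t_rel, m))
  for (i in seq_len(nrow(ev))) {
    idx <- ev$carrier_sample[i]:(ev$carrier_sample[i] + n_rel - 1)
    if (max(idx) > n_samples)
      stop("event ", ev$index[i], " extends past the end of the record")
    add <- base_wave
    if (ev$role[i] == "deviant" && !is.null(mmn_waves[[ev$stimulus[i]]]))
      add <- add + mmn_waves[[ev$stimulus[i]]]
    source[idx] <- source[idx] + add
  }
  data <- outer(unname(montage$weights), source)
  data <- data + generate_noise(n_ch, n_samples, noise,
                                seed = child_seed(seed, "noise"))
  structure(list(data = data, sample_rate = sample_rate,
                 channels = montage$channels, events = ev, seed = seed),
            class = "eeg_recording")
}

#' Derive an independent child seed from a master seed
#'
#' Deterministic per-purpose seeds so that toggling one stochastic feature
#' (noise, artifacts, jitter) does not shift another's random stream.
#'
#' @param seed master integer seed.
#' @param purpose short string naming the stream.
#' @return an integer seed in [0, 2^31).
#' @export
child_seed <- function(seed, purpose) {
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}

#' Inject supra-threshold artifacts into a recording
#'
#' Adds a large transient (half-sine, 50 ms) on all channels inside a
#' seeded random fraction of event epochs, emulating movement/electrode
#' artifacts that downstream amplitude-threshold rejection must catch.
#'
#' @param rec an \code{eeg_recording}.
#' @param rate per-event artifact probability in [0, 1].
#' @param magnitude transient peak in microvolts (>= the 50 uV rejection
#'   threshold to be useful).
#' @param seed integer seed.
#' @return list with \code{recording} (modified) and \code{log} (data frame
#'   of affected event indices and artifact peak samples).
#' @export
inject_artifacts <- function(rec, rate, magnitude = 120, seed = 1L) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  set.seed(child_seed(seed, "artifacts"))
  ev <- rec$events
  hit <- stats::runif(nrow(ev)) < rate
  log <- data.frame(event_index = integer(0), peak_sample = integer(0))
  if (any(hit)) {
    fs <- rec$sample_rate
    blip_n <- round(0.05 * fs)
    blip <- magnitude * sin(pi * seq(0, 1, length.out = blip_n))
    for (i in which(hit)) {
      at <- ev$carrier_sample[i] + round(stats::runif(1, 0.05, 0.5) * fs)
      idx <- at:(at + blip_n - 1)
      idx <- idx[idx <= ncol(rec$data)]
      rec$data[, idx] <- rec$data[, idx] +
        matrix(blip[seq_along(idx)], nrow(rec$data), length(idx), byrow = TRUE)
      log <- rbind(log, data.frame(event_index = ev$index[i], peak_sample = at))
    }
  }
  list(recording = rec, log = log)
}
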