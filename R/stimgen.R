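#' Inharmonic component series
#'
#' Geometric frequency series \code{base * ratio^(0:(n-1))}. With
#' \code{ratio = 1.15} the components are inharmonically spaced (no common
#' fundamental), which makes a tone complex non-confusable with speech while
#' keeping vowel-like spectral complexity.
#'
#' @param base first component frequency in Hz (> 0).
#' @param ratio multiplicative step between successive components.
#' @param n number of components (>= 1).
#' @return numeric vector of component frequencies in Hz.
#' @examples
#' inharmonic_series(500, 1.15, 15)
#' @export
inharmonic_series <- function(base, ratio, n) {
  if (!is.numeric(n) || n < 1) stop("n must be at least 1")
  if (base <= 0 || ratio <= 0) stop("base and ratio must be positive")
  base * ratio^(seq_len(n) - 1)
}

#' Formant weighting of a component series
#'
#' Per-component linear gains from a cascade of three analog two-pole
#' resonators centred at the formant frequencies. The resonator with centre
#' frequency F and bandwidth B has poles at \eqn{-\pi B \pm i 2\pi F}; the
#' gain at frequency f is the magnitude of its transfer function at
#' \eqn{s = i 2\pi f}, normalized to unity at DC per resonator, so gains are
#' strictly positive, peak near each formant, and tend to a flat response as
#' bandwidths grow.
#'
#' @param freqs component frequencies in Hz.
#' @param formants a [formant_set()].
#' @param bandwidths length-3 vector of formant bandwidths in Hz
#'   (conventional speech-synthesis defaults 80/120/160).
#' @return numeric vector of linear gains, same length as \code{freqs}.
#' @export
formant_weights <- function(freqs, formants, bandwidths = c(80, 120, 160)) {
  stopifnot(inherits(formants, "formant_set"), length(bandwidths) == 3)
  ff <- unlist(formants)
  gains <- rep(1, length(freqs))
  for (k in 1:3) {
    p <- complex(real = -pi * bandwidths[k], imaginary = 2 * pi * ff[k])
    s <- complex(imaginary = 2 * pi * freqs)
    # |p|^2 / |(s - p)(s - conj(p))| : unity at DC, resonant near ff[k]
    gains <- gains * Mod(p)^2 / (Mod(s - p) * Mod(s - Conj(p)))
  }
  gains
}

#' Tone-complex specification
#'
#' Parameters for one synthesized stimulus. In the default inharmonic mode
#' the source is the geometric series of [inharmonic_series()] (15
#' components from 500 Hz, each 1.15 times the previous); in harmonic mode
#' the source is a harmonic series on \code{f0}, used for vowel-like
#' fixtures.
#'
#' @param n_components number of source components.
#' @param base_freq first inharmonic component in Hz.
#' @param ratio inharmonic spacing ratio (> 1 in inharmonic mode).
#' @param formants a [formant_set()].
#' @param formant_bandwidths length-3 bandwidths in Hz.
#' @param duration stimulus duration in ms.
#' @param ramp linear onset/offset amplitude ramp in ms.
#' @param sample_rate output sampling rate in Hz.
#' @param peak peak-normalization target (max absolute amplitude).
#' @param harmonic_mode if TRUE, components are \code{f0 * 1:n_components}.
#' @param f0 fundamental in Hz (harmonic mode only).
#' @param label stimulus label carried into the waveform.
#' @return an object of class \code{tone_complex_spec}.
#' @export
tone_complex_spec <- function(n_components = 15, base_freq = 500, ratio = 1.15,
                              formants = stimulus_formants("e"),
                              formant_bandwidths = c(80, 120, 160),
                              duration = 220, ramp = 5, sample_rate = 44100,
                              peak = 0.9, harmonic_mode = FALSE, f0 = 220,
                              label = "stim") {
  if (n_components < 1) stop("n_components must be >= 1")
  if (!harmonic_mode && ratio <= 1) stop("ratio must exceed 1 in inharmonic mode")
  if (duration < 2 * ramp) stop("duration must be at least twice the ramp")
  spec <- list(n_components = n_components, base_freq = base_freq, ratio = ratio,
               formants = formants, formant_bandwidths = formant_bandwidths,
               duration = duration, ramp = ramp, sample_rate = sample_rate,
               peak = peak, harmonic_mode = harmonic_mode, f0 = f0, label = label)
  class(spec) <- "tone_complex_spec"
  fmax <- max(component_frequencies(spec))
  if (sample_rate < 4 * fmax)
    stop("sample_rate must be at least 4x the highest component frequency (",
         round(fmax, 1), " Hz)")
  spec
}

component_frequencies <- function(spec) {
  if (spec$harmonic_mode) spec$f0 * seq_len(spec$n_components)
  else inharmonic_series(spec$base_freq, spec$ratio, spec$n_components)
}

linear_ramp_envelope <- function(n, ramp_samples) {
  env <- rep(1, n)
  if (ramp_samples > 0) {
    up <- seq(0, 1, length.out = ramp_samples + 1)[-(ramp_samples + 1)]
    env[seq_len(ramp_samples)] <- up
    env[n + 1 - seq_len(ramp_samples)] <- up
  }
  env
}

#' Synthesize a formant-weighted tone complex
#'
#' Sums sinusoids at the spec's component frequencies with
#' [formant_weights()] gains, applies a linear amplitude ramp over the first
#' and last \code{ramp} ms, and peak-normalizes the final waveform to
#' \code{spec$peak}. With all-zero initial phases (the default,
#' \code{random_phases = FALSE}) the output is fully deterministic; seeded
#' random phases are available for robustness checks.
#'
#' @param spec a [tone_complex_spec()].
#' @param seed integer seed used only when \code{random_phases} is TRUE.
#' @param random_phases draw initial phases uniformly on \eqn{[0, 2\pi)}.
#' @return a \code{stimulus_waveform}: list with \code{samples},
#'   \code{sample_rate}, \code{label}, \code{carrier_onset} (ms).
#' @export
synthesize_complex <- function(spec, seed = 1L, random_phases = FALSE) {
  stopifnot(inherits(spec, "tone_complex_spec"))
  freqs <- component_frequencies(spec)
  if (any(freqs >= spec$sample_rate / 2))
    stop("component frequency at or above Nyquist")
  n <- round(spec$duration / 1000 * spec$sample_rate)
  t <- (seq_len(n) - 1) / spec$sample_rate
  gains <- formant_weights(freqs, spec$formants, spec$formant_bandwidths)
  phases <- if (random_phases) {
    set.seed(seed)
    stats::runif(length(freqs), 0, 2 * pi)
  } else rep(0, length(freqs))
  x <- drop(sin(outer(t, 2 * pi * freqs) +
                matrix(phases, n, length(freqs), byrow = TRUE)) %*% gains)
  x <- x * linear_ramp_envelope(n, round(spec$ramp / 1000 * spec$sample_rate))
  x <- x / max(abs(x)) * spec$peak
  structure(list(samples = x, sample_rate = spec$sample_rate,
                 label = spec$label, carrier_onset = 0),
            class = "stimulus_waveform")
}

#' Synthesize a vowel-like fixture
#'
#' Stand-in for a natural consonant-vowel syllable: a harmonic source on
#' \code{f0} with the same formant weighting, ramp and peak normalization as
#' [synthesize_complex()], optionally preceded by a 150-ms noise burst
#' emulating the fricative [f]. With the prefix enabled the
#' \code{carrier_onset} field is set to the prefix duration so downstream
#' epoching locks to vowel onset, not file onset.
#'
#' @param spec a [tone_complex_spec()] with \code{harmonic_mode = TRUE}
#'   (a non-harmonic spec without prefix degenerates to
#'   [synthesize_complex()]).
#' @param fricative_prefix prepend the noise burst.
#' @param prefix_duration prefix duration in ms.
#' @param prefix_level noise burst amplitude relative to \code{spec$peak}.
#' @param seed seed for the noise burst (and phases if requested).
#' @inheritParams synthesize_complex
#' @return a \code{stimulus_waveform}.
#' @export
synthesize_vowel_fixture <- function(spec, fricative_prefix = TRUE,
                                     prefix_duration = 150, prefix_level = 0.25,
                                     seed = 1L, random_phases = FALSE) {
  vowel <- synthesize_complex(spec, seed = seed, random_phases = random_phases)
  if (!fricative_prefix) return(vowel)
  np <- round(prefix_duration / 1000 * spec$sample_rate)
  set.seed(seed + 1L)
  burst <- stats::rnorm(np)
  burst <- burst / max(abs(burst)) * prefix_level * spec$peak
  burst <- burst * linear_ramp_envelope(np, round(spec$ramp / 1000 * spec$sample_rate))
  structure(list(samples = c(burst, vowel$samples),
                 sample_rate = spec$sample_rate, label = spec$label,
                 carrier_onset = prefix_duration),
            class = "stimulus_waveform")
}

#' The four stimuli of one experimental domain
#'
#' Builds the stimulus set used by one participant group from a single
#' configuration: a spectral pair (220 ms, [a]-like focal vs [e]-like
#' non-focal spectrum) and a durational pair (180 vs 360 ms, both [e]-like).
#' In the \code{"tone"} domain these are inharmonic complexes; in the
#' \code{"speech"} domain they are harmonic vowel fixtures with a 150-ms
#' fricative-like prefix. Prominence follows focalization (spectral: the
#' [a]-like stimulus is prominent) and total energy (durational: the long
#' stimulus is prominent).
#'
#' @param domain \code{"tone"} or \code{"speech"}.
#' @param sample_rate sampling rate in Hz.
#' @param seed seed for the speech-fixture noise bursts.
#' @return named list of four \code{stimulus_waveform}s with a
#'   \code{"meta"} attribute data frame (label, dimension, prominence,
#'   duration_ms).
#' @export
make_stimulus_set <- function(domain = c("tone", "speech"), sample_rate = 44100,
                              seed = 1L) {
  domain <- match.arg(domain)
  harmonic <- domain == "speech"
  mk <- function(formants, duration, label) {
    spec <- tone_complex_spec(formants = formants, duration = duration,
                              sample_rate = sample_rate,
                              harmonic_mode = harmonic, label = label)
    if (harmonic) synthesize_vowel_fixture(spec, seed = seed)
    else synthesize_complex(spec, seed = seed)
  }
  pre <- if (harmonic) "f" else "t"
  out <- list(
    mk(stimulus_formants("e"), 220, paste0(pre, "e220")),
    mk(stimulus_formants("a"), 220, paste0(pre, "a220")),
    mk(stimulus_formants("e"), 180, paste0(pre, "e180")),
    mk(stimulus_formants("e"), 360, paste0(pre, "e360"))
  )
  names(out) <- vapply(out, `[[`, character(1), "label")
  attr(out, "meta") <- data.frame(
    label = names(out),
    dimension = c("spectral", "spectral", "durational", "durational"),
    prominence = c("non-prominent", "prominent", "non-prominent", "prominent"),
    duration_ms = c(220, 220, 180, 360),
    stringsAsFactors = FALSE
  )
  out
}
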