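#' Convert frequency in Hz to the Bark scale
#'
#' The Bark scale approximates the critical bands of human hearing; formant
#' distances expressed in Bark are the standard currency of psychoacoustic
#' vowel-space metrics. Three classical conversion formulas are provided:
#' Traunmuller (default), Zwicker, and Schroeder.
#'
#' @param f numeric vector of frequencies in Hz; must be non-negative.
#' @param formula one of \code{"traunmuller"}, \code{"zwicker"},
#'   \code{"schroeder"}.
#' @return numeric vector of critical-band rates in Bark.
#' @examples
#' hz_to_bark(1000)                      # 8.527
#' hz_to_bark(c(500, 1000, 2000), formula = "schroeder")
#' @export
hz_to_bark <- function(f, formula = c("traunmuller", "zwicker", "schroeder")) {
  formula <- match.arg(formula)
  if (!is.numeric(f)) stop("frequency must be numeric")
  if (any(f < 0)) stop("frequency must be non-negative (got a negative value)")
  switch(formula,
    traunmuller = 26.81 * f / (1960 + f) - 0.53,
    zwicker     = 13 * atan(0.00076 * f) + 3.5 * atan((f / 7500)^2),
    schroeder   = 7 * asinh(f / 650)
  )
}

#' Convert Bark back to Hz
#'
#' Inverts [hz_to_bark()]. Traunmuller and Schroeder have closed-form
#' inverses; Zwicker is inverted numerically by root finding.
#'
#' @param z numeric vector in Bark.
#' @inheritParams hz_to_bark
#' @return numeric vector of frequencies in Hz.
#' @export
bark_to_hz <- function(z, formula = c("traunmuller", "zwicker", "schroeder")) {
  formula <- match.arg(formula)
  switch(formula,
    traunmuller = 1960 * (z + 0.53) / (26.28 - z),
    schroeder   = 650 * sinh(z / 7),
    zwicker     = vapply(z, function(zi) {
      stats::uniroot(function(f) hz_to_bark(f, "zwicker") - zi,
                     interval = c(0, 5e5), tol = 1e-9)$root
    }, numeric(1))
  )
}

#' Formant sets and JND parameters
#'
#' A `formant_set` carries the first three formant frequencies of a vowel or
#' vowel-like stimulus; `jnd_params` carries the discrimination thresholds
#' used to express acoustic distances in just-noticeable-difference (JND)
#' units: 0.3 Bark for formants, and a 5-ms Weber threshold at a 90-ms
#' reference for duration.
#'
#' @param f1,f2,f3 formant frequencies in Hz, with \code{0 < f1 < f2 < f3}.
#' @return an object of class \code{formant_set}.
#' @examples
#' formant_set(864, 1287, 2831)  # Czech [a]
#' @export
formant_set <- function(f1, f2, f3) {
  fs <- c(f1 = f1, f2 = f2, f3 = f3)
  if (any(!is.finite(fs)) || any(fs <= 0))
    stop("formant frequencies must be finite and strictly positive")
  if (!(f1 < f2 && f2 < f3))
    stop("formants must be strictly increasing: f1 < f2 < f3")
  structure(as.list(fs), class = "formant_set")
}

#' @rdname formant_set
#' @param formant_threshold formant discrimination threshold in Bark.
#' @param duration_threshold duration discrimination threshold in ms.
#' @param duration_reference reference duration in ms at which the duration
#'   threshold is stated.
#' @export
jnd_params <- function(formant_threshold = 0.3, duration_threshold = 5,
                       duration_reference = 90) {
  p <- list(formant_threshold = formant_threshold,
            duration_threshold = duration_threshold,
            duration_reference = duration_reference)
  if (any(vapply(p, function(x) !is.numeric(x) || x <= 0, logical(1))))
    stop("all JND parameters must be strictly positive numbers")
  structure(p, class = "jnd_params")
}

#' Formant focalization distance
#'
#' Distance between the first and second formant on the Bark scale. Small
#' values mean F1 and F2 merge into one prominent energy band, making the
#' vowel "focal" (perceptually prominent), as for a low [a]; large values
#' mean a diffuse, non-focal spectrum, as for [e]-like vowels.
#'
#' @param fs a [formant_set()].
#' @inheritParams hz_to_bark
#' @return distance \code{bark(f2) - bark(f1)} in Bark (non-negative).
#' @export
focalization_distance <- function(fs, formula = "traunmuller") {
  stopifnot(inherits(fs, "formant_set"))
  hz_to_bark(fs$f2, formula) - hz_to_bark(fs$f1, formula)
}

#' Spectral distance between two stimuli in JND units
#'
#' Euclidean distance between the first three formants of two stimuli on the
#' Bark scale, divided by the formant discrimination threshold, giving a
#' count of just-noticeable differences.
#'
#' @param a,b [formant_set()] objects.
#' @param params a [jnd_params()] object.
#' @inheritParams hz_to_bark
#' @return non-negative JND count; zero iff \code{a} equals \code{b}.
#' @export
spectral_jnd_distance <- function(a, b, params = jnd_params(),
                                  formula = "traunmuller") {
  stopifnot(inherits(a, "formant_set"), inherits(b, "formant_set"),
            inherits(params, "jnd_params"))
  da <- hz_to_bark(unlist(a), formula) - hz_to_bark(unlist(b), formula)
  sqrt(sum(da^2)) / params$formant_threshold
}

#' Durational distance between two stimuli in JND units
#'
#' Counts cumulative Weber steps between two durations: starting from the
#' shorter duration, each step multiplies the current duration by
#' \code{1 + duration_threshold / duration_reference}. The number of steps
#' needed to reach the longer duration is
#' \deqn{\log(d_{max}/d_{min}) / \log(1 + \theta / d_{ref})}
#' which is symmetric in its arguments and depends on the durations only
#' through their ratio.
#'
#' @param d1,d2 durations in ms, strictly positive.
#' @param params a [jnd_params()] object.
#' @return non-negative JND count; zero iff \code{d1 == d2}.
#' @examples
#' duration_jnd_distance(180, 360)  # 12.82...; one decimal: 12.8
#' @export
duration_jnd_distance <- function(d1, d2, params = jnd_params()) {
  stopifnot(inherits(params, "jnd_params"))
  if (!is.numeric(d1) || !is.numeric(d2) || d1 <= 0 || d2 <= 0)
    stop("durations must be strictly positive")
  log(max(d1, d2) / min(d1, d2)) /
    log(1 + params$duration_threshold / params$duration_reference)
}

#' Round half away from zero
#'
#' Reporting convention for distance values: one decimal place by default,
#' with exact halves rounded away from zero (unlike base R's banker's
#' rounding).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Reference stimulus formants
#'
#' Formant sets of the two vowel qualities used throughout: the non-focal
#' front [e]-quality (755/1646/2710 Hz) and the focal low [a]-quality
#' (864/1287/2831 Hz), typical female Czech values.
#'
#' @param vowel \code{"e"} or \code{"a"}.
#' @return a [formant_set()].
#' @export
stimulus_formants <- function(vowel = c("e", "a")) {
  vowel <- match.arg(vowel)
  if (vowel == "e") formant_set(755, 1646, 2710) else formant_set(864, 1287, 2831)
}
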