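#' Identity-matched difference wave
#'
#' Deviant-minus-standard difference computed between ERPs of physically
#' identical stimuli (e.g., the [fa]-deviant ERP minus the [fa]-standard
#' ERP). Subtracting across different stimuli would confound the deviance
#' response with acoustic differences, so mismatched stimulus labels are
#' rejected.
#'
#' @param deviant_erp,standard_erp \code{erp} objects sharing the stimulus
#'   label, time axis and channels.
#' @return an \code{erp} holding the pointwise difference.
#' @export
difference_wave <- function(deviant_erp, standard_erp) {
  if (!identical(deviant_erp$stimulus, standard_erp$stimulus))
    stop("identity matching violated: deviant is '", deviant_erp$stimulus,
         "' but standard is '", standard_erp$stimulus, "'")
  if (!isTRUE(all.equal(deviant_erp$time, standard_erp$time)) ||
      !identical(deviant_erp$channels, standard_erp$channels))
    stop("deviant and standard ERPs must share time axis and channels")
  out <- deviant_erp
  out$data <- deviant_erp$data - standard_erp$data
  out$role <- "difference"
  out$n_trials <- min(deviant_erp$n_trials, standard_erp$n_trials)
  out$n_deviant_trials <- deviant_erp$n_trials
  out$n_standard_trials <- standard_erp$n_trials
  out
}

#' Analysis window for a deviance dimension
#'
#' The MMN is quantified in a 100-ms window starting 150 ms after change
#' onset. For a spectral deviant the change is present from carrier onset
#' (window 150-250 ms); for a durational deviant the change becomes
#' detectable only at the short-stimulus duration (180 ms for the standard
#' stimuli, giving 330-430 ms).
#'
#' @param dimension \code{"spectral"} or \code{"durational"}.
#' @param change_onset ms after carrier onset at which the deviance begins
#'   (ignored for spectral, where it is 0).
#' @return an \code{mmn_window}: numeric c(start, end) in ms.
#' @export
window_for <- function(dimension = c("spectral", "durational"),
                       change_onset = 180) {
  dimension <- match.arg(dimension)
  onset <- if (dimension == "spectral") 0 else change_onset
  structure(onset + c(150, 250), class = "mmn_window")
}

#' Signed area under the curve in a latency window
#'
#' Trapezoidal integral of one channel of a (difference) wave over the
#' analysis window, in microvolt-milliseconds. Window endpoints are snapped
#' to the nearest time-axis sample; the integral is signed, so a mismatch
#' negativity yields a negative area.
#'
#' @param wave an \code{erp}.
#' @param window an [window_for()] window (or numeric c(start, end) ms).
#' @param channel channel label.
#' @return signed area in microvolt-ms.
#' @export
auc <- function(wave, window, channel) {
  if (window[1] < min(wave$time) || window[2] > max(wave$time))
    stop("analysis window [", window[1], ", ", window[2],
         "] ms lies outside the epoch time axis")
  ch <- match(channel, wave$channels)
  if (is.na(ch)) stop("unknown channel: ", channel)
  i1 <- which.min(abs(wave$time - window[1]))
  i2 <- which.min(abs(wave$time - window[2]))
  pracma::trapz(wave$time[i1:i2], wave$data[ch, i1:i2])
}

#' Assemble the per-channel MMN table
#'
#' One row per participant x domain x dimension x deviant x channel with the
#' windowed AUC of the identity-matched difference wave -- the response
#' variable of the statistical model.
#'
#' @param erps named list of averaged ERPs from [average_epochs()]
#'   (names \code{"<stimulus>.<role>"}) for one participant and block.
#' @param participant participant identifier.
#' @param domain \code{"speech"} or \code{"tone"}.
#' @param dimension \code{"spectral"} or \code{"durational"}.
#' @param stim_meta data frame with \code{label} and \code{prominence}
#'   columns (as attached to [make_stimulus_set()] output).
#' @param channels channel labels to measure (default [analysis_grid()]).
#' @param window analysis window (default from [window_for()]).
#' @param smooth apply [savgol_smooth()] to the difference waves first.
#' @return data frame (class \code{mmn_table}) with columns participant,
#'   domain, dimension, deviant, channel, auc_uv_ms, n_dev, n_std.
#' @export
build_mmn_table <- function(erps, participant, domain, dimension, stim_meta,
                            channels = analysis_grid(),
                            window = window_for(dimension), smooth = TRUE) {
  stims <- unique(sub("\\.(deviant|standard)$", "", names(erps)))
  missing_cells <- character(0)
  rows <- list()
  for (s in stims) {
    dev_key <- paste0(s, ".deviant"); std_key <- paste0(s, ".standard")
    if (!dev_key %in% names(erps)) missing_cells <- c(missing_cells, dev_key)
    if (!std_key %in% names(erps)) missing_cells <- c(missing_cells, std_key)
    if (!all(c(dev_key, std_key) %in% names(erps))) next
    dw <- difference_wave(erps[[dev_key]], erps[[std_key]])
    if (smooth) dw <- savgol_smooth(dw)
    prom <- stim_meta$prominence[match(s, stim_meta$label)]
    if (is.na(prom)) stop("stimulus ", s, " not found in stim_meta")
    for (ch in channels) {
      rows[[length(rows) + 1]] <- data.frame(
        participant = participant, domain = domain, dimension = dimension,
        deviant = prom, stimulus = s, channel = ch,
        auc_uv_ms = auc(dw, window, ch),
        n_dev = dw$n_deviant_trials, n_std = dw$n_standard_trials,
        stringsAsFactors = FALSE)
    }
  }
  if (length(missing_cells))
    stop("missing ERP cells: ", paste(missing_cells, collapse = ", "))
  out <- do.call(rbind, rows)
  class(out) <- c("mmn_table", "data.frame")
  out
}
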