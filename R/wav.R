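#' Write a stimulus waveform to a WAV file
#'
#' Writes a mono RIFF/WAVE file, IEEE float32 by default (lossless for the
#' normalized stimuli apart from double-to-float truncation) or 16-bit PCM.
#' Stimulus metadata that WAV cannot carry (label, carrier onset) goes to a
#' JSON sidecar at \code{paste0(path, ".json")}.
#'
#' @param wave a \code{stimulus_waveform}.
#' @param path output file path.
#' @param format \code{"float32"} or \code{"pcm16"}.
#' @return \code{path}, invisibly.
#' @export
write_wav <- function(wave, path, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  x <- wave$samples
  fs <- as.integer(wave$sample_rate)
  bits <- if (format == "float32") 32L else 16L
  block <- bits %/% 8L
  data_bytes <- length(x) * block
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(if (format == "float32") 3L else 1L, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * block, con, size = 4, endian = "little")      # byte rate
  writeBin(block, con, size = 2, endian = "little")           # block align
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (format == "float32") {
    writeBin(x, con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(round(pmax(pmin(x, 1), -1) * 32767)), con,
             size = 2, endian = "little")
  }
  jsonlite::write_json(list(label = wave$label,
                            carrier_onset = wave$carrier_onset,
                            sample_rate = wave$sample_rate),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a WAV file written by [write_wav()]
#'
#' Parses mono RIFF/WAVE in float32 or 16-bit PCM and restores label and
#' carrier onset from the JSON sidecar when present.
#'
#' @param path WAV file path.
#' @return a \code{stimulus_waveform}.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  fmt <- NULL; samples <- NULL; fs <- NULL; audio_format <- NULL; bits <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      audio_format <- readBin(con, integer(), size = 2, endian = "little")
      n_ch <- readBin(con, integer(), size = 2, endian = "little")
      if (n_ch != 1) stop("only mono WAV is supported")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (size > 16) readBin(con, raw(), n = size - 16)
    } else if (id == "data") {
      if (is.null(audio_format)) stop("malformed WAV: data before fmt chunk")
      if (audio_format == 3 && bits == 32) {
        samples <- readBin(con, numeric(), n = size %/% 4, size = 4,
                           endian = "little")
      } else if (audio_format == 1 && bits == 16) {
        samples <- readBin(con, integer(), n = size %/% 2, size = 2,
                           endian = "little") / 32767
      } else stop("unsupported WAV encoding (format ", audio_format,
                  ", ", bits, " bits)")
    } else {
      readBin(con, raw(), n = size)
    }
    if (!is.null(samples) && !is.null(fs)) break
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  label <- basename(path); onset <- 0
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    label <- meta$label
    onset <- meta$carrier_onset
  }
  structure(list(samples = samples, sample_rate = fs, label = label,
                 carrier_onset = onset),
            class = "stimulus_waveform")
}
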