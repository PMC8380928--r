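pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: ", x)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "fg", width = 1)
  if (nchar(s) > width) s <- substr(formatC(x, format = "g", digits = width - 3), 1, width)
  pad_field(s, width)
}

#' Write an EEG recording to EDF+
#'
#' Serializes an \code{eeg_recording} to the 16-bit European Data Format
#' with an EDF+ annotations signal carrying the event markers (onset,
#' stimulus, role, train id, position, carrier onset). Data records are one
#' second long; the signal is zero-padded to a whole number of records and
#' the true sample count is stored in the recording-identification header
#' field so [read_edf()] restores the exact length. Amplitudes are quantized
#' to the configured physical range (error at most range/2^15).
#'
#' @param rec an \code{eeg_recording}.
#' @param path output file path.
#' @param phys_range symmetric physical range in microvolts (+/-).
#' @return \code{path}, invisibly.
#' @export
write_edf <- function(rec, path, phys_range = 1000) {
  if (max(abs(rec$data)) > phys_range)
    stop("recording exceeds the physical range +/-", phys_range,
         " uV; increase phys_range")
  fs <- rec$sample_rate
  n_ch <- nrow(rec$data)
  n_true <- ncol(rec$data)
  n_rec <- ceiling(n_true / fs)
  ann_spr <- 128L                      # 256 bytes of annotation per record
  n_sig <- n_ch + 1L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad_field("0", 8), pad_field("X X X X", 80),
    pad_field(paste0("Startdate X X X X nsamples=", n_true), 80),
    pad_field("01.01.01", 8), pad_field("00.00.00", 8),
    pad_field((n_sig + 1) * 256, 8), pad_field("EDF+C", 44),
    pad_field(n_rec, 8), pad_field(1, 8), pad_field(n_sig, 4)
  ), con, eos = NULL)
  lab <- c(rec$channels, "EDF Annotations")
  fld <- function(vals, w) writeChar(paste(vapply(vals, pad_field, "", width = w),
                                           collapse = ""), con, eos = NULL)
  fld(lab, 16)
  fld(rep("", n_sig), 80)                                    # transducer
  fld(c(rep("uV", n_ch), ""), 8)                             # physical dim
  fld(c(rep(edf_num(-phys_range, 8), n_ch), edf_num(-1, 8)), 8)
  fld(c(rep(edf_num(phys_range, 8), n_ch), edf_num(1, 8)), 8)
  fld(rep("-32767", n_sig), 8)   # symmetric digital range matches the encoder
  fld(rep("32767", n_sig), 8)
  fld(rep("", n_sig), 80)                                    # prefiltering
  fld(c(rep(fs, n_ch), ann_spr), 8)
  fld(rep("", n_sig), 32)
  scale <- 32767 / phys_range
  ev <- rec$events
  ev_rec <- floor((ev$sample - 1) / fs)                      # record index, 0-based
  for (r in seq_len(n_rec) - 1L) {
    idx <- (r * fs + 1):min((r + 1) * fs, n_true)
    block <- matrix(0L, fs, n_ch)
    block[seq_along(idx), ] <- round(t(rec$data[, idx, drop = FALSE]) * scale)
    writeBin(as.integer(block), con, size = 2, endian = "little")
    tal <- sprintf("+%d\x14\x14", r)
    for (i in which(ev_rec == r)) {
      onset <- (ev$sample[i] - 1) / fs
      txt <- sprintf("stim=%s;role=%s;train=%d;pos=%d;carrier=%d",
                     ev$stimulus[i], ev$role[i], ev$train_id[i],
                     ev$position_in_train[i],
                     ev$carrier_sample[i] - ev$sample[i])
      tal <- paste0(tal, sprintf("+%.7g\x14%s\x14", onset, txt))
    }
    raw_tal <- c(charToRaw(tal), as.raw(0))
    if (length(raw_tal) > 2 * ann_spr)
      stop("annotation record overflow in record ", r)
    ann <- raw(2 * ann_spr)
    ann[seq_along(raw_tal)] <- raw_tal
    writeBin(ann, con)
  }
  invisible(path)
}

#' Read an EDF+ file written by [write_edf()]
#'
#' Restores channel labels, sampling rate, physically scaled amplitudes,
#' true record length, and the event table from the annotations signal.
#'
#' @param path EDF file path.
#' @return an \code{eeg_recording}.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  if (substr(hdr, 1, 1) != "0") stop("malformed EDF header in ", path)
  rec_id <- substr(hdr, 89, 168)
  n_rec <- as.integer(substr(hdr, 237, 244))
  rec_dur <- as.numeric(substr(hdr, 245, 252))
  n_sig <- as.integer(substr(hdr, 253, 256))
  sig_hdr <- readChar(con, n_sig * 256, useBytes = TRUE)
  fields <- function(off, w) vapply(seq_len(n_sig) - 1, function(s)
    trimws(substr(sig_hdr, off + s * w + 1, off + (s + 1) * w)), "")
  labels <- fields(0, 16)
  pmin_ <- as.numeric(fields(n_sig * (16 + 80 + 8), 8))
  pmax_ <- as.numeric(fields(n_sig * (16 + 80 + 8 + 8), 8))
  dmin_ <- as.numeric(fields(n_sig * (16 + 80 + 8 + 8 + 8), 8))
  dmax_ <- as.numeric(fields(n_sig * (16 + 80 + 8 + 8 + 8 + 8), 8))
  spr <- as.integer(fields(n_sig * (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80), 8))
  is_ann <- labels == "EDF Annotations"
  ch <- which(!is_ann)
  fs <- spr[ch[1]] / rec_dur
  n_true <- as.integer(sub(".*nsamples=([0-9]+).*", "\\1", rec_id))
  if (is.na(n_true)) n_true <- n_rec * spr[ch[1]]
  data <- matrix(0, length(ch), n_rec * spr[ch[1]])
  ann_text <- character(0)
  for (r in seq_len(n_rec) - 1L) {
    for (s in seq_len(n_sig)) {
      if (is_ann[s]) {
        bytes <- readBin(con, raw(), n = 2 * spr[s])
        ann_text <- c(ann_text, rawToChar(bytes[bytes != as.raw(0)]))
      } else {
        vals <- readBin(con, integer(), n = spr[s], size = 2,
                        endian = "little")
        j <- match(s, ch)
        sc <- (pmax_[s] - pmin_[s]) / (dmax_[s] - dmin_[s])
        data[j, (r * spr[s] + 1):((r + 1) * spr[s])] <-
          (vals - dmin_[s]) * sc + pmin_[s]
      }
    }
  }
  data <- data[, seq_len(n_true), drop = FALSE]
  events <- parse_edf_annotations(paste(ann_text, collapse = ""), fs)
  structure(list(data = data, sample_rate = fs, channels = labels[ch],
                 events = events),
            class = "eeg_recording")
}

parse_edf_annotations <- function(txt, fs) {
  tals <- strsplit(txt, "\x14\\+", fixed = FALSE)[[1]]
  rows <- list()
  for (tal in tals) {
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    if (length(parts) < 2 || !nzchar(parts[2])) next
    onset <- as.numeric(sub("^\\+", "", parts[1]))
    kv <- strsplit(strsplit(parts[2], ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    val <- vapply(kv, `[`, "", 2); names(val) <- vapply(kv, `[`, "", 1)
    rows[[length(rows) + 1]] <- data.frame(
      onset = onset, sample = round(onset * fs) + 1L,
      stimulus = val[["stim"]], role = val[["role"]],
      train_id = as.integer(val[["train"]]),
      position_in_train = as.integer(val[["pos"]]),
      carrier_sample = round(onset * fs) + 1L + as.integer(val[["carrier"]]),
      stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, rows)
  if (is.null(ev)) return(NULL)
  ev <- ev[order(ev$onset), , drop = FALSE]
  ev$index <- seq_len(nrow(ev))
  rownames(ev) <- NULL
  ev
}
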