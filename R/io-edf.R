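# Minimal European Data Format (EDF) support: the plain continuous-recording
# subset (one data record per second, 16-bit integers, linear scaling from
# per-channel physical min/max). Enough for interchange of the simulated
# recordings with standard EEG tooling.

pad <- function(x, n) {
  x <- substr(as.character(x), 1, n)
  formatC(x, width = n, flag = "-")
}

#' Write a recording as an EDF file
#'
#' Writes the plain EDF subset: ASCII header, one 1-second data record per
#' block of `sfreq` samples, each channel stored as little-endian 16-bit
#' integers linearly scaled between the channel's physical minimum and
#' maximum. The sampling rate must be a whole number; a final partial second
#' is padded by repeating the last sample.
#'
#' @param recording an [eeg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  if (abs(recording$sfreq - round(recording$sfreq)) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  sf <- as.integer(round(recording$sfreq))
  x <- recording$data
  C <- nrow(x)
  n_rec <- as.integer(ceiling(ncol(x) / sf))
  if (ncol(x) < n_rec * sf)
    x <- cbind(x, matrix(x[, ncol(x)], C, n_rec * sf - ncol(x)))
  pmin_ <- apply(x, 1, min)
  pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767
  header_bytes <- 256L + 256L * C
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, n) writeChar(paste0(pad(x, n), collapse = ""), con,
                                 eos = NULL)
  wr("0", 8)
  wr(recording$subject_id, 80)
  wr("microstatr synthetic", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(header_bytes, 8)
  wr("", 44)
  wr(n_rec, 8)
  wr("1", 8)                 # record duration, seconds
  wr(C, 4)
  for (lab in recording$channel_labels) wr(lab, 16)
  for (i in seq_len(C)) wr("", 80)            # transducer
  for (i in seq_len(C)) wr("uV", 8)
  for (i in seq_len(C)) wr(sprintf("%.8g", pmin_[i]), 8)
  for (i in seq_len(C)) wr(sprintf("%.8g", pmax_[i]), 8)
  for (i in seq_len(C)) wr(dmin, 8)
  for (i in seq_len(C)) wr(dmax, 8)
  for (i in seq_len(C)) wr("", 80)            # prefilter
  for (i in seq_len(C)) wr(sf, 8)
  for (i in seq_len(C)) wr("", 32)
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * sf + 1):(r * sf)
    for (ch in seq_len(C)) {
      d <- round((x[ch, cols] - pmin_[ch]) / scale[ch]) + dmin
      writeBin(as.integer(pmin(pmax(d, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()] (plain EDF subset)
#'
#' @param path EDF file path.
#' @return An [eeg_recording()]; group metadata is not stored in EDF and
#'   comes back as `NA`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8)                       # version
  subject <- rd(80)
  rd(80); rd(8); rd(8)
  rd(8)                       # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  C <- as.integer(rd(4))
  labs <- vapply(seq_len(C), function(i) rd(16), character(1))
  for (i in seq_len(C)) rd(80)
  for (i in seq_len(C)) rd(8)
  pmin_ <- vapply(seq_len(C), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(C), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(C), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(C), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(C)) rd(80)
  spr <- vapply(seq_len(C), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(C)) rd(32)
  if (length(unique(spr)) != 1)
    stop("mixed per-channel sampling rates are not supported")
  sf <- spr[1] / rec_dur
  x <- matrix(0, C, n_rec * spr[1])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (ch in seq_len(C)) {
      d <- readBin(con, "integer", n = spr[1], size = 2, endian = "little")
      x[ch, cols] <- (d - dmin[ch]) * scale[ch] + pmin_[ch]
    }
  }
  eeg_recording(x, sf, channel_labels = labs, subject_id = subject)
}
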