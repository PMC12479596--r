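#' Band-pass and notch filtering
#'
#' Applies a second-order Butterworth band-pass (default 1-40 Hz) and a notch
#' (default 50 Hz, quality factor 30) to every channel. Both filters are
#' applied forward-backward (zero phase), preserving microstate timing.
#'
#' @param recording an [eeg_recording()].
#' @param low_hz,high_hz band-pass edges in Hz (0 < low < high < Nyquist).
#' @param notch_hz notch center frequency in Hz (< Nyquist); `NULL` skips the
#'   notch.
#' @param notch_q quality factor of the notch biquad.
#' @return The filtered `eeg_recording`.
#' @export
bandpass_notch <- function(recording, low_hz = 1, high_hz = 40,
                           notch_hz = 50, notch_q = 30) {
  nyq <- recording$sfreq / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("need 0 < low_hz < high_hz < Nyquist (", nyq, " Hz)")
  if (!is.null(notch_hz) && notch_hz >= nyq)
    stop("`notch_hz` must be below Nyquist (", nyq, " Hz)")
  bp <- signal::butter(2, c(low_hz, high_hz) / nyq, type = "pass")
  x <- recording$data
  for (ch in seq_len(nrow(x)))
    x[ch, ] <- signal::filtfilt(bp, x[ch, ])
  if (!is.null(notch_hz)) {
    # RBJ biquad notch: names the frequency and Q only, as is standard
    w0 <- 2 * pi * notch_hz / recording$sfreq
    alpha <- sin(w0) / (2 * notch_q)
    b <- c(1, -2 * cos(w0), 1)
    a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
    nf <- signal::Arma(b = b / a[1], a = a / a[1])
    for (ch in seq_len(nrow(x)))
      x[ch, ] <- signal::filtfilt(nf, x[ch, ])
  }
  recording$data <- x
  recording
}

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels from every sample, so the
#' channel mean is zero at every time point. Idempotent.
#'
#' @param recording an [eeg_recording()].
#' @return The re-referenced `eeg_recording`.
#' @export
average_reference <- function(recording) {
  recording$data <- sweep(recording$data, 2, colMeans(recording$data))
  recording
}

#' Downsample a recording
#'
#' The data are low-pass filtered (zero-phase Butterworth at 80% of the new
#' Nyquist) and every M-th sample is kept, where M is the integer decimation
#' factor. Duration is preserved to within one sample period.
#'
#' @param recording an [eeg_recording()].
#' @param target_hz new sampling rate (< current rate).
#' @return The downsampled `eeg_recording` with `sfreq = target_hz`.
#' @export
downsample <- function(recording, target_hz = 250) {
  sfreq <- recording$sfreq
  if (target_hz >= sfreq) stop("`target_hz` must be below the current rate")
  x <- recording$data
  if (abs(sfreq / target_hz - round(sfreq / target_hz)) < 1e-9) {
    f <- as.integer(round(sfreq / target_hz))
    lp <- signal::butter(4, 0.8 * (target_hz / 2) / (sfreq / 2), type = "low")
    y <- matrix(0, nrow(x), length(seq(1, ncol(x), by = f)))
    for (ch in seq_len(nrow(x)))
      y[ch, ] <- signal::filtfilt(lp, x[ch, ])[seq(1, ncol(x), by = f)]
  } else {
    stop("`target_hz` must divide `sfreq`; non-integer decimation is not supported")
  }
  recording$data <- y
  recording$sfreq <- target_hz
  recording
}

#' Global field power
#'
#' GFP(t) is the spatial standard deviation (population form, 1/C) of the
#' average-referenced potentials at time t. The recording is re-referenced
#' internally, so the result is invariant to channel-common offsets.
#'
#' @param recording an [eeg_recording()].
#' @return An object of class `gfp_series`: list with `values` (non-negative,
#'   one per sample) and `sfreq`.
#' @export
gfp <- function(recording) {
  x <- sweep(recording$data, 2, colMeans(recording$data))
  structure(list(values = sqrt(colMeans(x^2)), sfreq = recording$sfreq),
            class = "gfp_series")
}

#' Local maxima of a GFP series
#'
#' Finds strict local maxima; plateaus resolve to their leftmost sample and
#' endpoints are never peaks. With `min_separation_samples > 1` peaks are
#' kept greedily from the highest down, discarding any peak closer than the
#' minimum separation to one already kept.
#'
#' @param series a `gfp_series` from [gfp()], or a numeric vector.
#' @param min_separation_samples minimum distance between retained peaks.
#' @return Strictly increasing integer vector of peak indices.
#' @export
gfp_peaks <- function(series, min_separation_samples = 1) {
  v <- if (inherits(series, "gfp_series")) series$values else as.numeric(series)
  n <- length(v)
  if (n < 3) stop("need at least 3 samples")
  d <- diff(v)
  s <- sign(d)
  # propagate the next non-zero slope backwards across plateaus
  for (i in rev(seq_len(length(s) - 1)))
    if (s[i] == 0) s[i] <- s[i + 1]
  idx <- which(s[-length(s)] > 0 & s[-1] < 0) + 1L
  # s[i-1] refers to the slope into sample i; idx excludes endpoints already
  idx <- idx[d[idx - 1] > 0]  # require a strict rise into the (leftmost) peak
  if (min_separation_samples > 1 && length(idx) > 1) {
    keep <- integer(0)
    for (i in idx[order(v[idx], decreasing = TRUE)]) {
      if (!length(keep) || all(abs(keep - i) >= min_separation_samples))
        keep <- c(keep, i)
    }
    idx <- sort(keep)
  }
  idx
}

# Peak topographies as a peaks x channels matrix (average-referenced).
peak_maps <- function(recording, peaks) {
  x <- sweep(recording$data, 2, colMeans(recording$data))
  t(x[, peaks, drop = FALSE])
}
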