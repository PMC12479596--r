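#' Canonical EEG frequency bands
#'
#' The five bands used throughout the band-power analysis: delta 0.5-4,
#' theta 4-8, alpha 8-14, low beta 14-26, high beta 26-40 Hz (the beta split
#' can be re-derived from data with [data_driven_band_split()]).
#'
#' @return Named list of `c(low, high)` pairs in Hz.
#' @export
canonical_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 14),
       low_beta = c(14, 26), high_beta = c(26, 40))
}

#' Hanning-taper power spectrum
#'
#' Demeans each channel, applies a single Hanning taper over the whole
#' record, and computes one-sided FFT power. The FFT is zero-padded to the
#' next grid whose spacing does not exceed `max_resolution_hz`. Power is
#' scaled so that the sum over frequency bins equals the tapered time-domain
#' mean square (a Parseval identity), in microvolts squared.
#'
#' @param recording an [eeg_recording()] of at least 2 s.
#' @param max_resolution_hz upper bound on the frequency grid spacing.
#' @param n_segments optional Welch averaging: number of 50%-overlapping
#'   segments (1 = single taper over the whole record).
#' @return An object of class `power_spectrum`: list with `freqs` (Hz,
#'   strictly increasing, up to Nyquist), `power` (channels x freqs),
#'   `resolution` (Hz), `sfreq`.
#' @export
power_spectrum <- function(recording, max_resolution_hz = 0.034,
                           n_segments = 1) {
  x <- recording$data
  sfreq <- recording$sfreq
  if (ncol(x) / sfreq < 2) stop("record shorter than 2 s")
  if (n_segments > 1) {
    step <- floor(ncol(x) / (n_segments + 1))
    len <- 2 * step
    starts <- seq(1, by = step, length.out = n_segments)
    pieces <- lapply(starts, function(s) {
      seg <- recording
      seg$data <- x[, s:(s + len - 1), drop = FALSE]
      power_spectrum(seg, max_resolution_hz = max_resolution_hz)
    })
    out <- pieces[[1]]
    out$power <- Reduce(`+`, lapply(pieces, `[[`, "power")) / n_segments
    return(out)
  }
  N <- ncol(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, N - 1) / (N - 1))  # Hanning
  xw <- (x - rowMeans(x)) * rep(w, each = nrow(x))
  nfft <- max(N, ceiling(sfreq / max_resolution_hz))
  nfft <- nextn(nfft, c(2, 3, 5))
  Z <- matrix(0, nfft, nrow(x))
  Z[seq_len(N), ] <- t(xw)
  F <- mvfft(Z)
  nh <- floor(nfft / 2) + 1
  scale <- rep(2, nh)
  scale[1] <- 1
  if (nfft %% 2 == 0) scale[nh] <- 1
  pw <- t(Mod(F[seq_len(nh), , drop = FALSE])^2) *
    rep(scale, each = nrow(x)) / (nfft * sum(w^2))
  structure(list(freqs = (seq_len(nh) - 1) * sfreq / nfft,
                 power = pw, resolution = sfreq / nfft, sfreq = sfreq),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d channels, %d bins to %.1f Hz, resolution %.4f Hz\n",
              nrow(x$power), length(x$freqs), max(x$freqs), x$resolution))
  invisible(x)
}

#' Mean band power averaged across channels
#'
#' For each band, the mean power over frequency bins with
#' `low <= f < high`, averaged over channels.
#'
#' @param spectrum a `power_spectrum`.
#' @param bands named list of `c(low, high)` pairs; defaults to
#'   [canonical_bands()].
#' @return data.frame with columns `band`, `low`, `high`, `power`.
#' @export
band_power <- function(spectrum, bands = canonical_bands()) {
  chan_mean <- colMeans(spectrum$power)
  out <- lapply(names(bands), function(nm) {
    b <- bands[[nm]]
    if (b[1] >= b[2]) stop("band `", nm, "`: low must be below high")
    sel <- spectrum$freqs >= b[1] & spectrum$freqs < b[2]
    if (!any(sel)) stop("band `", nm, "` contains no frequency bins")
    data.frame(band = nm, low = b[1], high = b[2],
               power = mean(chan_mean[sel]))
  })
  do.call(rbind, out)
}

#' Data-driven frequency band boundaries by k-means
#'
#' Clusters (standardized frequency, standardized log power) pairs within a
#' frequency window using 2-D k-means (best of `nstart` restarts), orders the
#' clusters by mean frequency, and returns the midpoints between the
#' frequency extents of adjacent clusters -- the procedure used to split the
#' beta range into low and high beta.
#'
#' @param spectrum a `power_spectrum` (the channel-mean spectrum is used) or
#'   a list with `freqs` and `power`.
#' @param k_clusters number of clusters (>= 2).
#' @param freq_window `c(low, high)` window in Hz to cluster within.
#' @param seed integer seed or `NULL`.
#' @param nstart k-means restarts.
#' @return Numeric vector of `k_clusters - 1` boundary frequencies (Hz).
#' @export
data_driven_band_split <- function(spectrum, k_clusters = 2,
                                   freq_window = c(14, 40), seed = NULL,
                                   nstart = 20) {
  if (k_clusters < 2) stop("`k_clusters` must be >= 2")
  freqs <- spectrum$freqs
  pw <- if (is.matrix(spectrum$power)) colMeans(spectrum$power)
        else as.numeric(spectrum$power)
  sel <- freqs >= freq_window[1] & freqs <= freq_window[2]
  if (sum(sel) < k_clusters) stop("fewer frequency bins than clusters")
  f <- freqs[sel]
  lp <- log(pw[sel] + 1e-300)
  zf <- if (sd(f) > 0) (f - mean(f)) / sd(f) else f * 0
  zp <- if (sd(lp) > 1e-12) (lp - mean(lp)) / sd(lp) else lp * 0
  km <- with_seed(seed,
                  kmeans(cbind(zf, zp), centers = k_clusters, nstart = nstart,
                         iter.max = 50))
  ord <- order(tapply(f, km$cluster, mean))
  bounds <- numeric(k_clusters - 1)
  for (i in seq_len(k_clusters - 1)) {
    lo <- max(f[km$cluster == ord[i]])
    hi <- min(f[km$cluster == ord[i + 1]])
    bounds[i] <- (lo + hi) / 2
  }
  bounds
}
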