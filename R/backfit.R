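#' Back-fit template maps to every EEG sample
#'
#' Labels each sample with the template of highest absolute spatial
#' correlation (polarity disregarded). Samples whose best correlation falls
#' below `threshold` are left unassigned (label 0). Ties go to the lower map
#' index.
#'
#' @param recording an [eeg_recording()] (average-referenced internally).
#' @param templates a [template_maps()] object.
#' @param threshold spatial-correlation threshold in \[0, 1\] (default 0.5).
#' @return An object of class `ms_segmentation`: list with `labels`
#'   (integer, 0 = unassigned), `abs_corr` (winning absolute correlation per
#'   sample), `corr` (samples x k absolute-correlation matrix), `gfp`,
#'   `sfreq`, `k`, `map_labels`.
#' @export
assign_labels <- function(recording, templates, threshold = 0.5) {
  Tm <- templates$maps
  if (ncol(Tm) != nrow(recording$data))
    stop("template channel count (", ncol(Tm),
         ") does not match recording (", nrow(recording$data), ")")
  X <- sweep(recording$data, 2, colMeans(recording$data))
  n <- ncol(X); C <- nrow(X)
  norms <- sqrt(colSums(X^2))
  gfpv <- norms / sqrt(C)
  safe <- pmax(norms, 1e-300)
  corr <- abs(crossprod(X / rep(safe, each = C), t(Tm)))   # n x k
  lab <- max.col(corr, ties.method = "first")
  best <- corr[cbind(seq_len(n), lab)]
  lab[best < threshold | norms < 1e-300] <- 0L
  structure(list(labels = lab,
                 abs_corr = ifelse(lab > 0, best, 0),
                 corr = corr, gfp = gfpv, sfreq = recording$sfreq,
                 k = nrow(Tm), map_labels = templates$map_labels),
            class = "ms_segmentation")
}

#' @export
print.ms_segmentation <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf("<ms_segmentation> %d samples @ %g Hz, %d maps, %.1f%% assigned\n",
              n, x$sfreq, x$k, 100 * mean(x$labels > 0)))
  invisible(x)
}

# Windowed sums of each column of B over +/- w samples (edges truncated).
window_sums <- function(B, w) {
  n <- nrow(B)
  if (w == 0) return(B)
  t <- seq_len(n)
  hi <- pmin(t + w, n)
  lo <- pmax(t - w, 1L)
  apply(B, 2, function(col) {
    cs <- cumsum(c(0, col))
    cs[hi + 1L] - cs[lo]
  })
}

#' Temporally smooth a microstate label sequence
#'
#' Penalized windowed relabeling: each sample's score for map m is the
#' GFP-squared-weighted squared-correlation support summed over a window of
#' `half_window` samples on each side, plus a strength-scaled bonus
#' proportional to how many neighbors in the window currently carry label m.
#' Labels are updated simultaneously and iterated to a fixed point (cycle
#' detection, at most `max_iter` sweeps). Unassigned samples are never
#' relabeled. With `half_window = 0` and `strength = 0` the input is
#' returned unchanged.
#'
#' @param segmentation an `ms_segmentation` from [assign_labels()].
#' @param half_window window half-size in samples (default 3).
#' @param strength smoothing strength (default 10); 0 disables the
#'   neighbor bonus.
#' @param max_iter sweep cap.
#' @return The smoothed `ms_segmentation`.
#' @export
smooth_labels <- function(segmentation, half_window = 3, strength = 10,
                          max_iter = 50) {
  if (half_window < 0 || strength < 0)
    stop("`half_window` and `strength` must be non-negative")
  seg <- segmentation
  n <- length(seg$labels)
  k <- seg$k
  mask <- seg$labels > 0L
  if (!any(mask) || (half_window == 0 && strength == 0)) return(seg)
  B <- seg$corr^2 * seg$gfp^2
  Wsum <- window_sums(B, half_window)
  bonus <- strength * mean(seg$gfp^2)
  lab <- seg$labels
  odd <- which(mask & (seq_len(n) %% 2L == 1L))
  even <- which(mask & (seq_len(n) %% 2L == 0L))
  for (it in seq_len(max_iter)) {
    before <- lab
    # red-black half-sweeps: updating alternate samples against the current
    # labels converges where a fully synchronous update can oscillate
    for (half in list(odd, even)) {
      if (!length(half)) next
      Ind <- matrix(0, n, k)
      Ind[cbind(which(mask), lab[mask])] <- 1
      Ncnt <- window_sums(Ind, max(half_window, 1L)) - Ind
      score <- Wsum + bonus * Ncnt
      lab[half] <- max.col(score[half, , drop = FALSE], ties.method = "first")
    }
    if (identical(lab, before)) break
  }
  seg$labels <- lab
  seg$abs_corr <- ifelse(lab > 0, seg$corr[cbind(seq_len(n), pmax(lab, 1L))], 0)
  seg
}

#' Microstate temporal parameters of a segmentation
#'
#' Extracts the four classic per-map parameters:
#' * GEV (percent): `sum over samples labeled m of (GFP_t * r_t)^2`, divided
#'   by the total `sum of GFP_t^2`, times 100;
#' * mean duration (ms): average run length of map m (runs truncated at the
#'   recording edges are counted);
#' * coverage (percent of total samples labeled m);
#' * occurrence (runs of m per second).
#'
#' On segmentations without unassigned samples the bookkeeping identity
#' `coverage = occurrence * mean_duration / 10` holds exactly.
#'
#' @param segmentation an `ms_segmentation`.
#' @return data.frame of class `ms_metrics` with columns `map`, `map_label`,
#'   `gev`, `mean_duration`, `coverage`, `occurrence`.
#' @export
compute_metrics <- function(segmentation) {
  seg <- segmentation
  n <- length(seg$labels)
  if (!n) stop("empty segmentation")
  denom <- sum(seg$gfp^2)
  r <- rle(seg$labels)
  dur_s <- n / seg$sfreq
  out <- data.frame(map = seq_len(seg$k),
                    map_label = seg$map_labels %||% as.character(seq_len(seg$k)),
                    gev = 0, mean_duration = NA_real_, coverage = 0,
                    occurrence = 0)
  for (m in seq_len(seg$k)) {
    sel <- seg$labels == m
    out$gev[m] <- 100 * sum((seg$gfp[sel] * seg$abs_corr[sel])^2) / denom
    runs <- r$lengths[r$values == m]
    if (length(runs)) out$mean_duration[m] <- mean(runs) * 1000 / seg$sfreq
    out$coverage[m] <- 100 * sum(sel) / n
    out$occurrence[m] <- length(runs) / dur_s
  }
  class(out) <- c("ms_metrics", "data.frame")
  out
}
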