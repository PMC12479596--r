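#' EEG recording container
#'
#' A minimal container for one subject's multichannel EEG: a channels x
#' samples matrix in microvolts plus its sampling rate, channel labels and
#' subject metadata.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param sfreq sampling rate in Hz.
#' @param channel_labels character vector, one label per channel. Defaults to
#'   `E001`, `E002`, ...
#' @param subject_id subject identifier.
#' @param group group tag (`"A"`, `"B"` or `NA` when ungrouped).
#'
#' @return An object of class `eeg_recording`: a list with elements `data`,
#'   `sfreq`, `channel_labels`, `subject_id`, `group`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(20), 4, 5), sfreq = 250)
#' n_channels(rec)
#' @export
eeg_recording <- function(data, sfreq, channel_labels = NULL,
                          subject_id = "S01", group = NA_character_) {
  data <- as.matrix(data)
  dimnames(data) <- NULL
  if (!is.numeric(data)) stop("`data` must be a numeric matrix")
  if (nrow(data) < 2L) stop("need at least 2 channels")
  if (ncol(data) < 2L) stop("need at least 2 samples")
  if (!all(is.finite(data))) stop("`data` contains non-finite values")
  if (!is.numeric(sfreq) || length(sfreq) != 1L || sfreq <= 0)
    stop("`sfreq` must be a positive scalar")
  if (is.null(channel_labels))
    channel_labels <- sprintf("E%03d", seq_len(nrow(data)))
  if (length(channel_labels) != nrow(data))
    stop("one channel label per channel required")
  if (!is.na(group) && !group %in% c("A", "B"))
    stop("`group` must be \"A\", \"B\" or NA")
  structure(
    list(data = data, sfreq = as.numeric(sfreq),
         channel_labels = as.character(channel_labels),
         subject_id = as.character(subject_id), group = group),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s%s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id,
              if (is.na(x$group)) "" else paste0(" [group ", x$group, "]"),
              nrow(x$data), ncol(x$data), x$sfreq, ncol(x$data) / x$sfreq))
  invisible(x)
}

#' @rdname eeg_recording
#' @param x an `eeg_recording`.
#' @export
n_channels <- function(x) nrow(x$data)

#' @rdname eeg_recording
#' @export
n_samples <- function(x) ncol(x$data)

#' Template map container
#'
#' Holds k unit-norm, average-referenced scalp topographies (the microstate
#' classes) as a k x channels matrix.
#'
#' @param maps numeric matrix, k x channels; each row is normalized to zero
#'   channel mean and unit Euclidean norm.
#' @param map_labels character labels, defaults to `"A"`, `"B"`, ...
#' @param gev_total total global explained variance (fraction in \[0, 1\]) of
#'   the maps on the data they were derived from, or `NA` when unknown.
#' @return An object of class `template_maps`.
#' @export
template_maps <- function(maps, map_labels = NULL, gev_total = NA_real_) {
  maps <- as.matrix(maps)
  if (ncol(maps) < 2L) stop("maps need at least 2 channels")
  maps <- maps - rowMeans(maps)
  nrm <- sqrt(rowSums(maps^2))
  if (any(nrm < 1e-12)) stop("zero-variance template map")
  maps <- maps / nrm
  k <- nrow(maps)
  if (is.null(map_labels)) {
    map_labels <- if (k <= 26) LETTERS[seq_len(k)] else sprintf("M%02d", seq_len(k))
  }
  if (length(map_labels) != k) stop("one label per map required")
  rownames(maps) <- map_labels
  structure(list(maps = maps, map_labels = map_labels,
                 gev_total = gev_total),
            class = "template_maps")
}

#' @export
print.template_maps <- function(x, ...) {
  cat(sprintf("<template_maps> %d maps (%s), %d channels%s\n",
              nrow(x$maps), paste(x$map_labels, collapse = ", "),
              ncol(x$maps),
              if (is.na(x$gev_total)) ""
              else sprintf(", GEV %.1f%%", 100 * x$gev_total)))
  invisible(x)
}
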