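#' Read and write recordings as delimited text
#'
#' The plain-text interchange format is a channels x samples matrix of
#' tab-separated values, preceded by comment lines (`#key value`) carrying
#' the sampling rate, subject id, group and channel labels.
#'
#' @param recording an [eeg_recording()].
#' @param path file path.
#' @return `read_recording_txt` returns an `eeg_recording`;
#'   `write_recording_txt` returns `path` invisibly.
#' @export
write_recording_txt <- function(recording, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#sfreq %.10g", recording$sfreq),
               sprintf("#subject_id %s", recording$subject_id),
               sprintf("#group %s", ifelse(is.na(recording$group), "NA",
                                           recording$group)),
               paste("#channels", paste(recording$channel_labels,
                                        collapse = "\t"))), con)
  write.table(recording$data, con, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_txt
#' @export
read_recording_txt <- function(path) {
  lines <- readLines(path, n = 50)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("#", key))]
    if (!length(ln)) return(NULL)
    sub(paste0("^#", key, "[ \t]+"), "", ln[1])
  }
  sfreq <- as.numeric(get("sfreq") %||% stop("missing #sfreq header"))
  grp <- get("group") %||% "NA"
  chans <- get("channels")
  dat <- as.matrix(read.table(path, sep = "\t", comment.char = "#"))
  dimnames(dat) <- NULL
  eeg_recording(dat, sfreq,
                channel_labels = if (!is.null(chans))
                  strsplit(chans, "\t")[[1]] else NULL,
                subject_id = get("subject_id") %||% "S01",
                group = if (grp == "NA") NA_character_ else grp)
}

#' Read and write electrode montages as xyz text
#'
#' Whitespace-delimited file with one electrode per line: label and x, y, z
#' coordinates.
#'
#' @param montage an `eeg_montage`.
#' @param path file path.
#' @export
write_montage_xyz <- function(montage, path) {
  write.table(montage[, c("label", "x", "y", "z")], path, sep = " ",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_montage_xyz
#' @export
read_montage_xyz <- function(path) {
  d <- read.table(path, col.names = c("label", "x", "y", "z"),
                  stringsAsFactors = FALSE)
  class(d) <- c("eeg_montage", "data.frame")
  d
}

#' Write simulation ground truth as JSON
#'
#' @param truth a [simulation_truth()].
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(template_maps = unname(as.matrix(truth$template_maps$maps)),
         dwell_mean_ms = truth$dwell_mean_ms,
         transition_matrix = truth$transition_matrix,
         snr = truth$snr,
         group_effects = truth$group_effects,
         subject_sd = truth$subject_sd,
         seed = truth$seed),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Write a segmentation as per-sample CSV
#'
#' Columns: sample, label (0 = unassigned), abs_corr, gfp.
#'
#' @param segmentation an `ms_segmentation`.
#' @param path file path.
#' @export
write_segmentation_csv <- function(segmentation, path) {
  write.csv(data.frame(sample = seq_along(segmentation$labels),
                       label = segmentation$labels,
                       abs_corr = segmentation$abs_corr,
                       gfp = segmentation$gfp),
            path, row.names = FALSE)
  invisible(path)
}

#' Write a GFP series as single-column CSV
#'
#' @param series a `gfp_series`.
#' @param path file path.
#' @export
write_gfp_csv <- function(series, path) {
  write.csv(data.frame(gfp = series$values), path, row.names = FALSE)
  invisible(path)
}
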