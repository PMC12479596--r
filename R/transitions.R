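#' Count run-to-run microstate transitions
#'
#' Collapses the label sequence to runs and counts one transition per pair
#' of consecutive runs. Transitions into or out of unassigned stretches are
#' dropped; self-transitions are impossible by construction (consecutive
#' runs differ). With k maps there are k*(k-1) possible ordered pairs
#' (12 for the classic four maps).
#'
#' @param segmentation an `ms_segmentation`, a `state_sequence`, or an
#'   integer label vector (0 = unassigned).
#' @param k number of maps (taken from the segmentation when available).
#' @return k x k integer matrix of counts with zero diagonal.
#' @export
transition_counts <- function(segmentation, k = NULL) {
  labels <- if (inherits(segmentation, "ms_segmentation")) segmentation$labels
            else if (inherits(segmentation, "state_sequence")) segmentation$labels
            else as.integer(segmentation)
  if (is.null(k)) {
    k <- if (inherits(segmentation, "ms_segmentation")) segmentation$k
         else max(labels)
  }
  v <- rle(labels)$values
  counts <- matrix(0L, k, k)
  if (length(v) < 2) {
    warning("fewer than 2 runs: empty transition table")
    return(counts)
  }
  from <- v[-length(v)]
  to <- v[-1]
  ok <- from > 0L & to > 0L
  if (any(ok)) {
    tab <- table(factor(from[ok], levels = seq_len(k)),
                 factor(to[ok], levels = seq_len(k)))
    counts <- matrix(as.integer(tab), k, k)
  }
  counts
}

#' Per-map run counts of a segmentation
#'
#' @inheritParams transition_counts
#' @return integer vector of length k: number of runs of each map.
#' @export
run_frequencies <- function(segmentation, k = NULL) {
  labels <- if (inherits(segmentation, "ms_segmentation")) segmentation$labels
            else if (inherits(segmentation, "state_sequence")) segmentation$labels
            else as.integer(segmentation)
  if (is.null(k)) {
    k <- if (inherits(segmentation, "ms_segmentation")) segmentation$k
         else max(labels)
  }
  v <- rle(labels)$values
  tabulate(v[v > 0L], nbins = k)
}

#' Observed/expected normalization of transition probabilities
#'
#' Observed row-conditional probabilities `counts[i, j] / rowSums(counts)[i]`
#' are divided by the probabilities expected if successors were drawn
#' independently, in proportion to map run frequencies, with self-transitions
#' excluded from the normalizing pool:
#' `expected[i, j] = freq_j / sum(freq_m, m != i)`.
#' Ratios above 1 indicate sequential structure beyond what map frequencies
#' alone explain. Cells with undefined observed or expected probability
#' (empty row, zero expected frequency) are `NA`.
#'
#' @param counts k x k transition count matrix from [transition_counts()].
#' @param run_frequencies per-map run counts from [run_frequencies()].
#' @return An object of class `transition_table`: list with matrices
#'   `counts`, `observed`, `expected`, `normalized`.
#' @export
normalized_transitions <- function(counts, run_frequencies) {
  k <- nrow(counts)
  stopifnot(length(run_frequencies) == k)
  rs <- rowSums(counts)
  observed <- counts / ifelse(rs > 0, rs, NA_real_)
  expected <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    pool <- sum(run_frequencies[-i])
    if (pool > 0) expected[i, ] <- run_frequencies / pool
  }
  diag(observed) <- NA_real_
  diag(expected) <- NA_real_
  normalized <- observed / ifelse(expected > 0, expected, NA_real_)
  structure(list(counts = counts, observed = observed, expected = expected,
                 normalized = normalized),
            class = "transition_table")
}

#' @export
print.transition_table <- function(x, ...) {
  cat("<transition_table>", nrow(x$counts), "maps,",
      sum(x$counts), "transitions\n")
  cat("normalized observed/expected ratios:\n")
  print(round(x$normalized, 3))
  invisible(x)
}

#' Tidy a transition table
#'
#' @param x a `transition_table`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with one row per ordered off-diagonal pair: `from`,
#'   `to`, `count`, `observed`, `expected`, `normalized`.
#' @export
as.data.frame.transition_table <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  idx <- which(row(x$counts) != col(x$counts), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(from = idx[, 1], to = idx[, 2],
             count = x$counts[idx],
             observed = x$observed[idx],
             expected = x$expected[idx],
             normalized = x$normalized[idx])
}
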