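# Small fixtures and independent oracles used across the test files.

# standard small simulation setup
small_setup <- function(n_maps = 4, n_channels = 16, seed = 42, snr = 4, ...) {
  mont <- make_montage(n_channels)
  tm <- make_template_maps(n_maps, mont, seed = seed)
  list(montage = mont, templates = tm,
       truth = simulation_truth(tm, snr = snr, ...))
}

# k mutually orthogonal, zero-mean, unit-norm maps (exact)
orthogonal_maps <- function(k, C, seed = 1) {
  set.seed(seed)
  # Helmert-style contrasts are zero-sum and mutually orthogonal
  H <- contr.helmert(C)[, seq_len(k), drop = FALSE]
  t(H) / sqrt(colSums(H^2))
}

# Brute-force maximal GEV over every possible label assignment: for a fixed
# partition the optimal template of a cluster is the leading eigenvector of
# the summed outer products, contributing its leading eigenvalue.
brute_force_gev <- function(X, k) {
  X <- as.matrix(X)
  X <- X - rowMeans(X)
  n <- nrow(X)
  total <- sum(X^2)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  best <- 0
  for (i in seq_len(nrow(grid))) {
    lab <- grid[i, ]
    tot <- 0
    for (j in unique(lab)) {
      M <- crossprod(X[lab == j, , drop = FALSE])
      tot <- tot + eigen(M, symmetric = TRUE, only.values = TRUE)$values[1]
    }
    if (tot > best) best <- tot
  }
  best / total
}

# hand-built segmentation for metric tests
make_seg <- function(labels, sfreq = 250, k = max(labels),
                     abs_corr = NULL, gfp = NULL) {
  n <- length(labels)
  structure(list(labels = as.integer(labels),
                 abs_corr = abs_corr %||% rep(1, n),
                 corr = matrix(1, n, k),
                 gfp = gfp %||% rep(1, n),
                 sfreq = sfreq, k = k,
                 map_labels = LETTERS[seq_len(k)]),
            class = "ms_segmentation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rms <- function(x) sqrt(mean(x^2))

# pure sine test recording
sine_recording <- function(freq, sfreq = 250, duration_s = 4, C = 4) {
  t <- seq(0, duration_s - 1 / sfreq, by = 1 / sfreq)
  x <- outer(seq_len(C), sin(2 * pi * freq * t), function(a, b) b * a)
  eeg_recording(x, sfreq)
}
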