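#' Fit a microstate model to a cohort of EEG recordings
#'
#' The main entry point of the package. Runs the full microstate estimation
#' chain on a list of (preprocessed) recordings:
#' 1. two-level polarity-invariant modified k-means at GFP peaks
#'    (subject-level maps, then group-level maps, with merging of maps
#'    correlated at `merge_threshold` or above and a multi-criterion choice
#'    of the number of maps unless `k` is fixed);
#' 2. back-fitting of the group maps to every sample of every recording,
#'    with the correlation threshold and temporal smoothing;
#' 3. extraction of the four temporal parameters (GEV, mean duration,
#'    coverage, occurrence) per subject and map;
#' 4. Markov-chain transition counting with observed/expected
#'    normalization per subject.
#'
#' @param recordings list of [eeg_recording()] objects (assumed filtered;
#'   they are average-referenced internally).
#' @param k fixed number of group maps; `NULL` selects it by the
#'   meta-criterion over `k_range`.
#' @param k_range candidate map counts.
#' @param subject_k fixed subject-level map count (`NULL` = per-subject
#'   meta-criterion; fixing it is much faster).
#' @param restarts random restarts for clustering (default 300).
#' @param subject_restarts restarts at the subject level.
#' @param merge_threshold absolute spatial correlation at or above which
#'   group maps are merged (default 0.80).
#' @param threshold back-fitting spatial-correlation threshold (default 0.5).
#' @param half_window,strength temporal smoothing parameters (defaults 3
#'   samples and 10).
#' @param smooth apply temporal smoothing (default TRUE).
#' @param seed integer seed or `NULL`.
#' @return An object of class `microstate_fit` with components `templates`
#'   (a [template_maps()]), `k`, `gev_total`, `metrics` (long data.frame:
#'   subject, group, map, gev, mean_duration, coverage, occurrence),
#'   `transitions` (long data.frame of per-subject normalized transition
#'   ratios), `segmentations` (list of `ms_segmentation`), `params`, `call`.
#' @seealso [summary.microstate_fit()], [predict.microstate_fit()],
#'   [simulate.microstate_fit()]
#' @examples
#' \donttest{
#' tm <- make_template_maps(4, make_montage(32), seed = 1)
#' truth <- simulation_truth(tm, snr = 4)
#' coh <- simulate_cohort(3, truth, duration_s = 20, montage = make_montage(32),
#'                        seed = 1)
#' fit <- microstate_fit(coh$recordings, k = 4, subject_k = 4,
#'                       restarts = 10, seed = 1)
#' fit
#' }
#' @export
microstate_fit <- function(recordings, k = NULL, k_range = 1:12,
                           subject_k = NULL, restarts = 300,
                           subject_restarts = restarts,
                           merge_threshold = 0.80, threshold = 0.5,
                           half_window = 3, strength = 10, smooth = TRUE,
                           seed = NULL) {
  cl <- match.call()
  templates <- two_level_clustering(recordings, k_range = k_range,
                                    restarts = restarts,
                                    merge_threshold = merge_threshold,
                                    subject_k = subject_k,
                                    subject_restarts = subject_restarts,
                                    group_k = k, seed = seed)
  segs <- list()
  met <- list()
  trans <- list()
  for (i in seq_along(recordings)) {
    rec <- average_reference(recordings[[i]])
    seg <- assign_labels(rec, templates, threshold = threshold)
    if (smooth) seg <- smooth_labels(seg, half_window, strength)
    id <- rec$subject_id
    segs[[id]] <- seg
    m <- compute_metrics(seg)
    m$subject <- id
    m$group <- rec$group
    met[[id]] <- m
    tt <- normalized_transitions(transition_counts(seg), run_frequencies(seg))
    td <- as.data.frame(tt)
    td$subject <- id
    td$group <- rec$group
    trans[[id]] <- td
  }
  structure(list(
    templates = templates,
    k = nrow(templates$maps),
    gev_total = templates$gev_total,
    map_labels = templates$map_labels,
    metrics = do.call(rbind, c(met, list(make.row.names = FALSE))),
    transitions = do.call(rbind, c(trans, list(make.row.names = FALSE))),
    segmentations = segs,
    params = list(threshold = threshold, half_window = half_window,
                  strength = strength, merge_threshold = merge_threshold,
                  restarts = restarts, subject_k = subject_k, seed = seed),
    call = cl), class = "microstate_fit")
}

#' @export
print.microstate_fit <- function(x, ...) {
  groups <- table(x$metrics$group[!duplicated(x$metrics$subject)])
  cat("Microstate model\n")
  cat(sprintf("  %d maps (%s), total GEV %.1f%%\n", x$k,
              paste(x$map_labels, collapse = ", "), 100 * x$gev_total))
  cat(sprintf("  %d subjects (%s)\n", length(x$segmentations),
              paste(sprintf("%s: %d", names(groups), groups), collapse = ", ")))
  cat("  mean duration (ms) by map:\n")
  md <- tapply(x$metrics$mean_duration, x$metrics$map_label, mean, na.rm = TRUE)
  print(round(md, 1))
  invisible(x)
}

#' @export
coef.microstate_fit <- function(object, ...) object$templates$maps

#' Summarize a microstate fit with group comparisons
#'
#' Computes per-group means of the four temporal parameters and, when two
#' groups are present, Mann-Whitney tests per map and parameter with the
#' effective-number-of-tests Sidak-adjusted alpha (Li & Ji), plus pooled t
#' tests on the normalized transition ratios with their own adjusted alpha.
#'
#' @param object a `microstate_fit`.
#' @param alpha nominal family-wise alpha (default 0.05).
#' @param ... unused.
#' @return An object of class `summary.microstate_fit` with data.frames
#'   `parameter_tests` and `transition_tests` (columns: variable, group
#'   means, statistic, p, effect) and the adjusted alphas.
#' @export
summary.microstate_fit <- function(object, alpha = 0.05, ...) {
  m <- object$metrics
  groups <- sort(unique(m$group[!is.na(m$group)]))
  out <- list(fit = object, alpha = alpha, groups = groups)
  group_means <- aggregate(
    m[, c("gev", "mean_duration", "coverage", "occurrence")],
    by = list(map_label = m$map_label, group = m$group), FUN = mean,
    na.rm = TRUE)
  out$group_means <- group_means
  if (length(groups) == 2) {
    pars <- c("gev", "mean_duration", "coverage", "occurrence")
    rows <- list()
    for (p in pars) for (mp in sort(unique(m$map))) {
      xa <- m[[p]][m$group == groups[1] & m$map == mp]
      xb <- m[[p]][m$group == groups[2] & m$map == mp]
      if (any(!is.finite(xa)) || any(!is.finite(xb))) next
      tst <- mann_whitney(xa, xb)
      nm <- paste0(p, "_", object$map_labels[mp])
      rows[[nm]] <- data.frame(variable = nm, mean_a = mean(xa),
                               mean_b = mean(xb), U = tst$statistic,
                               p = tst$p, cliffs_delta = tst$effect)
    }
    out$parameter_tests <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    # effective number of tests from the subjects x variables matrix
    vm <- build_variable_matrix(m)
    out$meff_parameters <- tryCatch(li_ji_meff(vm), error = function(e) NULL)
    out$alpha_parameters <- if (!is.null(out$meff_parameters))
      sidak_alpha(alpha, out$meff_parameters) else alpha
    # transitions: pooled t tests on normalized ratios
    tr <- object$transitions
    trows <- list()
    for (ft in unique(paste(tr$from, tr$to))) {
      sel <- paste(tr$from, tr$to) == ft
      xa <- tr$normalized[sel & tr$group == groups[1]]
      xb <- tr$normalized[sel & tr$group == groups[2]]
      xa <- xa[is.finite(xa)]; xb <- xb[is.finite(xb)]
      if (length(xa) < 2 || length(xb) < 2) next
      tt <- t.test(xa, xb, var.equal = TRUE)
      fromto <- as.integer(strsplit(ft, " ")[[1]])
      nm <- paste0(object$map_labels[fromto[1]], "_to_",
                   object$map_labels[fromto[2]])
      sp <- sqrt(((length(xa) - 1) * var(xa) + (length(xb) - 1) * var(xb)) /
                   (length(xa) + length(xb) - 2))
      trows[[nm]] <- data.frame(variable = nm, mean_a = mean(xa),
                                mean_b = mean(xb),
                                t = unname(tt$statistic), p = tt$p.value,
                                cohens_d = (mean(xa) - mean(xb)) / sp)
    }
    out$transition_tests <- do.call(rbind, c(trows, list(make.row.names = FALSE)))
    tvm <- build_transition_matrix_wide(tr)
    out$meff_transitions <- tryCatch(li_ji_meff(tvm), error = function(e) NULL)
    out$alpha_transitions <- if (!is.null(out$meff_transitions))
      sidak_alpha(alpha, out$meff_transitions) else alpha
  }
  class(out) <- "summary.microstate_fit"
  out
}

# subjects x (map x parameter) matrix for the Li-Ji correction
build_variable_matrix <- function(metrics) {
  pars <- c("gev", "mean_duration", "coverage", "occurrence")
  subs <- unique(metrics$subject)
  cols <- list()
  for (p in pars) for (mp in sort(unique(metrics$map))) {
    v <- vapply(subs, function(s)
      metrics[[p]][metrics$subject == s & metrics$map == mp][1], numeric(1))
    if (all(is.finite(v)) && sd(v) > 1e-12)
      cols[[paste0(p, mp)]] <- v
  }
  do.call(cbind, cols)
}

build_transition_matrix_wide <- function(tr) {
  subs <- unique(tr$subject)
  keys <- unique(paste(tr$from, tr$to))
  cols <- list()
  for (ky in keys) {
    v <- vapply(subs, function(s) {
      z <- tr$normalized[tr$subject == s & paste(tr$from, tr$to) == ky]
      if (length(z)) z[1] else NA_real_
    }, numeric(1))
    if (all(is.finite(v)) && sd(v) > 1e-12) cols[[ky]] <- v
  }
  do.call(cbind, cols)
}

#' @export
print.summary.microstate_fit <- function(x, ...) {
  print(x$fit)
  cat("\nGroup means:\n")
  print(x$group_means, digits = 3)
  if (!is.null(x$parameter_tests)) {
    cat(sprintf("\nParameter tests (Mann-Whitney; Sidak-adjusted alpha = %.4f):\n",
                x$alpha_parameters))
    print(x$parameter_tests, digits = 3)
  }
  if (!is.null(x$transition_tests)) {
    cat(sprintf("\nTransition tests (pooled t; Sidak-adjusted alpha = %.4f):\n",
                x$alpha_transitions))
    print(x$transition_tests, digits = 3)
  }
  invisible(x)
}

#' Back-fit a fitted microstate model to new recordings
#'
#' @param object a `microstate_fit`.
#' @param newdata an [eeg_recording()] or list of them.
#' @param threshold,half_window,strength,smooth override the fit's
#'   back-fitting parameters.
#' @param ... unused.
#' @return An `ms_segmentation` (or list of them).
#' @export
predict.microstate_fit <- function(object, newdata,
                                   threshold = object$params$threshold,
                                   half_window = object$params$half_window,
                                   strength = object$params$strength,
                                   smooth = TRUE, ...) {
  one <- function(rec) {
    seg <- assign_labels(average_reference(rec), object$templates,
                         threshold = threshold)
    if (smooth) seg <- smooth_labels(seg, half_window, strength)
    seg
  }
  if (inherits(newdata, "eeg_recording")) one(newdata) else lapply(newdata, one)
}

#' Simulate recordings from a fitted microstate model
#'
#' Uses the fitted templates, the grand-mean per-map dwell durations and the
#' pooled observed transition probabilities as generative parameters for the
#' semi-Markov synthetic EEG generator -- a parametric-bootstrap style
#' round trip.
#'
#' @param object a `microstate_fit`.
#' @param nsim number of recordings.
#' @param seed integer seed or `NULL`.
#' @param duration_s,sfreq length and rate of each simulated recording.
#' @param montage electrode montage; defaults to a Fibonacci cap of the
#'   fitted channel count.
#' @param snr signal-to-noise RMS ratio.
#' @param ... unused.
#' @return list of [eeg_recording()] objects.
#' @export
simulate.microstate_fit <- function(object, nsim = 1, seed = NULL,
                                    duration_s = 60, sfreq = 250,
                                    montage = NULL, snr = 4, ...) {
  m <- object$metrics
  dwell <- vapply(sort(unique(m$map)), function(mp)
    mean(m$mean_duration[m$map == mp], na.rm = TRUE), numeric(1))
  dwell[!is.finite(dwell)] <- mean(dwell[is.finite(dwell)])
  tr <- object$transitions
  k <- object$k
  P <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    P[i, j] <- sum(tr$count[tr$from == i & tr$to == j])
  }
  P <- P / pmax(rowSums(P), 1)
  zero <- rowSums(P) == 0
  P[zero, ] <- 1 / (k - 1)
  diag(P) <- 0
  P <- P / rowSums(P)
  if (is.null(montage)) montage <- make_montage(ncol(object$templates$maps))
  truth <- simulation_truth(object$templates, dwell_mean_ms = dwell,
                            transition_matrix = P, snr = snr,
                            group_effects = NULL)
  lapply(seq_len(nsim), function(i) {
    sq <- simulate_state_sequence(truth, duration_s, sfreq,
                                  seed = child_seed(seed, i))
    simulate_recording(truth, sq, montage, snr = snr,
                       seed = child_seed(seed, i + nsim),
                       subject_id = sprintf("sim%02d", i))
  })
}

#' Plot fitted microstate topographies
#'
#' Draws each template map as an interpolated top-view scalp field
#' (azimuthal projection of the electrode positions, inverse-distance
#' interpolation).
#'
#' @param x a `microstate_fit` or `template_maps`.
#' @param montage electrode montage used for electrode positions; defaults
#'   to a Fibonacci cap of matching channel count.
#' @param grid_n interpolation grid resolution.
#' @param ... unused.
#' @export
plot.microstate_fit <- function(x, montage = NULL, grid_n = 60, ...) {
  plot(x$templates, montage = montage, grid_n = grid_n, ...)
}

#' @rdname plot.microstate_fit
#' @export
plot.template_maps <- function(x, montage = NULL, grid_n = 60, ...) {
  maps <- x$maps
  if (is.null(montage)) montage <- make_montage(ncol(maps))
  pos <- montage_positions(montage)
  # azimuthal equidistant projection to the unit disk
  rr <- acos(pmin(pmax(pos[, 3], -1), 1)) / (pi / 2)
  ang <- atan2(pos[, 2], pos[, 1])
  px <- rr * cos(ang); py <- rr * sin(ang)
  gx <- seq(-1.05, 1.05, length.out = grid_n)
  g <- expand.grid(x = gx, y = gx)
  k <- nrow(maps)
  old <- par(mfrow = c(1, k), mar = c(0.5, 0.5, 2, 0.5))
  on.exit(par(old), add = TRUE)
  for (m in seq_len(k)) {
    d2 <- outer(g$x, px, "-")^2 + outer(g$y, py, "-")^2
    wgt <- 1 / (d2 + 1e-4)
    z <- as.numeric(wgt %*% maps[m, ]) / rowSums(wgt)
    z[g$x^2 + g$y^2 > 1.05] <- NA
    image(gx, gx, matrix(z, grid_n, grid_n),
          col = hcl.colors(64, "RdBu", rev = TRUE),
          axes = FALSE, asp = 1, xlab = "", ylab = "",
          main = x$map_labels[m])
    points(px, py, pch = 16, cex = 0.4)
  }
  invisible(x)
}
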