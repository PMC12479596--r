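#' Spatial correlation between two scalp maps
#'
#' Pearson correlation across channels of the average-referenced vectors.
#' With `ignore_polarity = TRUE` (the microstate convention) the absolute
#' value is returned.
#'
#' @param u,v numeric vectors of equal length (one potential per channel).
#' @param ignore_polarity return `|r|` instead of the signed correlation.
#' @return A scalar in \[0, 1\] (or \[-1, 1\] when signed).
#' @export
spatial_correlation <- function(u, v, ignore_polarity = TRUE) {
  if (length(u) != length(v)) stop("channel counts differ")
  u <- u - mean(u); v <- v - mean(v)
  du <- sum(u^2); dv <- sum(v^2)
  if (du < 1e-300 || dv < 1e-300)
    stop("undefined correlation: zero-variance map")
  r <- sum(u * v) / sqrt(du * dv)
  if (ignore_polarity) abs(r) else r
}

# Internal: rows average-referenced; returns list(X, Xu, norms2).
prep_maps <- function(peak_maps) {
  X <- as.matrix(peak_maps)
  X <- X - rowMeans(X)
  norms2 <- rowSums(X^2)
  if (any(norms2 < 1e-300)) stop("zero-variance peak map")
  list(X = X, Xu = X / sqrt(norms2), norms2 = norms2)
}

# First principal pattern of a set of maps (leading eigenvector of the
# summed outer products), optionally weighted; sign-fixed, zero-mean, unit.
dominant_pattern <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  t <- e$vectors[, 1]
  t <- t - mean(t)
  t <- t / sqrt(sum(t^2))
  if (t[which.max(abs(t))] < 0) t <- -t
  t
}

#' Polarity-invariant modified k-means clustering of GFP-peak maps
#'
#' The classic microstate clustering: each peak map is assigned to the
#' template maximizing the squared spatial correlation (polarity ignored);
#' each template is then updated as the dominant spatial pattern (first
#' principal component) of its assigned peaks. Iterations stop when the GEV
#' improvement falls below `tol`. The best of `restarts` random
#' initializations (peaks sampled without replacement; all k-subsets
#' enumerated when there are fewer subsets than restarts) is returned.
#'
#' GEV here is the global explained variance on the peak set:
#' `sum((gfp_i * r_i)^2) / sum(gfp_i^2)` with `r_i` the spatial correlation
#' of peak i to its assigned template.
#'
#' @param peak_maps peaks x channels matrix (average-referenced internally).
#' @param k number of templates (<= number of peaks).
#' @param restarts number of random initializations.
#' @param seed integer seed or `NULL`.
#' @param max_iter iteration cap per restart.
#' @param tol convergence threshold on the GEV improvement.
#' @return An object of class `ms_clustering`: list with `k`, `templates`
#'   (k x channels, unit-norm rows), `assignment`, `corr` (signed correlation
#'   of each peak to its template), `gev`, `W` (within-cluster dispersion of
#'   the unit-normalized peaks), `W_gfp` (GFP-weighted dispersion), `n`,
#'   `restarts`, `iterations`.
#' @export
modified_kmeans <- function(peak_maps, k, restarts = 300, seed = NULL,
                            max_iter = 200, tol = 1e-6) {
  pm <- prep_maps(peak_maps)
  X <- pm$X; Xu <- pm$Xu; norms2 <- pm$norms2
  n <- nrow(X); C <- ncol(X)
  if (k > n) stop("k (", k, ") exceeds the number of peaks (", n, ")")
  denom <- sum(norms2)
  with_seed(seed, {
    if (k == 1L) {
      inits <- matrix(1L, 1, 1)   # init irrelevant for k = 1
    } else if (choose(n, k) <= restarts) {
      inits <- combn(n, k)
    } else {
      inits <- replicate(restarts, sample.int(n, k))
    }
    best <- NULL
    for (rs in seq_len(ncol(inits))) {
      Tm <- Xu[inits[, rs], , drop = FALSE]
      if (k == 1L) Tm <- matrix(dominant_pattern(crossprod(X)), 1, C)
      gev_prev <- -Inf
      lab <- integer(n)
      iter <- 0L
      repeat {
        iter <- iter + 1L
        corr <- tcrossprod(Xu, Tm)
        A <- corr * corr
        lab <- max.col(A, ties.method = "first")
        bf <- A[cbind(seq_len(n), lab)]
        empty <- setdiff(seq_len(k), unique(lab))
        for (j in empty) {             # re-seed from the worst-fit peak
          worst <- which.min(bf)
          lab[worst] <- j
          bf[worst] <- 1
        }
        gev <- sum(norms2 * A[cbind(seq_len(n), lab)]) / denom
        if (gev - gev_prev < tol || iter >= max_iter) break
        gev_prev <- gev
        for (j in seq_len(k)) {
          idx <- which(lab == j)
          Tm[j, ] <- if (length(idx) == 1L) Xu[idx, ]
                     else dominant_pattern(crossprod(X[idx, , drop = FALSE]))
        }
      }
      if (is.null(best) || gev > best$gev)
        best <- list(Tm = Tm, gev = gev, iterations = iter)
    }
    Tm <- best$Tm
    corr <- tcrossprod(Xu, Tm)
    A <- corr * corr
    lab <- max.col(A, ties.method = "first")
    r2 <- A[cbind(seq_len(n), lab)]
    structure(list(
      k = k, templates = Tm, assignment = lab,
      corr = corr[cbind(seq_len(n), lab)],
      gev = sum(norms2 * r2) / denom,
      W = sum(1 - r2),
      W_gfp = sum(norms2 * (1 - r2)),
      n = n, C = C, restarts = ncol(inits), iterations = best$iterations),
      class = "ms_clustering")
  })
}

#' @export
print.ms_clustering <- function(x, ...) {
  cat(sprintf("<ms_clustering> k = %d, n = %d peaks, GEV = %.3f (%d restarts)\n",
              x$k, x$n, x$gev, x$restarts))
  invisible(x)
}

#' Run modified k-means over a range of cluster numbers
#'
#' @param peak_maps peaks x channels matrix.
#' @param k_range contiguous integer range of candidate map counts.
#' @param restarts,seed,... passed to [modified_kmeans()].
#' @return List of `ms_clustering` runs (one per k) with the prepared peak
#'   matrix attached as attribute `"peaks"`.
#' @export
cluster_peaks <- function(peak_maps, k_range = 1:12, restarts = 300,
                          seed = NULL, ...) {
  k_range <- sort(unique(as.integer(k_range)))
  runs <- lapply(seq_along(k_range), function(i)
    modified_kmeans(peak_maps, k_range[i], restarts = restarts,
                    seed = child_seed(seed, i), ...))
  attr(runs, "peaks") <- as.matrix(peak_maps)
  class(runs) <- "ms_cluster_scan"
  runs
}

# Lower median: ties break towards the smaller k.
median_vote <- function(x) {
  x <- sort(as.integer(x))
  x[ceiling(length(x) / 2)]
}

sil_mean <- function(D, labs) {
  n <- nrow(D)
  ks <- sort(unique(labs))
  if (length(ks) < 2) return(NA_real_)
  sizes <- table(factor(labs, levels = ks))
  # mean distance of every point to every cluster
  M <- vapply(ks, function(j) rowSums(D[, labs == j, drop = FALSE]),
              numeric(n))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- match(labs[i], ks)
    n_own <- sizes[[own]]
    if (n_own <= 1) { s[i] <- 0; next }
    a <- M[i, own] / (n_own - 1)
    b <- min(M[i, -own] / as.numeric(sizes[-own]))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Choose the number of microstate maps by a multi-criterion median vote
#'
#' Computes five internal validity criteria on the clustering runs --
#' a cross-validation criterion (predictive residual variance),
#' Calinski-Harabasz, Krzanowski-Lai, mean silhouette on the polarity-
#' invariant correlation distance `1 - |r|`, and Davies-Bouldin -- takes each
#' criterion's optimal k and returns the median of the optima (ties resolved
#' towards the smaller k). When the peak set is degenerate (a single spatial
#' pattern), the smallest candidate k is returned.
#'
#' @param runs a list of `ms_clustering` runs for a contiguous k range, as
#'   produced by [cluster_peaks()].
#' @return list of class `ms_metacriterion` with elements `k` (the vote),
#'   `optima` (named per-criterion optimal k) and `criteria` (data.frame of
#'   raw criterion values per k, for audit).
#' @export
select_k_metacriterion <- function(runs) {
  if (length(runs) < 2) stop("need runs for at least 2 candidate k values")
  ks <- vapply(runs, function(r) r$k, integer(1))
  if (any(diff(ks) != 1L)) stop("k range must be contiguous")
  peaks <- attr(runs, "peaks")
  if (is.null(peaks)) stop("runs carry no peak matrix; use cluster_peaks()")
  pm <- prep_maps(peaks)
  n <- nrow(pm$X); C <- ncol(pm$X)
  lam1 <- eigen(crossprod(pm$Xu), symmetric = TRUE, only.values = TRUE)$values[1]
  W1 <- n - lam1
  if (W1 / n < 1e-9) {  # degenerate: one pattern explains everything
    return(structure(list(k = min(ks), optima = c(degenerate = min(ks)),
                          criteria = NULL), class = "ms_metacriterion"))
  }
  W <- vapply(runs, function(r) r$W, numeric(1))
  Wg <- vapply(runs, function(r) r$W_gfp, numeric(1))
  crit <- data.frame(k = ks, cv = NA_real_, ch = NA_real_, kl = NA_real_,
                     sil = NA_real_, db = NA_real_)
  # cross-validation criterion
  ok <- ks <= C - 2
  crit$cv[ok] <- (Wg[ok] / (n * (C - 1))) * ((C - 1) / (C - 1 - ks[ok]))^2
  # Calinski-Harabasz (needs dispersion at k = 1)
  Wfull <- W
  if (ks[1] > 1) {
    kk <- c(1L, ks); Wfull <- c(W1, W)
  } else kk <- ks
  i2 <- ks >= 2 & ks < n
  crit$ch[i2] <- ((W1 - W[i2]) / (ks[i2] - 1)) / (W[i2] / (n - ks[i2]))
  # Krzanowski-Lai on the k sequence including k = 1
  dif <- c(NA, (kk[-length(kk)])^(2 / C) * Wfull[-length(kk)] -
                (kk[-1])^(2 / C) * Wfull[-1])
  for (i in seq_along(kk)) {
    if (i > 1 && i < length(kk) && kk[i] >= 2 &&
        is.finite(dif[i]) && is.finite(dif[i + 1]) && abs(dif[i + 1]) > 1e-300) {
      val <- abs(dif[i]) / abs(dif[i + 1])
      j <- match(kk[i], ks)
      if (!is.na(j)) crit$kl[j] <- val
    }
  }
  # silhouette on a deterministic subsample
  idx <- if (n > 400) unique(round(seq(1, n, length.out = 400))) else seq_len(n)
  D <- 1 - abs(tcrossprod(pm$Xu[idx, , drop = FALSE]))
  for (i in seq_along(runs)) {
    if (ks[i] >= 2)
      crit$sil[i] <- sil_mean(D, runs[[i]]$assignment[idx])
  }
  # Davies-Bouldin with templates as centroids
  for (i in seq_along(runs)) {
    r <- runs[[i]]
    if (r$k < 2) next
    S <- vapply(seq_len(r$k), function(j) {
      m <- r$assignment == j
      if (!any(m)) NA_real_ else mean(1 - abs(r$corr[m]))
    }, numeric(1))
    Mt <- 1 - abs(tcrossprod(r$templates))
    ratio <- vapply(seq_len(r$k), function(j) {
      others <- setdiff(seq_len(r$k), j)
      max((S[j] + S[others]) / pmax(Mt[j, others], 1e-12), na.rm = TRUE)
    }, numeric(1))
    crit$db[i] <- mean(ratio, na.rm = TRUE)
  }
  optima <- c(
    cv  = if (any(is.finite(crit$cv)))  ks[which.min(crit$cv)]  else NA,
    ch  = if (any(is.finite(crit$ch)))  ks[which.max(crit$ch)]  else NA,
    kl  = if (any(is.finite(crit$kl)))  ks[which.max(crit$kl)]  else NA,
    sil = if (any(is.finite(crit$sil))) ks[which.max(crit$sil)] else NA,
    db  = if (any(is.finite(crit$db)))  ks[which.min(crit$db)]  else NA)
  optima <- optima[!is.na(optima)]
  structure(list(k = median_vote(optima), optima = optima, criteria = crit),
            class = "ms_metacriterion")
}

#' @export
print.ms_metacriterion <- function(x, ...) {
  cat("<ms_metacriterion> optimal k =", x$k, "\n")
  cat("  per-criterion optima:",
      paste(names(x$optima), x$optima, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Merge highly similar template maps
#'
#' Repeatedly merges the pair of maps with the highest absolute spatial
#' correlation at or above `threshold`, replacing them with the weighted
#' dominant pattern of the pair, until no pair remains above threshold.
#'
#' @param templates a [template_maps()] object or k x channels matrix.
#' @param threshold absolute-correlation merge threshold (default 0.80).
#' @param weights per-map weights (e.g. cluster sizes); default equal.
#' @return A [template_maps()] object; merge events are recorded in
#'   attribute `"merges"` as a data.frame with the merged pair's correlation.
#' @export
merge_maps <- function(templates, threshold = 0.80, weights = NULL) {
  Tm <- if (inherits(templates, "template_maps")) templates$maps
        else as.matrix(templates)
  Tm <- Tm - rowMeans(Tm)
  Tm <- Tm / sqrt(rowSums(Tm^2))
  w <- weights %||% rep(1, nrow(Tm))
  merges <- NULL
  while (nrow(Tm) >= 2) {
    Cm <- abs(tcrossprod(Tm))
    diag(Cm) <- 0
    mx <- which(Cm == max(Cm), arr.ind = TRUE)[1, ]
    if (Cm[mx[1], mx[2]] < threshold) break
    i <- min(mx); j <- max(mx)
    merged <- dominant_pattern(w[i] * tcrossprod(Tm[i, ]) +
                               w[j] * tcrossprod(Tm[j, ]))
    merges <- rbind(merges,
                    data.frame(map_i = i, map_j = j, corr = Cm[i, j]))
    keep <- setdiff(seq_len(nrow(Tm)), c(i, j))
    Tm <- rbind(Tm[keep, , drop = FALSE], merged)
    w <- c(w[keep], w[i] + w[j])
  }
  out <- template_maps(Tm)
  attr(out, "merges") <- merges
  out
}

#' Two-level (subject then group) microstate clustering
#'
#' Replicates the standard two-step procedure: modified k-means per subject
#' at that subject's GFP peaks (map count per subject by the meta-criterion,
#' or fixed via `subject_k` for speed), then a group-level modified k-means
#' on the pooled subject templates. Group maps correlated at
#' `merge_threshold` or higher are merged before output. The returned maps
#' are ordered by decreasing GEV contribution on the pooled peak set and
#' labeled A, B, C, ...
#'
#' @param recordings list of [eeg_recording()] objects (>= 2 subjects).
#' @param k_range candidate map counts for the meta-criterion.
#' @param restarts random restarts for group-level clustering.
#' @param merge_threshold absolute-correlation merge threshold.
#' @param subject_k fixed subject-level map count (`NULL` = per-subject
#'   meta-criterion).
#' @param subject_restarts restarts at the subject level.
#' @param group_k fixed group-level map count (`NULL` = meta-criterion).
#' @param seed integer seed or `NULL`.
#' @return A [template_maps()] object with `gev_total` computed on the
#'   concatenated GFP-peak maps of all subjects, and an `"audit"` attribute
#'   (per-subject chosen k, merge events, meta-criterion details).
#' @export
two_level_clustering <- function(recordings, k_range = 1:12, restarts = 300,
                                 merge_threshold = 0.80, subject_k = NULL,
                                 subject_restarts = restarts, group_k = NULL,
                                 seed = NULL) {
  if (length(recordings) < 2) stop("need at least 2 subjects")
  subj_templates <- list()
  subj_k <- integer(0)
  all_peaks <- list()
  for (i in seq_along(recordings)) {
    rec <- average_reference(recordings[[i]])
    pk <- gfp_peaks(gfp(rec))
    if (!length(pk)) {
      warning("subject ", rec$subject_id, " has no GFP peaks; skipped")
      next
    }
    P <- peak_maps(rec, pk)
    all_peaks[[length(all_peaks) + 1L]] <- P
    kr <- k_range[k_range <= nrow(P)]
    sseed <- child_seed(seed, i)
    if (!is.null(subject_k)) {
      run <- modified_kmeans(P, min(subject_k, nrow(P)),
                             restarts = subject_restarts, seed = sseed)
    } else {
      runs <- cluster_peaks(P, kr, restarts = subject_restarts, seed = sseed)
      sel <- select_k_metacriterion(runs)
      run <- runs[[match(sel$k, kr)]]
    }
    subj_templates[[length(subj_templates) + 1L]] <- run$templates
    subj_k <- c(subj_k, run$k)
  }
  if (!length(subj_templates)) stop("all subjects skipped: no GFP peaks found")
  pool <- do.call(rbind, subj_templates)
  gseed <- child_seed(seed, 0L)
  gsel <- NULL
  if (!is.null(group_k)) {
    grun <- modified_kmeans(pool, group_k, restarts = restarts, seed = gseed)
  } else {
    kr <- k_range[k_range <= nrow(pool)]
    gruns <- cluster_peaks(pool, kr, restarts = restarts, seed = gseed)
    gsel <- select_k_metacriterion(gruns)
    grun <- gruns[[match(gsel$k, kr)]]
  }
  sizes <- tabulate(grun$assignment, grun$k)
  merged <- merge_maps(grun$templates, threshold = merge_threshold,
                       weights = sizes)
  # GEV of the final maps on the concatenated peak set, per-map contributions
  X <- do.call(rbind, all_peaks)
  pm <- prep_maps(X)
  corr <- tcrossprod(pm$Xu, merged$maps)
  A <- corr * corr
  lab <- max.col(A, ties.method = "first")
  r2 <- A[cbind(seq_len(nrow(X)), lab)]
  contrib <- vapply(seq_len(nrow(merged$maps)), function(j)
    sum(pm$norms2[lab == j] * r2[lab == j]), numeric(1)) / sum(pm$norms2)
  ord <- order(contrib, decreasing = TRUE)
  out <- template_maps(merged$maps[ord, , drop = FALSE],
                       gev_total = sum(contrib))
  attr(out, "audit") <- list(subject_k = subj_k,
                             merges = attr(merged, "merges"),
                             group_selection = gsel,
                             gev_by_map = contrib[ord])
  out
}
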