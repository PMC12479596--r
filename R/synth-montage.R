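#' Deterministic electrode montage on a spherical scalp cap
#'
#' Places `n_channels` electrodes on the upper hemisphere of a unit sphere
#' using a Fibonacci spiral, giving an approximately uniform cap. The layout
#' is fully deterministic for a given channel count.
#'
#' @param n_channels number of electrodes (>= 8).
#' @return An object of class `eeg_montage`: a data.frame with columns
#'   `label`, `x`, `y`, `z` (z >= 0 for every electrode).
#' @examples
#' head(make_montage(32))
#' @export
make_montage <- function(n_channels = 64) {
  if (!is.numeric(n_channels) || length(n_channels) != 1L || n_channels < 8)
    stop("`n_channels` must be a single integer >= 8")
  n <- as.integer(n_channels)
  i <- seq_len(n)
  z <- (i - 0.5) / n                     # upper hemisphere only
  r <- sqrt(pmax(0, 1 - z^2))
  theta <- pi * (3 - sqrt(5)) * i        # golden angle
  out <- data.frame(label = sprintf("E%03d", i),
                    x = r * cos(theta), y = r * sin(theta), z = z,
                    stringsAsFactors = FALSE)
  class(out) <- c("eeg_montage", "data.frame")
  out
}

montage_positions <- function(montage) {
  as.matrix(montage[, c("x", "y", "z")])
}

# Canonical dipole axes used for the first four maps, mimicking the classic
# microstate orientations: A left-posterior/right-anterior, B the mirror
# image, C anterior-posterior, D a centro-frontal radial maximum.
canonical_axes <- function() {
  m <- rbind(A = c(0.7, 0.7, 0.15),
             B = c(-0.7, 0.7, 0.15),
             C = c(0, 1, 0.1),
             D = c(0, 0.25, 1))
  m / sqrt(rowSums(m^2))
}

dipole_field <- function(pos, loc, ori) {
  d <- sweep(pos, 2, loc)
  r3 <- (rowSums(d^2))^(3 / 2)
  as.numeric(d %*% ori) / pmax(r3, 1e-6)
}

#' Generate smooth dipolar template topographies
#'
#' Builds `n_maps` average-referenced, unit-norm scalp maps as potentials of
#' single current dipoles inside the head sphere. The first four maps use
#' jittered versions of the canonical microstate A-D orientations; further
#' maps use random orientations. Maps are regenerated (bounded retries) until
#' every pair has absolute spatial correlation below `max_abs_corr`
#' (default 0.7, comfortably under the 0.80 merge threshold), so template
#' similarity never triggers downstream merging by construction -- not even
#' after estimation noise nudges recovered maps slightly toward each other.
#'
#' @param n_maps number of maps, between 2 and 7.
#' @param montage an `eeg_montage` (see [make_montage()]).
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param max_tries retry budget per map before giving up.
#' @param max_abs_corr pairwise absolute-correlation bound (< 0.8).
#' @return A [template_maps()] object.
#' @examples
#' tm <- make_template_maps(4, make_montage(32), seed = 1)
#' @export
make_template_maps <- function(n_maps, montage, seed = NULL, max_tries = 200,
                               max_abs_corr = 0.7) {
  if (n_maps < 2 || n_maps > 7) stop("`n_maps` must be between 2 and 7")
  pos <- montage_positions(montage)
  base <- canonical_axes()
  with_seed(seed, {
    for (restart in seq_len(20)) {
      maps <- matrix(0, n_maps, nrow(pos))
      done <- TRUE
      for (m in seq_len(n_maps)) {
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          ori <- if (m <= 4) base[m, ] else rnorm(3)
          ori <- ori + rnorm(3, sd = 0.2)
          ori <- ori / sqrt(sum(ori^2))
          loc <- 0.3 * ori + c(0, 0, 0.1) + rnorm(3, sd = 0.05)
          v <- dipole_field(pos, loc, ori)
          v <- v - mean(v)
          nrm <- sqrt(sum(v^2))
          if (nrm < 1e-9) next
          v <- v / nrm
          if (m == 1L ||
              all(abs(maps[seq_len(m - 1), , drop = FALSE] %*% v) < max_abs_corr)) {
            if (v[which.max(abs(v))] < 0) v <- -v
            maps[m, ] <- v
            ok <- TRUE
            break
          }
        }
        if (!ok) {        # a bad early accept can strand later maps:
          done <- FALSE   # restart the whole set from fresh jitter
          break
        }
      }
      if (done) return(template_maps(maps))
    }
    stop("generation failure: could not draw ", n_maps,
         " maps with pairwise |r| < ", max_abs_corr, " within ",
         max_tries, " tries per map")
  })
}
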