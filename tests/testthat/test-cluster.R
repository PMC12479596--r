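test_that("spatial correlation is polarity-invariant and handles degenerate input", {
  u <- c(1, -1, 0.5, -0.5)
  expect_equal(spatial_correlation(u, u), 1)
  expect_equal(spatial_correlation(u, -u), 1)
  expect_equal(spatial_correlation(u, -u, ignore_polarity = FALSE), -1)
  maps <- orthogonal_maps(2, 6)
  expect_equal(spatial_correlation(maps[1, ], maps[2, ]), 0)
  expect_error(spatial_correlation(u, rep(2, 4)), "zero-variance")
  expect_error(spatial_correlation(u, c(1, 2)), "channel counts")
})

test_that("modified k-means recovers exact +/- copies of orthogonal maps with GEV 1", {
  M <- orthogonal_maps(3, 8)
  X <- rbind(M, -M) * c(1, 2, 3, 1.5, 2.5, 0.7)   # scaled +/- copies
  run <- modified_kmeans(X, 3, restarts = 30, seed = 1)
  expect_equal(run$gev, 1, tolerance = 1e-9)
  cc <- abs(tcrossprod(run$templates, M))
  expect_equal(sort(apply(cc, 1, max)), rep(1, 3), tolerance = 1e-9)
})

test_that("k = 1 returns the dominant eigenvector of the peak cross-product", {
  set.seed(5)
  X <- matrix(rnorm(60), 10, 6)
  run <- modified_kmeans(X, 1, restarts = 5, seed = 2)
  Xc <- X - rowMeans(X)
  ev <- eigen(crossprod(Xc), symmetric = TRUE)$vectors[, 1]
  expect_equal(abs(sum(run$templates[1, ] * ev / sqrt(sum(ev^2)))), 1,
               tolerance = 1e-9)
})

test_that("best-of-restarts GEV is non-decreasing in k", {
  set.seed(6)
  X <- matrix(rnorm(30 * 8), 30, 8)
  runs <- cluster_peaks(X, 1:5, restarts = 100, seed = 3)
  gev <- vapply(runs, function(r) r$gev, numeric(1))
  expect_true(all(diff(gev) > -1e-9))
})

test_that("clustering is invariant to global polarity flips and amplitude scaling", {
  set.seed(7)
  M <- orthogonal_maps(3, 8)
  X <- M[rep(1:3, each = 7), ] + 0.1 * matrix(rnorm(21 * 8), 21, 8)
  base <- modified_kmeans(X, 3, restarts = 20, seed = 4)
  flip <- modified_kmeans(X * rep(sample(c(-1, 1), 21, TRUE), 8), 3,
                          restarts = 20, seed = 4)
  scaled <- modified_kmeans(3 * X, 3, restarts = 20, seed = 4)
  expect_equal(flip$gev, base$gev, tolerance = 1e-9)
  expect_equal(scaled$gev, base$gev, tolerance = 1e-9)
  # same template set up to sign: matched correlations are exactly 1
  expect_equal(diag(abs(tcrossprod(scaled$templates, base$templates))),
               rep(1, 3), tolerance = 1e-6)
  expect_equal(diag(abs(tcrossprod(flip$templates, base$templates))),
               rep(1, 3), tolerance = 1e-6)
})

test_that("k-means attains the brute-force optimum on tiny instances", {
  set.seed(8)
  for (case in list(c(n = 6, k = 2), c(n = 7, k = 3), c(n = 8, k = 3))) {
    X <- matrix(rnorm(case["n"] * 6), case["n"], 6)
    oracle <- brute_force_gev(X, case["k"])
    run <- modified_kmeans(X, case["k"], restarts = 300, seed = 9)
    expect_equal(run$gev, oracle, tolerance = 1e-9,
                 info = paste(case, collapse = "/"))
  }
})

test_that("the meta-criterion median vote takes the lower median of the optima", {
  expect_equal(microstatr:::median_vote(c(3, 4, 4, 5, 6)), 4L)
  expect_equal(microstatr:::median_vote(c(3, 4, 5, 6)), 4L)   # tie -> smaller
  expect_equal(microstatr:::median_vote(c(2, 2, 7)), 2L)
})

test_that("degenerate single-pattern data selects the smallest k", {
  v <- orthogonal_maps(1, 10)
  X <- rbind(v, -v, 2 * v, -3 * v, v, 1.5 * v)
  runs <- cluster_peaks(X, 1:3, restarts = 10, seed = 10)
  expect_equal(select_k_metacriterion(runs)$k, 1L)
})

test_that("maps correlated at or above 0.80 are merged, below are kept", {
  M <- orthogonal_maps(2, 12)
  v1 <- M[1, ]
  mk <- function(r) {
    v <- r * v1 + sqrt(1 - r^2) * M[2, ]
    v / sqrt(sum(v^2))
  }
  merged <- merge_maps(rbind(v1, mk(0.9)), threshold = 0.80)
  expect_equal(nrow(merged$maps), 1)
  expect_equal(attr(merged, "merges")$corr, 0.9, tolerance = 1e-9)
  kept <- merge_maps(rbind(v1, mk(0.5)), threshold = 0.80)
  expect_equal(nrow(kept$maps), 2)
  expect_null(attr(kept, "merges"))
})

test_that("two-level clustering recovers shared maps across a small cohort", {
  s <- small_setup(n_channels = 24)
  coh <- simulate_cohort(3, s$truth, duration_s = 30, montage = s$montage,
                         seed = 12)
  gm <- two_level_clustering(coh$recordings, k_range = 1:6, restarts = 30,
                             subject_k = 4, seed = 13)
  expect_s3_class(gm, "template_maps")
  cc <- abs(tcrossprod(gm$maps, s$templates$maps))
  expect_true(all(apply(cc, 2, max) >= 0.95))
  expect_true(gm$gev_total > 0.5 && gm$gev_total <= 1)
  aud <- attr(gm, "audit")
  expect_equal(aud$subject_k, rep(4L, 6))
})
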