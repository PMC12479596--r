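test_that("summary-statistics t test behaves at its boundary cases", {
  eq <- student_t_summary(10, 2, 18, 10, 2, 18)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$effect, 0)
  expect_equal(eq$df, 34)
  expect_error(student_t_summary(1, 0, 18, 2, 1, 18), "positive")
  expect_error(student_t_summary(1, 1, 1, 2, 1, 18), "n >= 2")
})

test_that("Mann-Whitney U and Cliff's delta match the dominance-count oracle", {
  # non-overlapping samples saturate delta
  hi <- mann_whitney(11:15, 1:5)
  expect_equal(hi$effect, 1)
  expect_equal(mann_whitney(1:5, 11:15)$effect, -1)
  expect_equal(mann_whitney(c(1, 2, 3), c(2, 3, 1))$effect, 0)
  # brute-force pairwise dominance equals the U transform, ties included
  set.seed(4)
  for (rep in 1:20) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    x <- sample(1:8, n1, replace = TRUE)   # integer-valued -> plenty of ties
    y <- sample(1:8, n2, replace = TRUE)
    oracle <- (sum(outer(x, y, ">")) - sum(outer(x, y, "<"))) / (n1 * n2)
    expect_equal(mann_whitney(x, y)$effect, oracle, tolerance = 1e-12)
  }
  expect_error(mann_whitney(numeric(0), 1:3), "empty")
})

test_that("the U to delta conversion is linear with the documented orientation", {
  expect_equal(cliffs_delta_from_u(18 * 18 / 2, 18, 18), 0)
  expect_equal(cliffs_delta_from_u(0, 10, 10), -1)
  expect_equal(cliffs_delta_from_u(100, 10, 10), 1)
  expect_error(cliffs_delta_from_u(400, 18, 18), "out of range")
})

test_that("Li-Ji effective test count hits its closed forms", {
  # exactly uncorrelated variables (Helmert contrasts): M_eff = V
  X <- contr.helmert(8)          # 8 x 7, columns zero-sum and orthogonal
  m <- li_ji_meff(X)
  expect_equal(m$m_eff, 7, tolerance = 1e-9)
  expect_equal(sidak_alpha(0.05, m), 1 - 0.95^(1 / 7), tolerance = 1e-9)
  # a perfectly duplicated pair collapses to one effective test
  set.seed(5)
  v <- rnorm(10)
  expect_equal(li_ji_meff(cbind(v, v))$m_eff, 1, tolerance = 1e-9)
  expect_error(li_ji_meff(cbind(v, rep(1, 10))), "constant")
})

test_that("Sidak adjustment is anchored at m = 1 and strictly decreasing", {
  expect_equal(sidak_alpha(0.05, 1), 0.05)
  a <- vapply(seq(1, 12, by = 0.5), function(m) sidak_alpha(0.05, m),
              numeric(1))
  expect_true(all(diff(a) < 0))
  # m_eff stays within [1, V] for arbitrary data
  set.seed(6)
  for (rep in 1:10) {
    V <- sample(2:8, 1)
    X <- matrix(rnorm(12 * V), 12, V)
    m <- li_ji_meff(X)$m_eff
    expect_gte(m, 1); expect_lte(m, V + 1e-9)
  }
})

test_that("TANOVA returns p = 1 for identical groups and near-minimal p for disjoint ones", {
  set.seed(7)
  A <- matrix(rnorm(5 * 16), 5, 16)
  same <- tanova(A, A, n_perm = 200, seed = 1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  M <- orthogonal_maps(2, 16)
  Ga <- matrix(rep(M[1, ], 5), 5, byrow = TRUE) + 0.01 * matrix(rnorm(80), 5)
  Gb <- matrix(rep(M[2, ], 5), 5, byrow = TRUE) + 0.01 * matrix(rnorm(80), 5)
  far <- tanova(Ga, Gb, n_perm = 200, seed = 2)
  expect_lte(far$p, 2 / 201)
  expect_error(tanova(matrix(1, 3, 4), matrix(rnorm(12), 3, 4)), "zero-GFP")
})

test_that("Benjamini-Hochberg control matches the step-up enumeration", {
  expect_equal(bh_fdr(0.03)$p_adjusted, 0.03)
  res <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(res$rejected))
  expect_equal(res$p_adjusted, rep(0.04, 4))
  expect_false(any(bh_fdr(rep(1, 5))$rejected))
  expect_error(bh_fdr(c(0.2, 1.2)), "0, 1")
})

test_that("bootstrap correlation CIs behave on exact and seeded cases", {
  x <- 1:10
  perfect <- correlate_bootstrap(x, x, n_boot = 100, seed = 3)
  expect_equal(perfect$statistic, 1)
  expect_equal(perfect$ci[2], 1)
  # deterministic given the seed
  s <- correlate_bootstrap(x, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9),
                           method = "spearman", n_boot = 100, seed = 5)
  s2 <- correlate_bootstrap(x, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9),
                            method = "spearman", n_boot = 100, seed = 5)
  expect_identical(s$ci, s2$ci)
  expect_error(correlate_bootstrap(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(correlate_bootstrap(1:3, 1:3), "paired observations")
})
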