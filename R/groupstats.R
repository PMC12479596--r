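ms_test <- function(statistic, statistic_name, p, df = NULL, effect = NULL,
                    ci = NULL, method = statistic_name) {
  structure(list(statistic = statistic, statistic_name = statistic_name,
                 df = df, p = p, effect = effect, ci = ci, method = method),
            class = "ms_test")
}

#' @export
print.ms_test <- function(x, ...) {
  cat(sprintf("%s = %.4g%s, p = %.4g", x$statistic_name, x$statistic,
              if (!is.null(x$df)) sprintf(" (df = %g)", x$df) else "", x$p))
  if (!is.null(x$effect)) cat(sprintf(", effect = %.3f", x$effect))
  if (!is.null(x$ci)) cat(sprintf(", CI [%.3f, %.3f]", x$ci[1], x$ci[2]))
  cat("\n")
  invisible(x)
}

#' Pooled-variance two-sample t test from summary statistics
#'
#' Recomputes the pooled t statistic, two-sided p value and Cohen's d from
#' group means, SDs and sizes (df = n1 + n2 - 2), as used for demographic
#' tables that print only summary statistics.
#'
#' @param mean1,sd1,n1 first group's mean, SD and size.
#' @param mean2,sd2,n2 second group's mean, SD and size.
#' @return An `ms_test` with `statistic_name = "t"` and `effect` = Cohen's d
#'   (mean difference over pooled SD).
#' @examples
#' student_t_summary(19.78, 2.88, 18, 17.27, 1.996, 18)  # t ~ 3.04, d ~ 1.01
#' @export
student_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop("SDs must be positive")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  ms_test(t, "t", p = 2 * pt(-abs(t), df), df = df,
          effect = (mean1 - mean2) / sqrt(sp2),
          method = "pooled two-sample t (summary statistics)")
}

#' Mann-Whitney U test with Cliff's delta
#'
#' U is computed with midrank tie handling and oriented to the first sample
#' (`U = #\{x_i > y_j\} + ties / 2`). The p value comes from
#' [stats::wilcox.test()]: exact enumeration when `n1 * n2 <= 400` and there
#' are no ties, otherwise the normal approximation with continuity and tie
#' correction. Cliff's delta is the linear transform `2U / (n1 n2) - 1`.
#'
#' @param x,y numeric samples.
#' @param exact force exact (`TRUE`) or asymptotic (`FALSE`) p value;
#'   `NULL` chooses as above.
#' @param alternative passed to [stats::wilcox.test()].
#' @return An `ms_test` with `statistic_name = "U"` and `effect` = Cliff's
#'   delta.
#' @export
mann_whitney <- function(x, y, exact = NULL, alternative = "two.sided") {
  if (!length(x) || !length(y)) stop("empty sample")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (is.null(exact)) exact <- (n1 * n2 <= 400) && !ties
  p <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE,
                alternative = alternative)$p.value)
  ms_test(U, "U", p = p, effect = cliffs_delta_from_u(U, n1, n2),
          method = "Mann-Whitney U")
}

#' Cliff's delta from a Mann-Whitney U statistic
#'
#' `delta = 2U / (n1 * n2) - 1`, with U oriented to the first-listed group,
#' so delta = -1 when every x is below every y and +1 for the reverse.
#'
#' @param U the Mann-Whitney U statistic (0 <= U <= n1 * n2).
#' @param n1,n2 group sizes.
#' @return Cliff's delta in \[-1, 1\].
#' @examples
#' cliffs_delta_from_u(46, 18, 18)   # -0.716 -> prints as -0.72
#' @export
cliffs_delta_from_u <- function(U, n1, n2) {
  if (U < 0 || U > n1 * n2) stop("U out of range [0, n1*n2]")
  2 * U / (n1 * n2) - 1
}

#' Effective number of independent tests (Li & Ji)
#'
#' Estimates the effective number of independent tests from the eigenvalues
#' of the variables' correlation matrix:
#' `M_eff = sum over i of (I(|l_i| >= 1) + (|l_i| - floor(|l_i|)))`.
#'
#' @param variable_matrix subjects x variables numeric matrix (>= 3 subjects,
#'   >= 2 variables).
#' @return list of class `ms_meff` with `eigenvalues`, `m_eff`.
#' @seealso [sidak_alpha()]
#' @export
li_ji_meff <- function(variable_matrix) {
  X <- as.matrix(variable_matrix)
  if (ncol(X) < 2) stop("need at least 2 variables")
  if (nrow(X) < 3) stop("need at least 3 subjects")
  if (any(apply(X, 2, sd) < 1e-300))
    stop("undefined correlation: constant variable")
  lam <- eigen(cor(X), symmetric = TRUE, only.values = TRUE)$values
  a <- abs(lam)
  m_eff <- sum((a >= 1) + (a - floor(a)))
  structure(list(eigenvalues = lam, m_eff = m_eff), class = "ms_meff")
}

#' Sidak-adjusted per-test alpha
#'
#' `alpha_adj = 1 - (1 - alpha)^(1 / m_eff)`; with `m_eff = 1` the nominal
#' alpha is returned unchanged.
#'
#' @param alpha nominal family-wise alpha.
#' @param m_eff effective number of tests (an `ms_meff` or a positive
#'   scalar).
#' @return Adjusted per-test alpha in (0, alpha\].
#' @export
sidak_alpha <- function(alpha, m_eff) {
  if (inherits(m_eff, "ms_meff")) m_eff <- m_eff$m_eff
  if (m_eff < 1) stop("`m_eff` must be >= 1")
  1 - (1 - alpha)^(1 / m_eff)
}

# Normalize subject topographies to zero mean and unit GFP.
gfp_normalize_rows <- function(M) {
  M <- M - rowMeans(M)
  g <- sqrt(rowMeans(M^2))
  if (any(g < 1e-300)) stop("invalid input: zero-GFP map")
  M / g
}

#' Topographic analysis of variance (TANOVA)
#'
#' Nonparametric permutation test for a difference between two groups' mean
#' scalp topographies. Each subject map is scaled to unit GFP, group means
#' are formed and themselves GFP-normalized, and the statistic is the global
#' map dissimilarity `DISS = sqrt(mean over channels of squared difference)`.
#' The p value is the proportion of group-label permutations with a
#' dissimilarity at least as large as observed, counting the observed
#' statistic itself in numerator and denominator (so p is never 0).
#'
#' @param group_a_maps,group_b_maps subjects x channels matrices of
#'   topographies (>= 2 subjects each, equal channel counts).
#' @param n_perm number of permutations (default 5000).
#' @param seed integer seed or `NULL`.
#' @return An `ms_test` with `statistic_name = "diss"`.
#' @export
tanova <- function(group_a_maps, group_b_maps, n_perm = 5000, seed = NULL) {
  A <- as.matrix(group_a_maps); B <- as.matrix(group_b_maps)
  if (ncol(A) != ncol(B)) stop("channel counts differ")
  if (nrow(A) < 2 || nrow(B) < 2) stop("need >= 2 subjects per group")
  P <- gfp_normalize_rows(rbind(A, B))
  na <- nrow(A); nb <- nrow(B); n <- na + nb
  diss <- function(ia) {
    m1 <- colMeans(P[ia, , drop = FALSE])
    m2 <- colMeans(P[-ia, , drop = FALSE])
    m1 <- m1 - mean(m1); m2 <- m2 - mean(m2)
    g1 <- sqrt(mean(m1^2)); g2 <- sqrt(mean(m2^2))
    if (g1 < 1e-300 || g2 < 1e-300) stop("invalid input: zero-GFP mean map")
    sqrt(mean((m1 / g1 - m2 / g2)^2))
  }
  obs <- diss(seq_len(na))
  with_seed(seed, {
    perm <- vapply(seq_len(n_perm),
                   function(i) diss(sample.int(n, na)), numeric(1))
    p <- (1 + sum(perm >= obs)) / (n_perm + 1)
    ms_test(obs, "diss", p = p, method = "TANOVA (label permutation)")
  })
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up adjusted p values via [stats::p.adjust()] and the rejection set at
#' level `q`.
#'
#' @param p_values numeric vector of p values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return list with `p_adjusted` and logical `rejected`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  adj <- p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, rejected = !is.na(adj) & adj <= q)
}

#' Correlation with a bootstrap confidence interval
#'
#' Pearson or Spearman correlation with a percentile confidence interval
#' over `n_boot` paired resamples; the p value for the point estimate comes
#' from [stats::cor.test()].
#'
#' @param x,y paired numeric vectors (>= 4 observations).
#' @param method `"pearson"` or `"spearman"`.
#' @param n_boot number of bootstrap resamples (default 5000).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed or `NULL`.
#' @return An `ms_test` with `statistic_name` `"r"` or `"rho"` and `ci` the
#'   percentile interval.
#' @export
correlate_bootstrap <- function(x, y, method = c("pearson", "spearman"),
                                n_boot = 5000, conf = 0.95, seed = NULL) {
  method <- match.arg(method)
  n <- length(x)
  if (n < 4 || length(y) != n) stop("need >= 4 paired observations")
  if (sd(x) < 1e-300 || sd(y) < 1e-300)
    stop("undefined correlation: zero variance")
  est <- cor(x, y, method = method)
  p <- suppressWarnings(cor.test(x, y, method = method)$p.value)
  with_seed(seed, {
    boots <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      if (sd(x[idx]) < 1e-300 || sd(y[idx]) < 1e-300) return(NA_real_)
      cor(x[idx], y[idx], method = method)
    }, numeric(1))
    ci <- unname(quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          na.rm = TRUE))
    ms_test(est, if (method == "pearson") "r" else "rho", p = p, ci = ci,
            method = paste0(method, " correlation, bootstrap CI"))
  })
}
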