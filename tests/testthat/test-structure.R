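implied_R <- function() {
  R <- tcrossprod(default_loadings())
  diag(R) <- 1
  R
}

test_that("correlation matrix is symmetric with unit diagonal and validates input", {
  set.seed(60)
  m <- matrix(rnorm(200), 50, 4)
  R <- correlation_matrix(m)
  expect_equal(diag(R), rep(1, 4))
  expect_equal(R, t(R))
  m2 <- cbind(m, flat = 1)
  expect_error(correlation_matrix(m2), "flat")
  x <- rnorm(20)
  expect_equal(correlation_matrix(cbind(x, -x))[1, 2], -1)
})

test_that("dendrogram merges the most correlated subtests first", {
  # brute force: the maximum implied off-diagonal is the first merge
  R <- implied_R()
  off <- R; diag(off) <- NA
  top_pair <- rownames(R)[which(off == max(off, na.rm = TRUE), arr.ind = TRUE)[1, ]]
  hc <- subtest_dendrogram(R)
  first <- hc$labels[-hc$merge[1, ]]
  expect_setequal(first, top_pair)
  expect_setequal(first, c("fwd_span", "rev_span"))
  # heights are the documented transform of correlation
  expect_equal(min(hc$height), sqrt(2 * (1 - max(off, na.rm = TRUE))))
})

test_that("dendrogram recovers the documented high-correlation groupings", {
  # the three tight pairs form the first three merges under every linkage;
  # Grammatical Reasoning attaches only loosely to the reasoning pair
  # because zeroing the sub-display loadings leaves its implied
  # correlation with Digit Symbol Coding at 0.30, and Progressive
  # Matrices, which correlates strongly with nothing, joins last
  hc <- subtest_dendrogram(implied_R())
  first3 <- lapply(1:3, function(i) hc$labels[-hc$merge[i, ]])
  expect_setequal(first3[[1]], c("fwd_span", "rev_span"))
  expect_setequal(first3[[2]], c("digit_symbol", "arithmetic"))
  expect_setequal(first3[[3]], c("trail_a_s", "trail_b_s"))
  expect_equal(hc$labels[-hc$merge[7, ][hc$merge[7, ] < 0]], "matrices")
  # identical subtests (r = 1) are at distance 0 and merged first
  R2 <- matrix(c(1, 1, 0.2, 1, 1, 0.2, 0.2, 0.2, 1), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  hc2 <- subtest_dendrogram(R2)
  expect_equal(hc2$height[1], 0)
  expect_setequal(hc2$labels[-hc2$merge[1, ]], c("a", "b"))
  expect_error(subtest_dendrogram(matrix(c(1, 0.5, 0.2, 1), 2)), "symmetric")
})

test_that("newick export is well formed and carries all labels", {
  hc <- subtest_dendrogram(implied_R())
  nwk <- dendrogram_newick(hc)
  expect_match(nwk, ";$")
  expect_equal(lengths(regmatches(nwk, gregexpr("\\(", nwk))),
               lengths(regmatches(nwk, gregexpr("\\)", nwk))))
  for (lab in rownames(implied_R())) expect_match(nwk, lab, fixed = TRUE)
})

test_that("parallel analysis retains one factor for one-factor data and none for noise", {
  set.seed(61)
  L1 <- matrix(0.8, 8, 1)
  z <- matrix(rnorm(2000), ncol = 1) %*% t(L1) +
    matrix(rnorm(2000 * 8), ncol = 8) * sqrt(1 - 0.64)
  pa <- parallel_analysis(z, n_iter = 300, seed = 62)
  expect_equal(pa$n_factors_retained, 1L)
  retained_null <- vapply(1:5, function(s) {
    set.seed(s)
    x <- matrix(rnorm(2000 * 8), ncol = 8)
    parallel_analysis(x, n_iter = 300, seed = s + 50)$n_factors_retained
  }, 1L)
  expect_gte(sum(retained_null == 0L), 4)
})

test_that("parallel analysis is seed-reproducible and warns on few iterations", {
  set.seed(63)
  x <- matrix(rnorm(500 * 5), ncol = 5)
  a <- parallel_analysis(x, n_iter = 150, seed = 4)
  b <- parallel_analysis(x, n_iter = 150, seed = 4)
  expect_identical(a, b)
  expect_warning(parallel_analysis(x, n_iter = 50, seed = 4), "noisy")
  expect_error(parallel_analysis(x[1:4, ]), "more subjects")
})

test_that("observed eigenvalues match a direct reduced-matrix computation", {
  set.seed(64)
  x <- matrix(rnorm(1000 * 4), ncol = 4)
  pa <- parallel_analysis(x, n_iter = 150, seed = 5, reduction = "smc")
  R <- cor(x)
  h2 <- 1 - 1 / diag(solve(R))
  Rr <- R; diag(Rr) <- h2
  expect_equal(pa$observed_eigenvalues,
               sort(eigen(Rr)$values, decreasing = TRUE), tolerance = 1e-10)
})

test_that("ML factor model reports the standard df and flags Heywood cases", {
  X <- factor_cohort_scores()
  fs <- fit_ml_factor_model(X[1:2000, ], factors = 4)
  expect_equal(fs$df, 2)           # ((8-4)^2 - (8+4)) / 2
  expect_error(fit_ml_factor_model(X[1:2000, 1:4], factors = 3), "degrees of freedom")
  set.seed(65)
  f <- rnorm(800)
  x <- cbind(f + rnorm(800, sd = 0.02), f + rnorm(800, sd = 0.02),
             f + rnorm(800, sd = 1))
  hw <- fit_ml_factor_model(x, factors = 1)
  expect_true(hw$heywood)
})

test_that("varimax rotation preserves communalities and is orthogonal", {
  X <- factor_cohort_scores()
  fs <- fit_ml_factor_model(X[1:5000, ], factors = 4)
  un <- fit_ml_factor_model(X[1:5000, ], factors = 4, rotation = "none")
  expect_equal(unname(rowSums(fs$loadings^2)),
               unname(rowSums(un$loadings^2)), tolerance = 1e-8)
  expect_equal(unname(crossprod(fs$rotmat)), diag(4), tolerance = 1e-8)
})

test_that("large-sample rotated loadings recover the population varimax solution", {
  R <- implied_R()
  pop <- fit_ml_factor_model(R, factors = 4, n_obs = 50000)
  set.seed(66)
  L <- default_loadings()
  psi <- derive_uniquenesses(L)
  z <- matrix(rnorm(50000 * 4), ncol = 4) %*% t(L) +
    matrix(rnorm(50000 * 8), ncol = 8) %*% diag(sqrt(psi))
  colnames(z) <- rownames(L)
  fs <- fit_ml_factor_model(z, factors = 4)
  aligned <- align_loadings(fs$loadings, pop$loadings)
  expect_lt(max(abs(aligned - pop$loadings)), 0.05)
})

test_that("chi-square matches the Bartlett-corrected ML discrepancy", {
  set.seed(67)
  L <- default_loadings()
  psi <- derive_uniquenesses(L)
  z <- matrix(rnorm(3000 * 4), ncol = 4) %*% t(L) +
    matrix(rnorm(3000 * 8), ncol = 8) %*% diag(sqrt(psi))
  fs <- fit_ml_factor_model(z, factors = 4)
  ref <- factanal(covmat = cor(z), factors = 4, n.obs = 3000)
  expect_equal(fs$chisq, unname(ref$STATISTIC), tolerance = 1e-8)
  expect_equal(fs$p_value, unname(ref$PVAL), tolerance = 1e-8)
})

test_that("rmsea follows its closed form and interval inverts the noncentral chi-square", {
  r <- rmsea(19.01, 2, 130140)
  expect_equal(r$rmsea, sqrt((19.01 - 2) / (2 * 130139)), tolerance = 1e-12)
  expect_equal(round(r$rmsea, 4), 0.0081)
  expect_equal(round(r$ci_low, 3), 0.004)
  expect_equal(round(r$ci_high, 3), 0.012)
  # interval endpoints put the statistic at the right tail probabilities
  lam_hi <- r$ci_high^2 * 2 * 130139
  expect_equal(pchisq(19.01, 2, ncp = lam_hi), 0.025, tolerance = 1e-6)
  # whenever chisq <= df the point estimate is zero
  expect_equal(rmsea(1.5, 2, 1000)$rmsea, 0)
  expect_equal(rmsea(1.5, 2, 1000)$ci_low, 0)
})

test_that("loading variance proportions match hand arithmetic", {
  lv <- loading_variance(default_loadings())
  expect_equal(round(lv$proportion[["F1"]], 3), 0.156)
  expect_equal(round(lv$proportion[["F2"]], 3), 0.146)
  expect_equal(lv$cumulative[[4]], sum(lv$proportion))
  expect_lte(lv$cumulative[[4]], 1)
  expect_equal(loading_variance(matrix(0, 8, 1))$proportion, 0)
  expect_equal(loading_variance(matrix(c(1, rep(0, 7)), 8, 1))$proportion, 0.125)
})

test_that("simple-structure screen applies the documented boundary semantics", {
  rows <- rbind(
    arithmetic = c(0.754, 0.154, 0.211, 0),    # pass
    matrices   = c(0.219, 0.217, 0, 0.211),    # fail: weak primary
    boundary   = c(0.4, 0.3, 0, 0),            # fail: cross-loading not < 0.3
    edge_ok    = c(0.4, 0.299, 0, 0)           # pass at both boundaries
  )
  flags <- simple_structure_screen(rows)
  expect_equal(flags$passes, c(TRUE, FALSE, FALSE, TRUE))
  # negative loadings are screened by magnitude
  expect_true(simple_structure_screen(rbind(c(-0.6, 0.1, 0, 0)))$passes)
})
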