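#' Pearson correlation matrix of subtest scores
#'
#' @param scores Numeric matrix or data frame, subjects in rows and
#'   subtests in columns (at least 4 rows; every column must vary).
#' @return Symmetric correlation matrix with unit diagonal.
#' @examples
#' m <- matrix(rnorm(40), 10, 4)
#' correlation_matrix(m)
#' @export
correlation_matrix <- function(scores) {
  scores <- as.matrix(scores)
  if (!is.numeric(scores)) stop("scores must be numeric", call. = FALSE)
  if (nrow(scores) < 4) stop("at least 4 subjects are required", call. = FALSE)
  sds <- apply(scores, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(scores)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("degenerate variance in: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  stats::cor(scores)
}

#' Agglomerative dendrogram of subtests from their correlations
#'
#' Converts correlations to the Euclidean distance between unit-norm
#' standardized variables, `d = sqrt(2 * (1 - r))`, and clusters
#' agglomeratively: every subtest starts in its own cluster and at each
#' step the two most similar clusters are joined until one remains.
#'
#' @param corr Symmetric correlation matrix.
#' @param linkage Between-cluster linkage: `"average"` (default),
#'   `"single"` or `"complete"`.
#' @return An [stats::hclust] tree (merge order and heights).
#' @examples
#' R <- tcrossprod(default_loadings()); diag(R) <- 1
#' hc <- subtest_dendrogram(R)
#' hc$labels[hc$merge[1, ]* -1]  # first pair merged
#' @export
subtest_dendrogram <- function(corr, linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  corr <- as.matrix(corr)
  if (!isSymmetric(unname(corr), tol = 1e-8))
    stop("correlation matrix must be symmetric", call. = FALSE)
  d <- sqrt(pmax(2 * (1 - corr), 0))
  stats::hclust(stats::as.dist(d), method = linkage)
}

#' Export a dendrogram as a Newick string
#'
#' @param hc An [stats::hclust] tree.
#' @param digits Decimal places for branch lengths.
#' @return A single Newick-format string (heights as node depths).
#' @export
dendrogram_newick <- function(hc, digits = 4) {
  labs <- if (is.null(hc$labels)) as.character(seq_along(hc$order)) else hc$labels
  build <- function(i, parent_h) {
    if (i < 0) {
      sprintf("%s:%s", labs[-i], format(round(parent_h, digits)))
    } else {
      h <- hc$height[i]
      sprintf("(%s,%s):%s",
              build(hc$merge[i, 1], h), build(hc$merge[i, 2], h),
              format(round(parent_h - h, digits)))
    }
  }
  n <- nrow(hc$merge)
  h <- hc$height[n]
  paste0("(", build(hc$merge[n, 1], h), ",", build(hc$merge[n, 2], h), ");")
}

# squared multiple correlations
smc <- function(R) {
  Ri <- tryCatch(solve(R), error = function(e) solve(R + diag(1e-8, nrow(R))))
  1 - 1 / diag(Ri)
}

# factor-solution eigenvalues of the reduced correlation matrix. The
# default replaces the diagonal with communalities from a single-factor
# maximum-likelihood fit (the convention of the field's standard parallel
# analysis implementation); "smc" uses squared multiple correlations.
fa_eigenvalues <- function(R, reduction = "fa1") {
  h2 <- if (reduction == "fa1") {
    psi <- tryCatch(
      stats::factanal(covmat = R, factors = 1)$uniquenesses,
      error = function(e) NULL)
    if (is.null(psi)) smc(R) else 1 - psi
  } else {
    smc(R)
  }
  Rr <- R
  diag(Rr) <- h2
  sort(eigen(Rr, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

#' Parallel analysis for factor retention
#'
#' Compares the factor-solution eigenvalues of the observed data (the
#' eigenvalues of the reduced correlation matrix, whose diagonal holds
#' communalities from a single-factor maximum-likelihood fit by default,
#' or squared multiple correlations with `reduction = "smc"`) against the
#' position-wise reference eigenvalues obtained from `n_iter` independent
#' standard-normal data matrices of the same shape, reduced the same way.
#' Factors are retained from the top for as long as the observed
#' eigenvalue exceeds the reference (95th percentile by default; the mean
#' is also available).
#'
#' @param scores Subject-by-variable numeric matrix or data frame (more
#'   subjects than variables).
#' @param n_iter Number of random reference matrices (default 10000).
#' @param criterion `"quantile95"` (default) or `"mean"`.
#' @param reduction Diagonal used for the reduced correlation matrix:
#'   `"fa1"` (default) or `"smc"`.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `parallel_result`: list with
#'   `observed_eigenvalues`, `reference_mean`, `reference_q95`,
#'   `criterion`, `n_factors_retained`.
#' @examples
#' set.seed(5)
#' x <- matrix(rnorm(500 * 6), 500, 6)
#' parallel_analysis(x, n_iter = 200, seed = 1)$n_factors_retained
#' @export
parallel_analysis <- function(scores, n_iter = 10000,
                              criterion = c("quantile95", "mean"),
                              reduction = c("fa1", "smc"),
                              seed = NULL) {
  criterion <- match.arg(criterion)
  reduction <- match.arg(reduction)
  scores <- as.matrix(scores)
  if (!is.numeric(scores)) stop("scores must be numeric", call. = FALSE)
  n <- nrow(scores); p <- ncol(scores)
  if (n <= p) stop("more subjects than variables are required", call. = FALSE)
  if (n_iter < 100)
    warning("fewer than 100 reference matrices; the criterion will be noisy",
            call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  obs <- fa_eigenvalues(correlation_matrix(scores), reduction)
  ref <- matrix(NA_real_, n_iter, p)
  for (i in seq_len(n_iter)) {
    x <- matrix(stats::rnorm(n * p), n, p)
    ref[i, ] <- fa_eigenvalues(stats::cor(x), reduction)
  }
  ref_mean <- colMeans(ref)
  ref_q95 <- apply(ref, 2, stats::quantile, probs = 0.95, names = FALSE)
  thr <- if (criterion == "mean") ref_mean else ref_q95
  above <- obs > thr
  retained <- if (above[1]) which.min(c(above, FALSE)) - 1L else 0L
  structure(list(observed_eigenvalues = obs, reference_mean = ref_mean,
                 reference_q95 = ref_q95, criterion = criterion,
                 n_iter = n_iter, n_factors_retained = retained),
            class = "parallel_result")
}

#' @export
print.parallel_result <- function(x, ...) {
  cat("Parallel analysis (", x$n_iter, " reference matrices, criterion: ",
      x$criterion, ")\n", sep = "")
  print(data.frame(observed = round(x$observed_eigenvalues, 4),
                   ref_mean = round(x$reference_mean, 4),
                   ref_q95 = round(x$reference_q95, 4)))
  cat("factors retained:", x$n_factors_retained, "\n")
  invisible(x)
}

#' RMSEA with confidence interval from a factor-model chi-square
#'
#' Root mean square error of approximation:
#' `sqrt(max(chisq - df, 0) / (df * (n - 1)))`. The confidence interval
#' inverts the noncentral chi-square distribution: the bounds are the
#' noncentrality parameters at which the observed statistic sits at the
#' upper and lower tail probabilities.
#'
#' @param chisq Model chi-square statistic.
#' @param df Model degrees of freedom.
#' @param n Sample size.
#' @param level Confidence level (default 0.95).
#' @return List with `rmsea`, `ci_low`, `ci_high`.
#' @examples
#' rmsea(19.01, 2, 130140)
#' @export
rmsea <- function(chisq, df, n, level = 0.95) {
  if (df <= 0) stop("df must be positive", call. = FALSE)
  point <- sqrt(max(chisq - df, 0) / (df * (n - 1)))
  alpha <- (1 - level) / 2
  ncp_at <- function(target) {
    # ncp at which the observed statistic sits at cumulative prob `target`
    f <- function(l) stats::pchisq(chisq, df, ncp = l) - target
    if (f(0) <= 0) return(0)
    upper <- max(chisq * 2, 10)
    while (f(upper) > 0 && upper < 1e7) upper <- upper * 2
    stats::uniroot(f, c(0, upper), tol = 1e-10)$root
  }
  # lower bound: ncp with pchisq(chisq, df, ncp) = 1 - alpha
  lam_lo <- if (stats::pchisq(chisq, df) < 1 - alpha) 0 else ncp_at(1 - alpha)
  lam_hi <- if (stats::pchisq(chisq, df) < alpha) 0 else ncp_at(alpha)
  list(rmsea = point,
       ci_low = sqrt(lam_lo / (df * (n - 1))),
       ci_high = sqrt(lam_hi / (df * (n - 1))))
}

#' Proportion of total variance per factor
#'
#' For standardized variables, the proportion of total variance captured
#' by each factor is the column sum of squared loadings divided by the
#' number of variables.
#'
#' @param loadings Loading matrix (variables in rows).
#' @return List with `proportion` (per factor) and `cumulative`.
#' @examples
#' loading_variance(default_loadings())
#' @export
loading_variance <- function(loadings) {
  loadings <- as.matrix(loadings)
  prop <- colSums(loadings^2) / nrow(loadings)
  list(proportion = prop, cumulative = cumsum(prop))
}

#' Simple-structure screen of rotated loadings
#'
#' A variable passes if its primary (largest absolute) loading is at least
#' `primary` and its largest cross-loading (second-largest absolute
#' loading) is strictly below `cross`.
#'
#' @param loadings Rotated loading matrix (variables in rows).
#' @param primary Primary-loading threshold (default 0.4, inclusive).
#' @param cross Cross-loading threshold (default 0.3, exclusive).
#' @return Data frame with `primary_loading`, `max_cross_loading` and
#'   logical `passes` per variable.
#' @examples
#' simple_structure_screen(default_loadings())
#' @export
simple_structure_screen <- function(loadings, primary = 0.4, cross = 0.3) {
  loadings <- abs(as.matrix(loadings))
  prim <- apply(loadings, 1, max)
  second <- apply(loadings, 1, function(v) sort(v, decreasing = TRUE)[2])
  data.frame(primary_loading = prim, max_cross_loading = second,
             passes = prim >= primary & second < cross,
             row.names = rownames(loadings))
}

#' Maximum-likelihood factor analysis with varimax rotation
#'
#' Extracts `factors` common factors from the correlation matrix by
#' maximum likelihood and rotates with varimax (Kaiser row
#' normalization). The model chi-square carries the Bartlett correction
#' `(n - 1 - (2p + 5)/6 - 2k/3) * discrepancy`, with
#' `df = ((p - k)^2 - (p + k)) / 2`; fit is summarized by the p-value and
#' by RMSEA with its confidence interval. Each variable is screened for
#' simple structure (primary loading >= 0.4, all cross-loadings < 0.3).
#'
#' @param x Either a subject-by-variable score matrix/data frame, or a
#'   correlation matrix (then `n_obs` is required).
#' @param factors Number of factors to extract; `df` must be
#'   non-negative.
#' @param n_obs Sample size when `x` is a correlation matrix.
#' @param rotation `"varimax"` (default) or `"none"`.
#' @param psi_lower Lower bound for uniquenesses during optimization;
#'   solutions on this bound are flagged as Heywood cases.
#' @return An object of class `factor_solution`: loadings, uniquenesses,
#'   rotation matrix, per-factor proportions of variance, `chisq`, `df`,
#'   `p_value`, `rmsea` (with CI), `heywood` flag and
#'   `simple_structure` screen.
#' @examples
#' set.seed(6)
#' z <- matrix(rnorm(2000 * 2), 2000, 2)
#' x <- cbind(z[, 1] + rnorm(2000, sd = .6), z[, 1] + rnorm(2000, sd = .6),
#'            z[, 2] + rnorm(2000, sd = .6), z[, 2] + rnorm(2000, sd = .6),
#'            z[, 2] + rnorm(2000, sd = .6))
#' fit_ml_factor_model(x, factors = 2)
#' @export
fit_ml_factor_model <- function(x, factors, n_obs = NULL,
                                rotation = c("varimax", "none"),
                                psi_lower = 0.005) {
  rotation <- match.arg(rotation)
  x <- as.matrix(x)
  is_corr <- nrow(x) == ncol(x) &&
    isSymmetric(unname(x), tol = 1e-8) && all(abs(diag(x) - 1) < 1e-8)
  if (is_corr) {
    if (is.null(n_obs))
      stop("n_obs is required when a correlation matrix is supplied",
           call. = FALSE)
    R <- x
    n <- n_obs
  } else {
    R <- correlation_matrix(x)
    n <- nrow(x)
  }
  p <- ncol(R)
  df <- ((p - factors)^2 - (p + factors)) / 2
  if (df < 0)
    stop("negative degrees of freedom for ", factors, " factors on ",
         p, " variables", call. = FALSE)
  fa <- stats::factanal(covmat = R, factors = factors, n.obs = n,
                        rotation = "none",
                        control = list(lower = psi_lower))
  L <- unclass(fa$loadings)
  rot <- diag(factors)
  if (rotation == "varimax" && factors > 1) {
    v <- stats::varimax(L, normalize = TRUE)
    L <- unclass(v$loadings)
    rot <- v$rotmat
    # order factors by explained variance, sign-align to positive sums
    ord <- order(colSums(L^2), decreasing = TRUE)
    L <- L[, ord, drop = FALSE]
    rot <- rot[, ord, drop = FALSE]
    sgn <- ifelse(colSums(L) < 0, -1, 1)
    L <- sweep(L, 2, sgn, `*`)
    rot <- sweep(rot, 2, sgn, `*`)
    colnames(L) <- paste0("F", seq_len(factors))
  }
  psi <- fa$uniquenesses
  heywood <- any(psi <= psi_lower + 1e-8)
  chisq <- if (df > 0) unname(fa$STATISTIC) else NA_real_
  pval <- if (df > 0) unname(fa$PVAL) else NA_real_
  rms <- if (df > 0) rmsea(chisq, df, n) else
    list(rmsea = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
  lv <- loading_variance(L)
  structure(list(
    loadings = L, uniquenesses = psi, rotmat = rot,
    proportion_variance = lv$proportion, cumulative_variance = lv$cumulative,
    chisq = chisq, df = df, p_value = pval, rmsea = rms,
    heywood = heywood, simple_structure = simple_structure_screen(L),
    n_obs = n, factors = factors, rotation = rotation
  ), class = "factor_solution")
}

#' @export
print.factor_solution <- function(x, digits = 3, ...) {
  cat("Maximum-likelihood factor solution (", x$factors, " factors, ",
      x$rotation, " rotation, n = ", x$n_obs, ")\n", sep = "")
  print(round(x$loadings, digits))
  cat("Proportion of total variance:",
      paste(round(x$proportion_variance, digits), collapse = " "), "\n")
  if (!is.na(x$chisq))
    cat(sprintf("chi-square(%g) = %.2f, p = %.3g; RMSEA = %.4f [%.4f, %.4f]\n",
                x$df, x$chisq, x$p_value, x$rmsea$rmsea, x$rmsea$ci_low,
                x$rmsea$ci_high))
  if (x$heywood) cat("note: Heywood case (uniqueness at lower bound)\n")
  invisible(x)
}
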