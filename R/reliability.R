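#' Pearson correlation with Fisher-transform confidence interval
#'
#' Computes the product-moment correlation of paired scores and an
#' analytic confidence interval on the Fisher z scale:
#' `tanh(atanh(r) +/- z_crit / sqrt(n - 3))`.
#'
#' @param x,y Numeric vectors of paired scores (at least 4 complete
#'   pairs, each with nonzero variance).
#' @param level Confidence level (default 0.95).
#' @return An object of class `reliability_estimate`: list with `r`,
#'   `fisher_z`, `ci_low`, `ci_high`, `level`, `n_pairs`.
#' @examples
#' set.seed(1)
#' x <- rnorm(100); y <- 0.8 * x + rnorm(100, sd = 0.6)
#' pearson_fisher_ci(x, y)
#' @export
pearson_fisher_ci <- function(x, y, level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("at least 4 complete pairs are required", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: one coordinate has zero variance", call. = FALSE)
  r <- stats::cor(x, y)
  zc <- stats::qnorm(1 - (1 - level) / 2)
  if (abs(r) < 1) {
    fz <- atanh(r)
    ci <- tanh(fz + c(-1, 1) * zc / sqrt(n - 3))
  } else {
    fz <- sign(r) * Inf
    ci <- c(r, r)
  }
  structure(list(r = r, fisher_z = fz, ci_low = ci[1], ci_high = ci[2],
                 level = level, n_pairs = n),
            class = "reliability_estimate")
}

#' @export
print.reliability_estimate <- function(x, ...) {
  cat(sprintf("r = %.3f (%d pairs), %g%% CI [%.3f, %.3f]\n",
              x$r, x$n_pairs, 100 * x$level, x$ci_low, x$ci_high))
  if (!is.null(x$boot_median))
    cat(sprintf("bootstrap: median %.3f, CI [%.3f, %.3f], IQR %.4f (%d iter)\n",
                x$boot_median, x$boot_ci[1], x$boot_ci[2], x$boot_iqr,
                x$n_iter))
  invisible(x)
}

#' Nonparametric bootstrap of a test-retest correlation
#'
#' Resamples whole pairs with replacement `n_iter` times, recomputes the
#' Pearson correlation for each resample, and summarizes the bootstrap
#' distribution by its median, inter-quartile range, and percentile
#' confidence interval (the 2.5 and 97.5 percent points at the default
#' level). Degenerate resamples in which either coordinate is constant are
#' dropped and counted.
#'
#' @inheritParams pearson_fisher_ci
#' @param n_iter Number of bootstrap resamples (default 10000).
#' @param seed Optional integer seed; the same seed reproduces the
#'   summaries exactly.
#' @return List with `boot_median`, `boot_iqr`, `boot_ci` (length 2),
#'   `n_iter`, `n_dropped`.
#' @examples
#' set.seed(2)
#' x <- rnorm(60); y <- 0.7 * x + rnorm(60, sd = 0.7)
#' bootstrap_reliability(x, y, n_iter = 500, seed = 9)
#' @export
bootstrap_reliability <- function(x, y, n_iter = 10000, seed = NULL,
                                  level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("at least 4 complete pairs are required", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rs <- numeric(n_iter)
  dropped <- 0L
  for (i in seq_len(n_iter)) {
    idx <- sample.int(n, n, replace = TRUE)
    xb <- x[idx]; yb <- y[idx]
    if (stats::sd(xb) == 0 || stats::sd(yb) == 0) {
      rs[i] <- NA_real_
      dropped <- dropped + 1L
    } else {
      rs[i] <- stats::cor(xb, yb)
    }
  }
  rs <- rs[!is.na(rs)]
  alpha <- (1 - level) / 2
  list(boot_median = stats::median(rs),
       boot_iqr = unname(diff(stats::quantile(rs, c(0.25, 0.75)))),
       boot_ci = unname(stats::quantile(rs, c(alpha, 1 - alpha))),
       n_iter = n_iter, n_dropped = dropped)
}

#' Full reliability estimate (analytic + bootstrap)
#'
#' Convenience wrapper combining [pearson_fisher_ci()] and
#' [bootstrap_reliability()] into one `reliability_estimate`.
#'
#' @inheritParams bootstrap_reliability
#' @return A `reliability_estimate` with both analytic and bootstrap
#'   fields.
#' @export
reliability_estimate <- function(x, y, level = 0.95, n_iter = 10000,
                                 seed = NULL) {
  est <- pearson_fisher_ci(x, y, level = level)
  boot <- bootstrap_reliability(x, y, n_iter = n_iter, seed = seed,
                                level = level)
  est[names(boot)] <- boot
  est
}

#' Fisher r-to-z comparison of two independent correlations
#'
#' Tests equality of two correlation coefficients estimated on independent
#' samples: `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`,
#' with a two-sided p-value from the standard normal.
#'
#' @param r1,r2 Correlation coefficients, each with `|r| < 1`.
#' @param n1,n2 Sample sizes (each > 3).
#' @return List with `z` and `p`.
#' @examples
#' fisher_z_two_sample(0.846, 161, 0.836, 177)
#' @export
fisher_z_two_sample <- function(r1, n1, r2, n2) {
  if (n1 <= 3 || n2 <= 3) stop("both samples must exceed 3", call. = FALSE)
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("|r| = 1 gives an infinite Fisher transform", call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Reliability within groups of a moderator
#'
#' Splits retest pairs by a moderator and estimates the reliability within
#' each group. Three schemes are supported: explicit group `labels`;
#' `sd_bins`, four bins around the moderator mean with edges at
#' mean +/- 0.5 SD and +/- 1.5 SD (edges floored to integers, boundary
#' values assigned to the lower bin -- the convention used for
#' inter-test-interval analyses); and `quartiles`, right-closed intervals
#' at the integer-floored empirical quartiles (the convention used for
#' engagement counters).
#'
#' @inheritParams pearson_fisher_ci
#' @param by Moderator: group labels for `scheme = "labels"`, otherwise a
#'   numeric variable (e.g. inter-test interval in days).
#' @param scheme `"labels"`, `"sd_bins"` or `"quartiles"`.
#' @param min_group Minimum pairs per group; smaller groups are skipped
#'   with a warning.
#' @return List with `estimates` (named list of `reliability_estimate`),
#'   `edges` (interval cut points, `NULL` for labels), and `groups`
#'   (the per-pair group assignment).
#' @examples
#' set.seed(3)
#' x <- rnorm(200); y <- 0.8 * x + rnorm(200, sd = 0.6)
#' iti <- round(runif(200, 29, 235))
#' grouped_reliability(x, y, iti, scheme = "sd_bins")$edges
#' @export
grouped_reliability <- function(x, y, by,
                                scheme = c("labels", "sd_bins", "quartiles"),
                                level = 0.95, min_group = 4) {
  scheme <- match.arg(scheme)
  stopifnot(length(x) == length(y), length(by) == length(x))
  if (scheme == "labels") {
    g <- as.character(by)
    edges <- NULL
  } else {
    edges <- if (scheme == "sd_bins") {
      m <- mean(by); s <- stats::sd(by)
      floor(m + c(-0.5, 0.5, 1.5) * s)
    } else {
      floor(stats::quantile(by, c(0.25, 0.5, 0.75), type = 1, names = FALSE))
    }
    # right-closed: group 1 is by <= edges[1], group 4 is by > edges[3]
    g <- as.character(1L + findInterval(by, edges + 0.5))
  }
  out <- list()
  for (lev in sort(unique(g))) {
    rows <- g == lev
    if (sum(rows) < min_group) {
      warning("group ", lev, " has fewer than ", min_group,
              " pairs; skipped", call. = FALSE)
      next
    }
    out[[lev]] <- pearson_fisher_ci(x[rows], y[rows], level = level)
  }
  list(estimates = out, edges = edges, groups = g)
}

#' Two-stage engagement variance model
#'
#' Stage 1 regresses the time-2 score on the time-1 score and an
#' engagement counter by ordinary least squares. Stage 2 regresses the
#' squared stage-1 residuals on engagement: a positive and significant
#' stage-2 slope indicates that residual variance grows with engagement,
#' i.e. that test-retest reliability decreases as engagement increases.
#'
#' @param score1,score2 Scores at the two administrations.
#' @param engagement Engagement counter (e.g. unique days or games
#'   played).
#' @param robust If `TRUE`, stage-2 standard errors use the
#'   heteroscedasticity-consistent HC3 estimator (requires the `sandwich`
#'   package); default is conventional OLS standard errors.
#' @return List with `stage1` (coefficient table, `r_squared`, `f`, `df`)
#'   and `stage2` (coefficient table including the engagement slope, its
#'   t and p, plus `r_squared`, `f`, `df`).
#' @examples
#' set.seed(4)
#' s1 <- rnorm(200, 100, 15)
#' eng <- rpois(200, 30)
#' s2 <- 0.8 * s1 + rnorm(200, 20, 8)
#' engagement_variance_model(s1, s2, eng)$stage2$coefficients
#' @export
engagement_variance_model <- function(score1, score2, engagement,
                                      robust = FALSE) {
  ok <- is.finite(score1) & is.finite(score2) & is.finite(engagement)
  if (sum(ok) < 10)
    stop("at least 10 complete triples are required", call. = FALSE)
  d <- data.frame(score1 = score1[ok], score2 = score2[ok],
                  engagement = engagement[ok])
  m1 <- stats::lm(score2 ~ score1 + engagement, data = d)
  if (m1$rank < 3)
    stop("rank-deficient design: predictors are collinear", call. = FALSE)
  d$sq_resid <- stats::residuals(m1)^2
  m2 <- stats::lm(sq_resid ~ engagement, data = d)
  s1 <- summary(m1); s2 <- summary(m2)
  co2 <- s2$coefficients
  if (robust) {
    if (!requireNamespace("sandwich", quietly = TRUE))
      stop("robust = TRUE requires the 'sandwich' package", call. = FALSE)
    vc <- sandwich::vcovHC(m2, type = "HC3")
    se <- sqrt(diag(vc))
    tval <- stats::coef(m2) / se
    co2 <- cbind(Estimate = stats::coef(m2), `Std. Error` = se,
                 `t value` = tval,
                 `Pr(>|t|)` = 2 * stats::pt(-abs(tval), m2$df.residual))
  }
  list(
    stage1 = list(coefficients = s1$coefficients,
                  r_squared = s1$r.squared,
                  f = unname(s1$fstatistic[1]),
                  df = unname(s1$fstatistic[2:3])),
    stage2 = list(coefficients = co2,
                  slope = co2["engagement", "Estimate"],
                  t = co2["engagement", "t value"],
                  p = co2["engagement", "Pr(>|t|)"],
                  r_squared = s2$r.squared,
                  f = unname(s2$fstatistic[1]),
                  df = unname(s2$fstatistic[2:3]))
  )
}
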