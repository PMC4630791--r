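#' Demographic-effect regression on non-age-normed sum scores
#'
#' Ordinary least squares predicting the non-age-normed battery sum score
#' from gender (male reference), years of education and age (both
#' continuous), with the education-by-age, gender-by-education and
#' gender-by-age interactions. Rows with missing demographics (including
#' undisclosed gender) are excluded, and the excluded count reported,
#' mirroring a complete-case analysis.
#'
#' @param cohort Data frame with columns `gender` (`"F"`/`"M"`/`"ND"`),
#'   `education_years`, `age` and the outcome column.
#' @param outcome Name of the outcome column (default `"sum_score"`; see
#'   [scale_without_age()]).
#' @return List of class `demographic_model`: `coefficients` (estimate,
#'   SE, t, p per term), `r_squared`, `f`, `df`, `n_used`, `n_dropped`,
#'   and the underlying `lm` fit.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 2000), seed = 11)
#' fit <- fit_demographic_model(scale_without_age(cohort))
#' fit$coefficients
#' @export
fit_demographic_model <- function(cohort, outcome = "sum_score") {
  need <- c("gender", "education_years", "age", outcome)
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  d <- cohort[need]
  names(d)[4] <- ".outcome"
  d$gender[d$gender == "ND"] <- NA
  keep <- stats::complete.cases(d)
  n_dropped <- sum(!keep)
  d <- d[keep, ]
  if (nrow(d) < 20)
    stop("fewer than 20 complete-demographic subjects", call. = FALSE)
  d$gender <- factor(d$gender, levels = c("M", "F"))
  fit <- stats::lm(.outcome ~ gender + education_years + age +
                     education_years:age + gender:education_years +
                     gender:age, data = d)
  if (fit$rank < 7)
    stop("design matrix is rank deficient", call. = FALSE)
  s <- summary(fit)
  structure(list(
    coefficients = s$coefficients,
    r_squared = s$r.squared,
    f = unname(s$fstatistic[1]),
    df = unname(s$fstatistic[2:3]),
    n_used = nrow(d), n_dropped = n_dropped, fit = fit
  ), class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat(sprintf(
    "Demographic regression: n = %d (%d dropped), R^2 = %.3f, F(%g, %g) = %.1f\n",
    x$n_used, x$n_dropped, x$r_squared, x$df[1], x$df[2], x$f))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Welch two-sample t-test (raw samples or summary statistics)
#'
#' Unequal-variance comparison of two group means:
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite
#' degrees of freedom, evaluated at non-integer df without rounding.
#' Supply either two raw samples `x` and `y`, or the six summary
#' statistics -- useful when only published group means and SDs are
#' available.
#'
#' @param x,y Optional raw samples.
#' @param mean1,sd1,n1,mean2,sd2,n2 Summary statistics, used when `x` and
#'   `y` are not given.
#' @return List of class `welch_result`: `t`, `df`, `p` (two-sided),
#'   `mean_difference`.
#' @examples
#' welch_two_sample(mean1 = 89.2, sd1 = 15.82, n1 = 1493,
#'                  mean2 = 84.1, sd2 = 17.12, n2 = 105)
#' @export
welch_two_sample <- function(x = NULL, y = NULL,
                             mean1 = NULL, sd1 = NULL, n1 = NULL,
                             mean2 = NULL, sd2 = NULL, n2 = NULL) {
  if (!is.null(x) && !is.null(y)) {
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    mean1 <- mean(x); sd1 <- stats::sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y)
  }
  if (is.null(mean1) || is.null(sd1) || is.null(n1) ||
      is.null(mean2) || is.null(sd2) || is.null(n2))
    stop("supply either raw samples x and y, or all six summary statistics",
         call. = FALSE)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 observations",
                             call. = FALSE)
  if (sd1 == 0 && sd2 == 0)
    stop("degenerate input: both groups have zero variance", call. = FALSE)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  structure(list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
                 mean_difference = mean1 - mean2),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch t(%.2f) = %.3f, p = %.4g (mean difference %.3f)\n",
              x$df, x$t, x$p, x$mean_difference))
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical between/within variance decomposition across two or more
#' groups.
#'
#' @param groups Either a list of numeric samples, or a numeric vector
#'   (then `labels` assigns groups).
#' @param labels Optional group labels when `groups` is a vector.
#' @return List with `f`, `df_between`, `df_within`, `p`.
#' @examples
#' anova_oneway(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
#' @export
anova_oneway <- function(groups, labels = NULL) {
  if (!is.list(groups)) {
    stopifnot(!is.null(labels), length(labels) == length(groups))
    groups <- split(groups, labels)
  }
  if (length(groups) < 2) stop("at least 2 groups are required", call. = FALSE)
  if (any(vapply(groups, length, 1L) < 2))
    stop("each group needs at least 2 observations", call. = FALSE)
  all_x <- unlist(groups, use.names = FALSE)
  grand <- mean(all_x)
  n_g <- vapply(groups, length, 1L)
  means <- vapply(groups, mean, 1)
  ssb <- sum(n_g * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  dfb <- length(groups) - 1
  dfw <- length(all_x) - length(groups)
  f <- (ssb / dfb) / (ssw / dfw)
  list(f = f, df_between = dfb, df_within = dfw,
       p = stats::pf(f, dfb, dfw, lower.tail = FALSE))
}

#' Group difference in reference-SD units
#'
#' `(mean_ref - mean_group) / sd_ref`: how many reference-group standard
#' deviations the comparison group falls below the reference. The
#' denominator is an explicit argument because published effect sizes of
#' this kind do not always state which SD was used.
#'
#' @param mean_ref,mean_group Group means.
#' @param sd_ref Standard deviation used as the unit (must be > 0).
#' @return Numeric effect size.
#' @examples
#' sd_effect_size(100.2, 89.2, 14.49)
#' @export
sd_effect_size <- function(mean_ref, mean_group, sd_ref) {
  if (sd_ref <= 0) stop("sd_ref must be positive", call. = FALSE)
  (mean_ref - mean_group) / sd_ref
}
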