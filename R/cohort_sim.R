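#' Reference four-factor loading pattern for the default battery
#'
#' The 8 x 4 varimax-rotated loading matrix used as the simulator default.
#' It reproduces the published factor solution for this battery: a mental
#' flexibility factor (Arithmetic/Grammatical Reasoning, Digit Symbol
#' Coding), a memory factor (Forward/Reverse Memory Span), an
#' attention/speed factor (Trail Making A/B), and a weak fourth factor.
#' Loadings suppressed in the published display are set to 0.
#'
#' @return An 8 x 4 numeric matrix; rows named by subtest in registry
#'   order, columns `F1`..`F4`.
#' @examples
#' default_loadings()
#' @export
default_loadings <- function() {
  L <- rbind(
    trail_a_s    = c(0.186, 0.178, 0.671, 0.000),
    trail_b_s    = c(0.376, 0.228, 0.455, 0.300),
    fwd_span     = c(0.179, 0.621, 0.196, 0.000),
    rev_span     = c(0.158, 0.731, 0.158, 0.112),
    digit_symbol = c(0.450, 0.260, 0.388, 0.000),
    matrices     = c(0.219, 0.217, 0.000, 0.211),
    arithmetic   = c(0.754, 0.154, 0.211, 0.000),
    grammatical  = c(0.442, 0.160, 0.160, 0.218)
  )
  colnames(L) <- paste0("F", 1:4)
  L
}

#' Uniquenesses implied by a loading matrix
#'
#' Standard factor-analysis identity: the uniqueness of variable *j* is
#' `1 - sum(loadings[j, ]^2)`, the variance not explained by the common
#' factors when variables are standardized.
#'
#' @param loadings Numeric matrix of standardized loadings (variables in
#'   rows).
#' @return Numeric vector of uniquenesses, one per row of `loadings`.
#' @examples
#' derive_uniquenesses(default_loadings())
#' @export
derive_uniquenesses <- function(loadings) {
  loadings <- as.matrix(loadings)
  h2 <- rowSums(loadings^2)
  if (any(h2 > 1 + 1e-12))
    stop("Heywood case: communality exceeds 1 for row(s) ",
         paste(which(h2 > 1 + 1e-12), collapse = ", "), call. = FALSE)
  1 - pmin(h2, 1)
}

# reference retest-reliability targets per subtest
default_reliabilities <- function() {
  c(trail_a_s = 0.570, trail_b_s = 0.529, fwd_span = 0.530,
    rev_span = 0.510, digit_symbol = 0.738, matrices = 0.388,
    arithmetic = 0.734, grammatical = 0.533)
}

# reference demographic regression coefficients on the non-age-normed sum
# scale (outcome = sum of eight 100/15 scaled scores; male = reference)
default_demographic_effects <- function() {
  list(intercept = 748.073, gender_f = -11.766653, education = 13.290844,
       age = -0.797219, education_x_age = -0.139730,
       gender_x_education = -0.342012, gender_x_age = 0.201607)
}

# per-subtest scaled-point deficits (healthy minus group) for the two
# self-reported clinical groups, in registry order
default_group_profiles <- function() {
  list(
    MCI = c(trail_a_s = 7.8, trail_b_s = 8.1, fwd_span = 6.5,
            rev_span = 6.7, digit_symbol = 10.5, matrices = 3.6,
            arithmetic = 7.5, grammatical = 4.5),
    AD = c(trail_a_s = 9.7, trail_b_s = 12.0, fwd_span = 7.5,
           rev_span = 9.4, digit_symbol = 17.3, matrices = 4.0,
           arithmetic = 12.0, grammatical = 8.9)
  )
}

# monotone links from standardized latent score to raw subtest units.
# time links give right-skewed completion seconds (lower = better);
# count links give rounded non-negative counts.
default_raw_links <- function() {
  list(
    trail_a_s    = list(type = "time",  log_center = log(42), log_scale = 0.30),
    trail_b_s    = list(type = "time",  log_center = log(85), log_scale = 0.35),
    fwd_span     = list(type = "count", center = 14, scale = 4,  min = 0, max = Inf),
    rev_span     = list(type = "count", center = 12, scale = 4,  min = 0, max = Inf),
    digit_symbol = list(type = "count", center = 38, scale = 10, min = 0, max = Inf),
    matrices     = list(type = "count", center = 11, scale = 2.8, min = 0, max = 17),
    arithmetic   = list(type = "count", center = 12, scale = 5,  min = 0, max = Inf),
    grammatical  = list(type = "count", center = 15, scale = 6,  min = 0, max = Inf)
  )
}

apply_raw_link <- function(link, z) {
  if (link$type == "time") {
    round(exp(link$log_center + link$log_scale * (-z)), 1)
  } else {
    pmin(pmax(round(link$center + link$scale * z), link$min), link$max)
  }
}

#' Simulation configuration for synthetic cohorts
#'
#' Collects every knob of the cohort simulator with defaults calibrated to
#' the published normative study: the four-factor loading pattern
#' ([default_loadings()]), demographic gradients on the non-age-normed sum
#' scale, per-subtest retest-reliability targets, a mean practice shift of
#' 1.1 Grand-Index points, clinical deficit profiles for self-reported MCI
#' and AD, and inter-test-interval / engagement distributions (ITI mean
#' 78.8, SD 19.86, truncated to 29-235 days; unique days played mean 36.7,
#' SD 19.2, range 0-185; games played right-skewed with mean 353.7, SD
#' 432.2, capped at 8997).
#'
#' @param n_subjects Number of healthy (normative) subjects.
#' @param n_retest Number of healthy subjects who also take the battery a
#'   second time (default 0). May be a fraction of `n_subjects`.
#' @param n_mci,n_ad Number of additional subjects in the self-reported
#'   MCI / AD groups (aged 50+; default 0).
#' @param seed Default RNG seed used by [simulate_cohort()] when no seed is
#'   passed there.
#' @param loadings 8 x 4 loading matrix; uniquenesses are derived from it.
#' @param demographic_effects Named list of regression coefficients on the
#'   non-age-normed sum scale (see the package defaults in the fitted
#'   config), or `NULL` to disable demographic gradients.
#' @param retest_reliability Named vector of target test-retest
#'   correlations per subtest, each in (0, 1].
#' @param practice_mean,practice_sd Mean and SD of the practice shift added
#'   to the second session, in Grand-Index points. The default SD is 0:
#'   random retest variability is already produced by the reliability
#'   model, and with the default targets it implies a change-score SD of
#'   about 8.5 points on its own.
#' @param group_profiles List with elements `MCI` and `AD`: per-subtest
#'   deficits in scaled points injected for the clinical groups.
#' @param engagement_noise Heteroscedasticity knob: the session-2 noise SD
#'   is multiplied by `sqrt(1 + engagement_noise * games_played / 353.7)`.
#'   Default 0 (engagement independent of measurement noise).
#' @param links Raw-score link functions per subtest; the defaults give
#'   right-skewed completion seconds for the timed subtests and rounded
#'   bounded counts for the rest.
#' @param keep_latent If `TRUE`, [simulate_cohort()] attaches the latent
#'   standardized scores as the `"latent"` attribute of the cohort.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_subjects = 1000, n_retest = 400, seed = 7)
#' @export
sim_config <- function(n_subjects = 1000,
                       n_retest = 0,
                       n_mci = 0,
                       n_ad = 0,
                       seed = NULL,
                       loadings = default_loadings(),
                       demographic_effects = default_demographic_effects(),
                       retest_reliability = default_reliabilities(),
                       practice_mean = 1.1,
                       practice_sd = 0,
                       group_profiles = default_group_profiles(),
                       engagement_noise = 0,
                       links = default_raw_links(),
                       keep_latent = FALSE) {
  loadings <- as.matrix(loadings)
  psi <- derive_uniquenesses(loadings)   # also validates row norms
  if (!is.null(retest_reliability)) {
    if (any(retest_reliability <= 0 | retest_reliability > 1))
      stop("retest reliability targets must lie in (0, 1]", call. = FALSE)
  }
  if (n_retest > 0 && n_retest < 1) n_retest <- round(n_retest * n_subjects)
  structure(list(
    n_subjects = as.integer(n_subjects), n_retest = as.integer(n_retest),
    n_mci = as.integer(n_mci), n_ad = as.integer(n_ad), seed = seed,
    loadings = loadings, uniquenesses = psi,
    demographic_effects = demographic_effects,
    retest_reliability = retest_reliability,
    practice_mean = practice_mean, practice_sd = practice_sd,
    group_profiles = group_profiles, engagement_noise = engagement_noise,
    links = links, keep_latent = isTRUE(keep_latent)
  ), class = "sim_config")
}

# inverse-CDF truncated normal draw
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# reference-regression linear predictor for the demographic shift; missing
# demographics contribute their cohort-typical value so the shift is 0 on
# those terms
demographic_linear_predictor <- function(eff, age, edu, gender) {
  f <- ifelse(is.na(gender) | gender == "ND", 0.533, as.numeric(gender == "F"))
  e <- ifelse(is.na(edu), 15.2, edu)
  eff$intercept + eff$gender_f * f + eff$education * e + eff$age * age +
    eff$education_x_age * e * age + eff$gender_x_education * f * e +
    eff$gender_x_age * f * age
}

#' Simulate a synthetic cohort with calibrated statistical structure
#'
#' Draws subjects with realistic demographics (ages 13-89 with mean about
#' 46; gender 53.3/40.1/6.6 percent F/M/undisclosed; education categories
#' matching the normative study), generates standardized subtest scores
#' from a four-factor model `z = d + Lambda f + sqrt(psi) eps` with a
#' demographic shift `d` calibrated so that refitting the demographic
#' regression on the simulated cohort recovers the reference coefficients,
#' converts them to raw subtest units through monotone links, and
#' optionally generates a second session whose per-subtest retest
#' correlations hit the configured targets. Members of the clinical groups
#' receive their scaled-point deficit profile on top.
#'
#' The second-session model is
#' `z2 = d + rho * u1 + sqrt(1 - rho^2) * u2`, with `u2` a fresh draw from
#' the same factor model and `rho` solved per subtest so that the
#' observable correlation (which includes the shared demographic
#' component) equals the target.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; falls back to `config$seed`. The same config
#'   and seed always yield a bit-identical cohort.
#' @return A cohort data frame with one row per subject-session and
#'   columns `subject_id`, `age`, `gender`, `education_years`, `group`,
#'   `session`, `iti_days`, `days_played`, `games_played`, and the eight
#'   raw-score columns. If `config$keep_latent` is set, the latent
#'   standardized scores are attached as `attr(cohort, "latent")`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 500, n_retest = 200), seed = 42)
#' table(cohort$session)
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  subtests <- ncpt_subtests()
  p <- nrow(subtests)
  k <- ncol(config$loadings)
  n_h <- config$n_subjects
  n <- n_h + config$n_mci + config$n_ad
  if (n_h < 2) stop("need at least 2 healthy subjects", call. = FALSE)

  group <- c(rep("healthy", n_h), rep("MCI", config$n_mci),
             rep("AD", config$n_ad))

  # demographics: healthy ages are a uniform mixture over 13-89 (mean ~46);
  # clinical-group ages are truncated normals matching the reported groups
  age <- numeric(n)
  mix <- stats::runif(n_h) < 0.4
  age[seq_len(n_h)] <- ifelse(mix, stats::runif(n_h, 13, 90),
                              stats::runif(n_h, 28, 58))
  if (config$n_mci > 0)
    age[group == "MCI"] <- rtruncnorm(config$n_mci, 65.2, 8.53, 50, 89.99)
  if (config$n_ad > 0)
    age[group == "AD"] <- rtruncnorm(config$n_ad, 68.8, 8.31, 50, 89.99)

  gender <- sample(c("F", "M", "ND"), n, replace = TRUE,
                   prob = c(0.533, 0.401, 0.066))
  edu_cat <- sample(1:4, n, replace = TRUE,
                    prob = c(0.144, 0.454, 0.302, 0.099))
  education_years <- rep(NA_real_, n)
  education_years[edu_cat == 1] <- sample(8:12, sum(edu_cat == 1), replace = TRUE)
  education_years[edu_cat == 2] <- sample(13:16, sum(edu_cat == 2), replace = TRUE)
  education_years[edu_cat == 3] <- sample(17:22, sum(edu_cat == 3), replace = TRUE)

  # standardized demographic shift, auto-calibrated so the refitted
  # regression recovers the reference coefficients (the 1/sqrt(1 + var d)
  # attenuation from the larger total variance cancels exactly)
  if (!is.null(config$demographic_effects)) {
    lp <- demographic_linear_predictor(config$demographic_effects,
                                       age, education_years, gender)
    d0 <- (lp - mean(lp)) / (15 * p)
    v0 <- stats::var(d0)
    if (v0 >= 1)
      stop("demographic effects imply more than the total score variance",
           call. = FALSE)
    d <- d0 / sqrt(1 - v0)
  } else {
    d <- numeric(n)
  }

  draw_factor_scores <- function(m) {
    f <- matrix(stats::rnorm(m * k), m, k)
    e <- matrix(stats::rnorm(m * p), m, p)
    f %*% t(config$loadings) + e * rep(sqrt(config$uniquenesses), each = m)
  }

  u1 <- draw_factor_scores(n)
  z1 <- u1 + d
  shift_z <- matrix(0, n, p)
  for (g in names(config$group_profiles)) {
    rows <- group == g
    if (any(rows))
      shift_z[rows, ] <- matrix(-config$group_profiles[[g]][subtests$subtest] / 15,
                                sum(rows), p, byrow = TRUE)
  }
  z1 <- z1 + shift_z

  raw1 <- matrix(NA_real_, n, p)
  colnames(raw1) <- subtests$subtest
  for (j in seq_len(p))
    raw1[, j] <- apply_raw_link(config$links[[subtests$subtest[j]]], z1[, j])

  subject_id <- sprintf("S%06d", seq_len(n))
  cohort <- data.frame(
    subject_id = subject_id, age = age, gender = gender,
    education_years = education_years, group = group, session = 1L,
    iti_days = NA_real_, days_played = NA_real_, games_played = NA_real_,
    as.data.frame(raw1), stringsAsFactors = FALSE
  )

  latent <- list(z1 = z1, d = d)

  # second session for a healthy retest subsample
  n_r <- min(config$n_retest, n_h)
  if (n_r > 0) {
    if (is.null(config$retest_reliability))
      stop("retest requested but no reliability targets configured",
           call. = FALSE)
    ridx <- sort(sample(seq_len(n_h), n_r))
    # the observable retest correlation is computed on age-normed scaled
    # scores, so only the within-age-bin part of the demographic shift is
    # shared between sessions; solve rho against that variance
    bin_r <- assign_age_bin(age[ridx], age_bins())
    d_centered <- d[ridx] - stats::ave(d[ridx], bin_r)
    var_d <- if (n_r > 1) stats::var(d_centered) else 0
    r_tar <- config$retest_reliability[subtests$subtest]
    # the raw-score links discretize (rounding, range caps), which
    # attenuates the observable scaled-score correlation; estimate each
    # link's fidelity a2 = cor(scaled-equivalent, latent)^2 on session 1
    # and solve rho against the deflated target
    bin_h <- assign_age_bin(age[seq_len(n_h)], age_bins())
    bin_int <- function(raw, dirn) {
      # within-bin inverse normal transform; bins too small to rank are NA
      se <- rep(NA_real_, n_h)
      for (b in unique(bin_h)) {
        rows <- bin_h == b
        if (sum(rows) >= 2)
          se[rows] <- rank_inverse_normal(raw[rows], direction = dirn)
      }
      se
    }
    a2 <- vapply(seq_len(p), function(j) {
      se <- bin_int(raw1[seq_len(n_h), j], subtests$direction[j])
      zc <- z1[seq_len(n_h), j] - stats::ave(z1[seq_len(n_h), j], bin_h)
      stats::cor(se, zc, use = "complete.obs")^2
    }, 1)
    r_model <- pmin(r_tar / a2, 1)
    rho <- r_model * (1 + var_d) - var_d
    # one Newton step on an internal calibration retest: realized
    # observable correlations at the preliminary rho are measured on a
    # pseudo-session, and rho corrected with the local slope a2/(1+var_d)
    rho <- pmin(pmax(rho, 0), 1)
    u_cal <- draw_factor_scores(n_h)
    z_cal <- d[seq_len(n_h)] + u1[seq_len(n_h), , drop = FALSE] %*% diag(rho, p) +
      u_cal %*% diag(sqrt(1 - rho^2), p)
    obs0 <- vapply(seq_len(p), function(j) {
      dirn <- subtests$direction[j]
      raw_c <- apply_raw_link(config$links[[subtests$subtest[j]]], z_cal[, j])
      se1 <- bin_int(raw1[seq_len(n_h), j], dirn)
      se2 <- bin_int(raw_c, dirn)
      stats::cor(se1, se2, use = "complete.obs")
    }, 1)
    rho <- rho + (r_tar - obs0) * (1 + var_d) / a2
    if (any(rho > 1 + 0.03) || any(rho < -1e-6))
      stop("infeasible retest reliability target after noise decomposition ",
           "(solved latent correlation outside [0, 1])", call. = FALSE)
    rho <- pmin(pmax(rho, 0), 1)

    iti <- round(rtruncnorm(n_r, 78.8, 19.86, 29, 235))
    days <- round(rtruncnorm(n_r, 36.7, 19.2, 0, 185))
    # right-skewed games-played counts (lognormal matched to mean 353.7,
    # SD 432.2), capped at the observed maximum
    cv2 <- (432.2 / 353.7)^2
    sdlog <- sqrt(log(1 + cv2))
    meanlog <- log(353.7) - sdlog^2 / 2
    games <- pmin(round(stats::rlnorm(n_r, meanlog, sdlog)), 8997)

    u2 <- draw_factor_scores(n_r)
    infl <- sqrt(1 + config$engagement_noise * games / 353.7)
    z2 <- d[ridx] + u1[ridx, , drop = FALSE] %*% diag(rho, p) +
      (u2 * infl) %*% diag(sqrt(1 - rho^2), p)

    # practice shift: a Grand-Index-scale change converted to a uniform
    # standardized shift via the empirical scaled-sum variance; age-normed
    # scaled scores carry only within-age-bin variance, so the conversion
    # uses bin-centered latent scores
    bin_h <- assign_age_bin(age[seq_len(n_h)], age_bins())
    z1h <- z1[seq_len(n_h), , drop = FALSE]
    z1c <- apply(z1h, 2, function(v) v - stats::ave(v, bin_h))
    sd_z <- apply(z1c, 2, stats::sd)
    sum_proxy <- (15 * z1c) %*% (1 / sd_z)
    sd_sum <- stats::sd(sum_proxy)
    gi_shift <- config$practice_mean +
      config$practice_sd * stats::rnorm(n_r)
    delta <- gi_shift * sd_sum / (225 * sum(1 / sd_z))
    z2 <- z2 + delta

    raw2 <- matrix(NA_real_, n_r, p)
    colnames(raw2) <- subtests$subtest
    for (j in seq_len(p))
      raw2[, j] <- apply_raw_link(config$links[[subtests$subtest[j]]], z2[, j])

    cohort$iti_days[ridx] <- iti
    cohort$days_played[ridx] <- days
    cohort$games_played[ridx] <- games
    s2 <- data.frame(
      subject_id = subject_id[ridx], age = age[ridx], gender = gender[ridx],
      education_years = education_years[ridx], group = group[ridx],
      session = 2L, iti_days = iti, days_played = days, games_played = games,
      as.data.frame(raw2), stringsAsFactors = FALSE
    )
    cohort <- rbind(cohort, s2)
    latent$z2 <- z2
    latent$retest_idx <- ridx
  }
  rownames(cohort) <- NULL
  if (config$keep_latent) attr(cohort, "latent") <- latent
  cohort
}
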