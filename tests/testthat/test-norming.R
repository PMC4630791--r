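test_that("rank inverse normal transform matches an inverse-error-function oracle", {
  # qnorm(p) = sqrt(2) * erfinv(2p - 1), evaluated with an independent
  # high-precision implementation
  skip_if_not_installed("pracma")
  x <- c(10, 20, 30, 40, 50)
  got <- rank_inverse_normal(x)
  p <- (seq_along(x) - 0.5) / length(x)
  expected <- 100 + 15 * sqrt(2) * pracma::erfinv(2 * p - 1)
  expect_equal(got, expected, tolerance = 1e-9)
  expect_equal(round(got, 1), c(80.8, 92.1, 100.0, 107.9, 119.2))
})

test_that("middle value of an odd-sized distinct sample scores exactly 100", {
  expect_equal(rank_inverse_normal(c(1, 2, 3))[2], 100)
  expect_equal(rank_inverse_normal(c(5, 80, 41))[3], 100)
})

test_that("lower-is-better direction reverses the scale", {
  s <- rank_inverse_normal(c(10, 20, 30), direction = "lower_better")
  expect_gt(s[1], 100)   # fastest time scores best
  expect_lt(s[3], 100)
  expect_equal(s[2], 100)
  expect_equal(s, rev(rank_inverse_normal(c(10, 20, 30))))
})

test_that("ties receive identical scaled scores under both positions", {
  for (pos in c("hazen", "weibull")) {
    s <- rank_inverse_normal(c(7, 3, 7, 1, 7), position = pos)
    expect_length(unique(s[c(1, 3, 5)]), 1)
  }
})

test_that("distinct samples have scaled mean exactly 100 and SD near 15", {
  set.seed(41)
  for (n in c(5, 50, 2000)) {
    s <- rank_inverse_normal(runif(n))
    expect_equal(mean(s), 100, tolerance = 1e-12)
  }
  s <- rank_inverse_normal(rnorm(2000))
  expect_lt(abs(sd(s) - 15), 0.05)
})

test_that("degenerate inputs are rejected", {
  expect_error(rank_inverse_normal(5), "at least 2")
  expect_error(rank_inverse_normal(c(1, NA, 3)), "finite")
  expect_error(rank_inverse_normal(c(1, Inf)), "finite")
})

test_that("weibull plotting position uses r/(n+1)", {
  s <- rank_inverse_normal(1:4, position = "weibull")
  expect_equal(s, 100 + 15 * qnorm((1:4) / 5))
})

test_that("default age-bin scheme has 14 bins with the two wide ends", {
  b <- age_bins()
  expect_equal(nrow(b), 14)
  expect_equal(b$lower[1], 13)
  expect_equal(b$upper[1], 19)
  expect_equal(b$lower[14], 80)
  expect_equal(b$upper[14], 89)
  expect_true(all(b$upper[-c(1, 14)] - b$lower[-c(1, 14)] == 4))
  # bins partition 13-89 with no overlap
  expect_equal(b$lower[-1], b$upper[-14] + 1)
})

test_that("norm tables equal the direct transform on each bin and are idempotent", {
  set.seed(42)
  n <- 600
  cohort <- simulate_cohort(sim_config(n_subjects = n), seed = 42)
  cohort <- cohort[cohort$session == 1L, ]
  nt <- build_norm_tables(cohort)
  scored <- score_subjects(cohort, nt)
  # idempotence: re-scoring reproduces table construction bit for bit
  scored2 <- score_subjects(cohort, nt)
  expect_identical(scored, scored2)
  # each bin's stored values equal rank_inverse_normal on the bin's raws
  bins <- age_bins()
  b <- 3
  rows <- cohort$age >= bins$lower[b] & cohort$age < bins$upper[b] + 1
  direct <- rank_inverse_normal(cohort$digit_symbol[rows])
  expect_equal(scored$scaled_digit_symbol[rows], direct)
  direct_t <- rank_inverse_normal(cohort$trail_a_s[rows],
                                  direction = "lower_better")
  expect_equal(scored$scaled_trail_a_s[rows], direct_t)
})

test_that("small bins agree with the exhaustive rank-enumeration oracle", {
  set.seed(43)
  subtests <- ncpt_subtests()
  for (m in c(2, 5, 8)) {
    raw <- lapply(seq_len(nrow(subtests)), function(j)
      sample(c(round(runif(m - 1, 5, 60)), 30)))  # may contain ties
    cohort <- data.frame(subject_id = paste0("s", 1:m),
                         age = runif(m, 30, 34), gender = "F",
                         education_years = 16, group = "healthy",
                         session = 1L)
    for (j in seq_len(nrow(subtests))) cohort[[subtests$subtest[j]]] <- raw[[j]]
    nt <- build_norm_tables(cohort, bins = data.frame(lower = 30, upper = 34))
    scored <- score_subjects(cohort, nt)
    for (j in seq_len(nrow(subtests))) {
      expect_equal(scored[[paste0("scaled_", subtests$subtest[j])]],
                   oracle_scaled(raw[[j]], subtests$direction[j]),
                   tolerance = 1e-12)
    }
  }
})

test_that("monotonicity holds within bins for random cohorts", {
  set.seed(44)
  for (rep in 1:5) {
    x <- sample(0:30, 40, replace = TRUE)
    s <- rank_inverse_normal(x)
    o <- order(x)
    expect_true(all(diff(s[o]) >= 0))
    st <- rank_inverse_normal(x + 1, direction = "lower_better")
    expect_true(all(diff(st[o]) <= 0))
  }
})

test_that("bin underflow errors name the offending bin", {
  cohort <- simulate_cohort(sim_config(n_subjects = 50), seed = 45)
  cohort <- cohort[cohort$session == 1L & cohort$age < 75, ]
  expect_error(build_norm_tables(cohort), "age bin \\d+-\\d+ holds")
})

test_that("ages outside the supported range are rejected at scoring", {
  cohort <- simulate_cohort(sim_config(n_subjects = 500), seed = 46)
  cohort <- cohort[cohort$session == 1L, ]
  nt <- build_norm_tables(cohort)
  bad <- cohort[1, ]
  bad$age <- 95
  expect_error(score_subjects(bad, nt), "not covered")
  bad$age <- 10
  expect_error(score_subjects(bad, nt), "not covered")
})

test_that("missing subtest scores give an incomplete-battery error", {
  cohort <- simulate_cohort(sim_config(n_subjects = 500), seed = 47)
  cohort <- cohort[cohort$session == 1L, ]
  nt <- build_norm_tables(cohort)
  cohort$rev_span[3] <- NA
  expect_error(score_subjects(cohort, nt), "rev_span")
})

test_that("unseen raw values use the worse-direction step with clamping", {
  subtests <- data.frame(subtest = c("ct", "tm"),
                         direction = c("higher_better", "lower_better"),
                         stringsAsFactors = FALSE)
  cohort <- data.frame(subject_id = paste0("s", 1:5), age = 30:34,
                       gender = "F", education_years = 12,
                       group = "healthy", session = 1L,
                       ct = c(10, 20, 30, 40, 50),
                       tm = c(12, 24, 36, 48, 60))
  nt <- build_norm_tables(cohort, bins = data.frame(lower = 30, upper = 34),
                          subtests = subtests)
  scored <- score_subjects(cohort, nt)
  probe <- cohort
  probe$ct <- c(5, 25, 30, 49, 99)   # below range, between, exact, between, above
  probe$tm <- c(6, 30, 36, 50, 99)
  ps <- score_subjects(probe, nt)
  # counts: between-values floor to the next-worse (lower) observed score
  expect_equal(ps$scaled_ct, scored$scaled_ct[c(1, 2, 3, 4, 5)])
  # times: between-values floor to the next-worse (slower) observed score
  expect_equal(ps$scaled_tm, scored$scaled_tm[c(1, 3, 3, 5, 5)])
  # monotone in the probe's own ordering
  expect_true(all(diff(ps$scaled_ct) >= 0))
  expect_true(all(diff(ps$scaled_tm) <= 0))
})

test_that("grand index equals a brute-force two-subtest oracle", {
  subtests <- data.frame(subtest = c("a", "b"),
                         direction = c("higher_better", "lower_better"),
                         stringsAsFactors = FALSE)
  cohort <- data.frame(subject_id = paste0("s", 1:5), age = c(30, 31, 32, 33, 34),
                       gender = "F", education_years = 12,
                       group = "healthy", session = 1L,
                       a = c(3, 9, 27, 81, 243), b = c(50, 10, 30, 20, 40))
  nt <- build_norm_tables(cohort, bins = data.frame(lower = 30, upper = 34),
                          subtests = subtests)
  scored <- score_subjects(cohort, nt)
  sum_oracle <- oracle_scaled(cohort$a) + oracle_scaled(cohort$b, "lower_better")
  gi_oracle <- oracle_scaled(sum_oracle)
  expect_equal(scored$sum_score, sum_oracle, tolerance = 1e-12)
  expect_equal(scored$grand_index, gi_oracle, tolerance = 1e-12)
})

test_that("scoring the norming cohort gives grand index mean 100", {
  co <- simulate_cohort(sim_config(n_subjects = 3000), seed = 48)
  co <- co[co$session == 1L, ]
  scored <- score_subjects(co, build_norm_tables(co))
  expect_equal(mean(scored$grand_index), 100, tolerance = 0.2)
})

test_that("scale_without_age equals norm tables built with one all-age bin", {
  co <- simulate_cohort(sim_config(n_subjects = 400), seed = 49)
  co <- co[co$session == 1L, ]
  nt1 <- build_norm_tables(co, bins = data.frame(lower = 13, upper = 89))
  via_tables <- score_subjects(co, nt1)
  direct <- scale_without_age(co)
  for (st in ncpt_subtests()$subtest)
    expect_equal(direct[[paste0("scaled_", st)]],
                 via_tables[[paste0("scaled_", st)]])
  expect_equal(direct$sum_score, via_tables$sum_score)
})

test_that("age norming removes the age gradient that raw sums retain", {
  co <- big_cohort()
  s1 <- co[co$session == 1L & co$group == "healthy", ]
  plain <- scale_without_age(s1)
  scored <- score_subjects(s1, big_norms())
  r_plain <- cor(plain$age, plain$sum_score)
  r_normed <- cor(scored$age, scored$grand_index)
  expect_lt(r_plain, -0.3)         # raw sums decline with age
  expect_lt(abs(r_normed), 0.05)   # age-normed index does not
})
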