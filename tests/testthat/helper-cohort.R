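# shared fixtures, built once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# large calibrated cohort with a retest arm and clinical groups
big_cohort <- function() {
  cached("big_cohort", simulate_cohort(
    sim_config(n_subjects = 20000, n_retest = 8000, n_mci = 800),
    seed = 20260924))
}

big_norms <- function() {
  cached("big_norms", {
    co <- big_cohort()
    build_norm_tables(co[co$session == 1L & co$group == "healthy", ])
  })
}

# scored session-1/session-2 pairs, wide format
big_retest_pairs <- function() {
  cached("big_retest_pairs", {
    co <- big_cohort()
    nt <- big_norms()
    s1 <- score_subjects(co[co$session == 1L & co$group == "healthy", ], nt)
    s2 <- score_subjects(co[co$session == 2L, ], nt)
    merge(s1, s2, by = "subject_id", suffixes = c("_1", "_2"))
  })
}

# small healthy-only cohort without demographic gradients, useful for
# structure analyses driven purely by the factor model
factor_cohort_scores <- function() {
  cached("factor_cohort_scores", {
    co <- simulate_cohort(
      sim_config(n_subjects = 10000, demographic_effects = NULL), seed = 3)
    s1 <- co[co$session == 1L, ]
    sc <- score_subjects(s1, build_norm_tables(s1))
    sc[paste0("scaled_", ncpt_subtests()$subtest)]
  })
}

# exhaustive mid-rank oracle for the inverse normal transform: ranks are
# counted by pairwise comparison, never by rank()
oracle_scaled <- function(x, direction = "higher_better") {
  perf <- if (direction == "lower_better") -x else x
  vapply(perf, function(v) {
    r <- sum(perf < v) + (1 + sum(perf == v)) / 2
    100 + 15 * qnorm((r - 0.5) / length(perf))
  }, 1)
}

# align columns of a loading matrix to a reference by greedy max |inner
# product|, with sign flips
align_loadings <- function(Lhat, L) {
  k <- ncol(L)
  used <- logical(k)
  out <- matrix(NA_real_, nrow(L), k)
  for (j in seq_len(k)) {
    ip <- vapply(seq_len(k), function(m)
      if (used[m]) -Inf else abs(sum(L[, j] * Lhat[, m])), 1)
    m <- which.max(ip)
    used[m] <- TRUE
    out[, j] <- Lhat[, m] * sign(sum(L[, j] * Lhat[, m]))
  }
  out
}
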