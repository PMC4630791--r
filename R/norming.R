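#' Percentile rank-based inverse normal transformation
#'
#' Ranks the observations, converts the (mid-)ranks to percentiles with a
#' plotting position, maps each percentile through the standard normal
#' quantile function, and rescales to the conventional normative scale with
#' mean `target_mean` and standard deviation `target_sd`. Ties share a
#' mid-rank and therefore receive identical scaled scores. For
#' `direction = "lower_better"` (e.g. completion times) smaller raw values
#' receive larger scaled scores.
#'
#' With the default Hazen plotting position `(rank - 0.5) / n` the set of
#' percentiles is symmetric about 0.5, so for distinct values the scaled
#' scores have sample mean exactly `target_mean`, and the sample SD
#' converges to `target_sd` as `n` grows.
#'
#' @param x Numeric vector of raw scores (at least 2 finite values).
#' @param direction `"higher_better"` (default) or `"lower_better"`.
#' @param position Plotting position: `"hazen"` for `(r - 0.5)/n`
#'   (default) or `"weibull"` for `r/(n + 1)`.
#' @param target_mean,target_sd Location and scale of the normative score
#'   scale; defaults 100 and 15.
#' @return Numeric vector of scaled scores, same length and order as `x`.
#' @examples
#' rank_inverse_normal(c(10, 20, 30, 40, 50))
#' rank_inverse_normal(c(31.2, 28.5, 44.0), direction = "lower_better")
#' @export
rank_inverse_normal <- function(x,
                                direction = c("higher_better", "lower_better"),
                                position = c("hazen", "weibull"),
                                target_mean = 100, target_sd = 15) {
  direction <- match.arg(direction)
  position <- match.arg(position)
  if (!is.numeric(x) || length(x) < 2L)
    stop("at least 2 numeric values are required", call. = FALSE)
  if (any(!is.finite(x)))
    stop("raw scores must all be finite", call. = FALSE)
  perf <- if (direction == "lower_better") -x else x
  r <- rank(perf, ties.method = "average")
  n <- length(x)
  p <- switch(position,
    hazen = (r - 0.5) / n,
    weibull = r / (n + 1)
  )
  target_mean + target_sd * stats::qnorm(p)
}

#' Default age-bin scheme for normative tables
#'
#' Ages 13 to 89 are partitioned into 14 bins: a wide 13-19 bin, twelve
#' 5-year bins (20-24, 25-29, ..., 75-79), and a wide 80-89 bin. Bins are
#' half-open `[lower, upper + 1)` on continuous age, i.e. a bin labelled
#' 20-24 covers ages in `[20, 25)`.
#'
#' @return Data frame with columns `lower` and `upper` (both inclusive, in
#'   whole years) defining the bins in ascending order.
#' @examples
#' age_bins()
#' @export
age_bins <- function() {
  lower <- c(13, seq(20, 75, by = 5), 80)
  upper <- c(19, seq(24, 79, by = 5), 89)
  data.frame(lower = lower, upper = upper)
}

# index of the bin covering each age; NA where uncovered
assign_age_bin <- function(age, bins) {
  idx <- rep(NA_integer_, length(age))
  for (b in seq_len(nrow(bins))) {
    hit <- age >= bins$lower[b] & age < bins$upper[b] + 1
    idx[hit] <- b
  }
  idx
}

#' Build age-binned normative tables for a cohort
#'
#' For every subtest and every age bin, applies the rank-based inverse
#' normal transformation ([rank_inverse_normal()]) to the observed raw
#' scores and stores the resulting raw-to-scaled lookup as a step function.
#' The scaled subtest scores of the norming cohort are then summed per
#' subject and the same transformation is applied to the sums to build the
#' battery-level aggregate table that maps a sum score to the Grand Index.
#'
#' @param cohort Cohort data frame (one row per subject-session) with an
#'   `age` column and one raw-score column per subtest. Typically only
#'   baseline (session 1) rows of the normative sample are supplied.
#' @param bins Age-bin scheme as returned by [age_bins()].
#' @param subtests Subtest registry (see [ncpt_subtests()]).
#' @param position Plotting position passed to [rank_inverse_normal()].
#' @param target_mean,target_sd Normative scale parameters.
#' @return An object of class `norm_table_set`: a list with elements
#'   `tables` (one `norm_table` per subtest, each holding per-bin sorted
#'   unique raw values and their scaled values), `aggregate` (the
#'   sum-to-Grand-Index step function), `bins`, and the scale parameters.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 400), seed = 1)
#' nt <- build_norm_tables(cohort)
#' nt
#' @export
build_norm_tables <- function(cohort, bins = age_bins(),
                              subtests = ncpt_subtests(),
                              position = "hazen",
                              target_mean = 100, target_sd = 15) {
  stopifnot(is.data.frame(cohort), "age" %in% names(cohort))
  missing_cols <- setdiff(subtests$subtest, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing raw-score columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bin_idx <- assign_age_bin(cohort$age, bins)
  if (anyNA(bin_idx))
    stop("some ages fall outside every age bin (supported range ",
         bins$lower[1], "-", bins$upper[nrow(bins)], ")", call. = FALSE)
  counts <- tabulate(bin_idx, nbins = nrow(bins))
  if (any(counts < 2L)) {
    bad <- which(counts < 2L)[1]
    stop(sprintf("age bin %d-%d holds %d subject(s); at least 2 are required",
                 bins$lower[bad], bins$upper[bad], counts[bad]), call. = FALSE)
  }

  tables <- vector("list", nrow(subtests))
  names(tables) <- subtests$subtest
  for (j in seq_len(nrow(subtests))) {
    col <- subtests$subtest[j]
    dir <- subtests$direction[j]
    per_bin <- vector("list", nrow(bins))
    for (b in seq_len(nrow(bins))) {
      raw <- cohort[[col]][bin_idx == b]
      if (any(!is.finite(raw)))
        stop("non-finite raw score in subtest ", col, call. = FALSE)
      scaled <- rank_inverse_normal(raw, direction = dir, position = position,
                                    target_mean = target_mean,
                                    target_sd = target_sd)
      o <- order(raw)
      keep <- !duplicated(raw[o])      # ties map to one (raw, scaled) pair
      per_bin[[b]] <- list(raw = raw[o][keep], scaled = scaled[o][keep])
    }
    tables[[j]] <- structure(
      list(subtest = col, direction = dir, bins = per_bin),
      class = "norm_table"
    )
  }
  set <- structure(
    list(tables = tables, aggregate = NULL, bins = bins,
         subtests = subtests, position = position,
         target_mean = target_mean, target_sd = target_sd),
    class = "norm_table_set"
  )
  # battery-level aggregate: rank-INT of the norming cohort's sum scores
  scaled <- score_subtests_only(cohort, set)
  sums <- rowSums(scaled)
  agg_scaled <- rank_inverse_normal(sums, position = position,
                                    target_mean = target_mean,
                                    target_sd = target_sd)
  o <- order(sums)
  keep <- !duplicated(sums[o])
  set$aggregate <- list(raw = sums[o][keep], scaled = agg_scaled[o][keep])
  set
}

# step-function lookup: x gets the scaled value of the nearest observed raw
# value in the worse-performance direction; beyond the observed range the
# extreme scaled value is used. Monotone by construction.
lookup_step <- function(raw_sorted, scaled_sorted, x, direction = "higher_better") {
  perf_grid <- if (direction == "lower_better") rev(-raw_sorted) else raw_sorted
  perf_scaled <- if (direction == "lower_better") rev(scaled_sorted) else scaled_sorted
  perf_x <- if (direction == "lower_better") -x else x
  idx <- findInterval(perf_x, perf_grid)   # largest grid value <= perf_x
  idx[idx < 1L] <- 1L                      # clamp below observed range
  perf_scaled[idx]
}

# scaled subtest scores only (no aggregate); errors mirror score_subjects
score_subtests_only <- function(cohort, set) {
  bins <- set$bins
  bin_idx <- assign_age_bin(cohort$age, bins)
  if (anyNA(bin_idx))
    stop("some ages are not covered by the normative tables", call. = FALSE)
  out <- matrix(NA_real_, nrow(cohort), nrow(set$subtests))
  colnames(out) <- paste0("scaled_", set$subtests$subtest)
  for (j in seq_len(nrow(set$subtests))) {
    col <- set$subtests$subtest[j]
    if (anyNA(cohort[[col]]))
      stop("incomplete battery: missing raw scores in ", col, call. = FALSE)
    tab <- set$tables[[col]]
    for (b in unique(bin_idx)) {
      rows <- bin_idx == b
      pb <- tab$bins[[b]]
      out[rows, j] <- lookup_step(pb$raw, pb$scaled, cohort[[col]][rows],
                                  direction = tab$direction)
    }
  }
  out
}

#' Score a cohort against normative tables
#'
#' Looks up each subject's scaled subtest scores in the age-binned tables,
#' sums them, and converts the sum to the Grand Index through the
#' battery-level aggregate table. Raw values not observed when the tables
#' were built are mapped to the scaled value of the nearest observed raw
#' value in the worse-performance direction; values beyond the observed
#' range take the extreme scaled value of the bin. Re-scoring the norming
#' cohort through its own tables reproduces its scaled scores exactly.
#'
#' @param cohort Cohort data frame; every subject must have an age covered
#'   by the tables and a complete set of raw subtest scores.
#' @param tables A `norm_table_set` from [build_norm_tables()] (or reloaded
#'   via [read_norm_tables()]).
#' @param aggregate Optional replacement sum-to-Grand-Index table (a list
#'   with `raw` and `scaled`); defaults to the one stored in `tables`.
#' @return A data frame with the identifying columns of `cohort` that are
#'   present (`subject_id`, `session`, `age`, `group`), one
#'   `scaled_<subtest>` column per subtest, `sum_score`, and `grand_index`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 400), seed = 1)
#' nt <- build_norm_tables(cohort)
#' head(score_subjects(cohort, nt))
#' @export
score_subjects <- function(cohort, tables, aggregate = NULL) {
  stopifnot(inherits(tables, "norm_table_set"))
  if (is.null(aggregate)) aggregate <- tables$aggregate
  if (is.null(aggregate))
    stop("no aggregate sum-to-Grand-Index table available", call. = FALSE)
  scaled <- score_subtests_only(cohort, tables)
  sums <- rowSums(scaled)
  gi <- lookup_step(aggregate$raw, aggregate$scaled, sums)
  id_cols <- intersect(c("subject_id", "session", "age", "group"),
                       names(cohort))
  out <- cbind(cohort[id_cols], as.data.frame(scaled),
               sum_score = sums, grand_index = gi)
  rownames(out) <- NULL
  out
}

#' Non-age-normed sum scores
#'
#' Applies the rank-based inverse normal transformation per subtest over
#' the whole cohort at once (a single bin spanning all ages) and sums the
#' resulting scaled scores per subject. Because age is not removed, these
#' sums retain age-related performance differences, which is what makes
#' them suitable as the outcome of a demographic-effect regression.
#'
#' @inheritParams build_norm_tables
#' @return Data frame with the identifying/demographic columns of `cohort`
#'   that are present, per-subtest `scaled_<subtest>` columns, and
#'   `sum_score`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 300), seed = 1)
#' head(scale_without_age(cohort)$sum_score)
#' @export
scale_without_age <- function(cohort, subtests = ncpt_subtests(),
                              position = "hazen",
                              target_mean = 100, target_sd = 15) {
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 2)
  scaled <- matrix(NA_real_, nrow(cohort), nrow(subtests))
  colnames(scaled) <- paste0("scaled_", subtests$subtest)
  for (j in seq_len(nrow(subtests))) {
    col <- subtests$subtest[j]
    scaled[, j] <- rank_inverse_normal(cohort[[col]],
                                       direction = subtests$direction[j],
                                       position = position,
                                       target_mean = target_mean,
                                       target_sd = target_sd)
  }
  id_cols <- intersect(c("subject_id", "session", "age", "gender",
                         "education_years", "group"), names(cohort))
  out <- cbind(cohort[id_cols], as.data.frame(scaled),
               sum_score = rowSums(scaled))
  rownames(out) <- NULL
  out
}

#' @export
print.norm_table_set <- function(x, ...) {
  cat("Normative table set:", length(x$tables), "subtests,",
      nrow(x$bins), "age bins (",
      x$bins$lower[1], "-", x$bins$upper[nrow(x$bins)], " y)\n", sep = " ")
  cat("  scale: mean", x$target_mean, "/ SD", x$target_sd,
      "; plotting position:", x$position, "\n")
  n_raw <- vapply(x$tables, function(t)
    sum(vapply(t$bins, function(b) length(b$raw), 1L)), 1L)
  cat("  stored raw values per subtest:\n")
  print(n_raw)
  invisible(x)
}
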