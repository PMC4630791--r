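# paired t as a one-sample t on the vector of pair differences; the
# all-zero case is defined as t = 0, p = 1
paired_t <- function(diffs) {
  n <- length(diffs)
  if (n == 0)
    return(list(t = NA_real_, df = NA_integer_, p = NA_real_))
  m <- mean(diffs)
  s <- stats::sd(diffs)
  if (n < 2 || s == 0) {
    t <- if (isTRUE(all.equal(m, 0))) 0 else sign(m) * Inf
    return(list(t = t, df = n - 1, p = if (t == 0) 1 else 0))
  }
  t <- m / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

match_key <- function(df, keys, age_discretize) {
  parts <- lapply(keys, function(k) {
    v <- df[[k]]
    if (k == "age") v <- age_discretize(v)
    if (is.numeric(v)) v <- format(v, trim = TRUE)
    v
  })
  do.call(paste, c(parts, sep = "\r"))
}

#' Exact case-control matching without replacement
#'
#' Walks the cases in the given order; each case consumes one control that
#' agrees exactly on every matching key (after discretization: age is
#' truncated to integer years by default, gender and education are
#' compared as recorded). A consumed control is never reused. Cases with
#' no remaining exact match are dropped and counted. The score difference
#' (control minus case) is summarized by its mean and a paired t-test.
#'
#' @param cases,control_pool Data frames containing the matching keys and
#'   the score column.
#' @param keys Matching keys (default age, gender, education years).
#' @param score Name of the score column compared between matched pairs
#'   (default `"grand_index"`).
#' @param tie_break How to choose among equally eligible controls:
#'   `"random"` (uniform, from the current RNG stream; default) or
#'   `"first"` (first remaining in pool order).
#' @param age_discretize Function applied to the age key before comparison
#'   (default [floor()]).
#' @return Object of class `match_run`: `pairs` (case id/row, control
#'   id/row, both scores), `n_matched`, `n_unmatched`,
#'   `mean_difference` (control - case), `t`, `df`, `p`.
#' @examples
#' pool <- data.frame(subject_id = paste0("C", 1:6), age = c(60, 60, 61, 60, 70, 70),
#'                    gender = c("F", "M", "F", "F", "M", "M"),
#'                    education_years = 16, grand_index = c(101, 99, 96, 103, 98, 97))
#' case <- data.frame(subject_id = "P1", age = 60, gender = "F",
#'                    education_years = 16, grand_index = 88)
#' exact_match(case, pool, tie_break = "first")
#' @export
exact_match <- function(cases, control_pool,
                        keys = c("age", "gender", "education_years"),
                        score = "grand_index",
                        tie_break = c("random", "first"),
                        age_discretize = floor) {
  tie_break <- match.arg(tie_break)
  if (nrow(control_pool) == 0) stop("empty control pool", call. = FALSE)
  for (k in c(keys, score)) {
    if (!k %in% names(cases) || !k %in% names(control_pool))
      stop("column '", k, "' must be present in both tables", call. = FALSE)
  }
  ckey <- match_key(cases, keys, age_discretize)
  pkey <- match_key(control_pool, keys, age_discretize)
  avail <- split(seq_len(nrow(control_pool)), pkey)

  n <- nrow(cases)
  ctrl_row <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    cand <- avail[[ckey[i]]]
    if (is.null(cand) || length(cand) == 0L) next
    pick <- if (tie_break == "random" && length(cand) > 1L)
      cand[sample.int(length(cand), 1L)] else cand[1L]
    ctrl_row[i] <- pick
    avail[[ckey[i]]] <- setdiff(cand, pick)
  }
  matched <- !is.na(ctrl_row)
  case_score <- cases[[score]][matched]
  control_score <- control_pool[[score]][ctrl_row[matched]]
  diffs <- control_score - case_score
  tt <- paired_t(diffs)
  id_of <- function(df, rows) {
    if ("subject_id" %in% names(df)) df$subject_id[rows] else rows
  }
  pairs <- data.frame(
    case_id = id_of(cases, which(matched)),
    control_id = id_of(control_pool, ctrl_row[matched]),
    case_score = case_score, control_score = control_score,
    difference = diffs, stringsAsFactors = FALSE
  )
  structure(list(pairs = pairs, n_matched = sum(matched),
                 n_unmatched = sum(!matched),
                 mean_difference = mean(diffs),
                 t = tt$t, df = tt$df, p = tt$p),
            class = "match_run")
}

#' @export
print.match_run <- function(x, ...) {
  cat(sprintf(
    "Exact match: %d pairs (%d cases unmatched); mean difference %.3f, paired t(%d) = %.3f, p = %.3g\n",
    x$n_matched, x$n_unmatched, x$mean_difference, x$df, x$t, x$p))
  invisible(x)
}

#' Repeated exact matching with shuffled case order
#'
#' Exact matching without replacement is sensitive to the order in which
#' cases claim controls, so the procedure is repeated with the case order
#' (and the random tie-breaks among eligible controls) reshuffled on an
#' independent stream each time, yielding a distribution of matched-group
#' differences rather than a single estimate.
#'
#' @inheritParams exact_match
#' @param n_repeats Number of repeats (default 1000).
#' @param seed Optional integer seed; results are bit-reproducible given
#'   it.
#' @return Object of class `repeated_match_summary`: `runs` (per-run mean
#'   difference, t, p, pairs), `mean_difference` (min/mean/max across
#'   runs), `t_range`, `n_repeats`.
#' @examples
#' pool <- data.frame(age = rep(60:64, each = 20), gender = "F",
#'                    education_years = 16, grand_index = rnorm(100, 100, 15))
#' case <- data.frame(age = c(60, 62), gender = "F", education_years = 16,
#'                    grand_index = c(85, 90))
#' repeated_matched_comparison(case, pool, n_repeats = 10, seed = 1)
#' @export
repeated_matched_comparison <- function(cases, control_pool,
                                        keys = c("age", "gender", "education_years"),
                                        score = "grand_index",
                                        n_repeats = 1000, seed = NULL,
                                        age_discretize = floor) {
  if (!is.null(seed)) set.seed(seed)
  runs <- vector("list", n_repeats)
  skipped <- 0L
  for (r in seq_len(n_repeats)) {
    ord <- sample.int(nrow(cases))
    run <- exact_match(cases[ord, , drop = FALSE], control_pool,
                       keys = keys, score = score, tie_break = "random",
                       age_discretize = age_discretize)
    if (run$n_matched == 0L) {
      warning("run ", r, " produced no matched pairs; skipped",
              call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    runs[[r]] <- data.frame(run = r, mean_difference = run$mean_difference,
                            t = run$t, p = run$p, n_pairs = run$n_matched)
  }
  runs <- do.call(rbind, runs)
  structure(list(
    runs = runs,
    mean_difference = c(min = min(runs$mean_difference),
                        mean = mean(runs$mean_difference),
                        max = max(runs$mean_difference)),
    t_range = range(runs$t),
    n_repeats = n_repeats - skipped
  ), class = "repeated_match_summary")
}

#' @export
print.repeated_match_summary <- function(x, ...) {
  cat(sprintf(
    "Repeated matching (%d runs): mean difference %.2f (range %.2f to %.2f), t range [%.2f, %.2f]\n",
    x$n_repeats, x$mean_difference["mean"], x$mean_difference["min"],
    x$mean_difference["max"], x$t_range[1], x$t_range[2]))
  invisible(x)
}
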