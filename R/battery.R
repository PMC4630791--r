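#' Subtest registry for the default eight-subtest battery
#'
#' The battery comprises eight subtests spanning attention/psychomotor speed
#' (Trail Making A and B, completion time in seconds), processing speed
#' (Digit Symbol Coding), visual short-term and working memory (Forward and
#' Reverse Memory Span), fluid reasoning (Progressive Matrices), numerical
#' problem solving (Arithmetic Reasoning) and cognitive flexibility
#' (Grammatical Reasoning). For the two Trail Making subtests the raw
#' measure is completion time, so smaller values indicate better
#' performance; all other subtests are counts where larger is better.
#'
#' @return A data frame with one row per subtest and columns `subtest`
#'   (short identifier used as a raw-score column name in cohort tables),
#'   `label` (human-readable name) and `direction`
#'   (`"higher_better"` or `"lower_better"`).
#' @examples
#' ncpt_subtests()
#' @export
ncpt_subtests <- function() {
  data.frame(
    subtest = c("trail_a_s", "trail_b_s", "fwd_span", "rev_span",
                "digit_symbol", "matrices", "arithmetic", "grammatical"),
    label = c("Trail Making A", "Trail Making B", "Forward Memory Span",
              "Reverse Memory Span", "Digit Symbol Coding",
              "Progressive Matrices", "Arithmetic Reasoning",
              "Grammatical Reasoning"),
    direction = c("lower_better", "lower_better", "higher_better",
                  "higher_better", "higher_better", "higher_better",
                  "higher_better", "higher_better"),
    stringsAsFactors = FALSE
  )
}

# columns every cohort table must carry, beyond the raw-score columns
cohort_meta_columns <- function() {
  c("subject_id", "age", "gender", "education_years", "group", "session")
}

cohort_required_columns <- function(subtests = ncpt_subtests()) {
  c(cohort_meta_columns(), subtests$subtest)
}
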