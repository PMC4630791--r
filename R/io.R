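NORM_TABLE_FORMAT_VERSION <- "1.0"

#' Read a cohort table from CSV/TSV
#'
#' Reads a delimited subject-by-session table (comma-delimited by default;
#' tab-delimited for `.tsv`/`.tab` files), validates the schema, and types
#' the columns. The literal `"ND"` (not disclosed) is parsed as missing
#' for gender and education. Rows violating basic validity (age outside
#' 13-89, non-positive completion times, negative counts, unparseable
#' numbers) are rejected with line-numbered diagnostics. Missing
#' engagement counters default to 0 with a warning.
#'
#' @param path File path.
#' @param subtests Subtest registry defining the raw-score columns.
#' @param max_errors Maximum number of row diagnostics to show.
#' @return A validated cohort data frame.
#' @export
read_cohort <- function(path, subtests = ncpt_subtests(), max_errors = 10) {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = "character",
                           na.strings = c("NA", ""))
  required <- cohort_required_columns(subtests)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("schema error: missing required column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  to_num <- function(v) {
    v[v == "ND"] <- NA
    suppressWarnings(as.numeric(v))
  }
  out <- data.frame(subject_id = raw$subject_id, stringsAsFactors = FALSE)
  out$age <- to_num(raw$age)
  out$gender <- ifelse(is.na(raw$gender), "ND", raw$gender)
  out$education_years <- to_num(raw$education_years)
  out$group <- raw$group
  out$session <- suppressWarnings(as.integer(raw$session))
  for (eng in c("iti_days", "days_played", "games_played")) {
    if (eng %in% names(raw)) {
      out[[eng]] <- to_num(raw[[eng]])
    } else {
      warning("engagement column '", eng, "' absent; defaulting to 0",
              call. = FALSE)
      out[[eng]] <- 0
    }
  }
  for (col in subtests$subtest) out[[col]] <- to_num(raw[[col]])

  problems <- character(0)
  note <- function(rows, what) {
    if (any(rows, na.rm = TRUE))
      problems <<- c(problems,
                     paste0("line ", which(rows) + 1L, ": ", what))
  }
  note(is.na(out$age) | out$age < 13 | out$age >= 90,
       "age missing or outside the normative range 13-89")
  note(!out$gender %in% c("F", "M", "ND"), "unrecognized gender code")
  note(is.na(out$session) | !out$session %in% c(1L, 2L),
       "session must be 1 or 2")
  for (j in seq_len(nrow(subtests))) {
    col <- subtests$subtest[j]
    bad <- is.na(out[[col]]) & !is.na(raw[[col]])
    note(bad, paste0("unparseable value in ", col))
    if (subtests$direction[j] == "lower_better") {
      note(!is.na(out[[col]]) & out[[col]] <= 0,
           paste0("non-positive completion time in ", col))
    } else {
      note(!is.na(out[[col]]) & out[[col]] < 0,
           paste0("negative count in ", col))
    }
  }
  if (length(problems)) {
    shown <- utils::head(problems, max_errors)
    stop("invalid rows (", length(problems), " problem(s)):\n  ",
         paste(shown, collapse = "\n  "),
         if (length(problems) > max_errors) "\n  ..." else "",
         call. = FALSE)
  }
  dup <- duplicated(out[c("subject_id", "session")])
  if (any(dup))
    stop("duplicate subject_id/session: ",
         paste(unique(out$subject_id[dup]), collapse = ", "), call. = FALSE)
  out
}

#' Write a cohort table to CSV/TSV
#'
#' Counterpart of [read_cohort()]; missing values are written as `ND`.
#'
#' @param cohort Cohort data frame.
#' @param path Output path; `.tsv` selects tab delimiting.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(cohort, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "ND")
  invisible(path)
}

#' Serialize normative tables to JSON
#'
#' Writes a `norm_table_set` (per-subtest, per-age-bin raw/scaled pairs
#' plus the battery-level aggregate table) as versioned JSON. Numeric
#' values are written at full precision so that a read/write round trip
#' is lossless and scoring through reloaded tables is bit-identical.
#'
#' @param set A `norm_table_set` from [build_norm_tables()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_norm_tables <- function(set, path) {
  stopifnot(inherits(set, "norm_table_set"))
  obj <- list(
    format_version = NORM_TABLE_FORMAT_VERSION,
    target_mean = set$target_mean, target_sd = set$target_sd,
    position = set$position,
    bins = list(lower = set$bins$lower, upper = set$bins$upper),
    subtests = lapply(set$tables, function(t) list(
      subtest = t$subtest, direction = t$direction,
      bins = lapply(seq_along(t$bins), function(b) list(
        lower = set$bins$lower[b], upper = set$bins$upper[b],
        raw = t$bins[[b]]$raw, scaled = t$bins[[b]]$scaled
      ))
    )),
    aggregate = set$aggregate
  )
  # I(17) requests 17 significant digits, enough to round-trip doubles
  # exactly; the scoring step functions are sensitive to last-ulp drift
  json <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read normative tables from JSON
#'
#' @param path Path to a file written by [write_norm_tables()].
#' @return A `norm_table_set`.
#' @export
read_norm_tables <- function(path) {
  obj <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE),
    error = function(e) stop("cannot parse norm-table file: ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(obj$format_version) ||
      !identical(obj$format_version, NORM_TABLE_FORMAT_VERSION))
    stop("incompatible norm-table format version: found '",
         obj$format_version %||% "<none>", "', expected '",
         NORM_TABLE_FORMAT_VERSION, "'", call. = FALSE)
  bins <- data.frame(lower = as.numeric(obj$bins$lower),
                     upper = as.numeric(obj$bins$upper))
  tables <- lapply(obj$subtests, function(t) structure(
    list(subtest = t$subtest, direction = t$direction,
         bins = lapply(t$bins, function(b)
           list(raw = as.numeric(b$raw), scaled = as.numeric(b$scaled)))),
    class = "norm_table"
  ))
  names(tables) <- vapply(tables, `[[`, "", "subtest")
  reg <- ncpt_subtests()
  subtests <- reg[match(names(tables), reg$subtest), ]
  structure(list(
    tables = tables,
    aggregate = list(raw = as.numeric(obj$aggregate$raw),
                     scaled = as.numeric(obj$aggregate$scaled)),
    bins = bins, subtests = subtests, position = obj$position,
    target_mean = obj$target_mean, target_sd = obj$target_sd
  ), class = "norm_table_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a simulation configuration from YAML or JSON
#'
#' Fields mirror the arguments of [sim_config()]; unknown fields are an
#' error. `loadings` may be given as a list of rows. YAML input requires
#' the `yaml` package.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs require the 'yaml' package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  allowed <- names(formals(sim_config))
  unknown <- setdiff(names(obj), allowed)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(obj$loadings)) {
    obj$loadings <- do.call(rbind, lapply(obj$loadings, as.numeric))
    rownames(obj$loadings) <- ncpt_subtests()$subtest
  }
  if (!is.null(obj$retest_reliability))
    obj$retest_reliability <- unlist(obj$retest_reliability)
  if (!is.null(obj$group_profiles))
    obj$group_profiles <- lapply(obj$group_profiles, unlist)
  do.call(sim_config, obj)
}
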