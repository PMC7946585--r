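#' Read and write cohort tables
#'
#' Three CSV schemas carry a cohort: daily engagement logs, baseline
#' covariates, and longitudinal visits. Files are UTF-8, comma-separated,
#' header required, missing values as empty fields, booleans serialized as
#' 0/1. Readers validate every row and fail with row-numbered diagnostics;
#' the write-then-read round trip is the identity.
#'
#' @param path CSV file path.
#' @param study_days upper bound for the `day` column (default 91).
#' @return readers return validated tibbles; writers return `path` invisibly.
#' @name cohort_io
NULL

LOG_COLS <- c("participant_id", "day", "smbg_recorded", "diet_recorded",
              "exercise_recorded", "messages_sent", "messages_read")
BASELINE_COLS <- c("participant_id", "age", "sex", "bmi", "sbp", "dbp",
                   "hba1c_baseline", "total_chol", "tg", "hdl", "ldl",
                   "smoker", "drinker", "dm_duration", "insulin",
                   "antihypertensive", "antidyslipidemic", "sdsca_diet",
                   "sdsca_exercise", "sdsca_glucose", "sdsca_foot", "ads_total")
VISIT_COLS <- c("participant_id", "visit_month", VISIT_OUTCOMES, "observed")

read_checked <- function(path, required, col_types) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- readr::read_csv(path, col_types = col_types, na = c("", "NA"),
                       progress = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(paste0("schema error in ", basename(path), ": missing column(s) ",
                 paste(missing, collapse = ", ")))
  }
  x[, required]
}

row_fail <- function(path, rows, field, why) {
  abort(paste0("validation error in ", basename(path), ", field `", field,
               "`: ", why, " (row ", paste(head(rows, 5), collapse = ", "),
               if (length(rows) > 5) ", ..." else "", ")"))
}

#' @rdname cohort_io
#' @export
read_logs <- function(path, study_days = 91) {
  x <- read_checked(path, LOG_COLS,
                    readr::cols(participant_id = "c", .default = "d"))
  for (fl in c("smbg_recorded", "diet_recorded", "exercise_recorded")) {
    bad <- which(!x[[fl]] %in% c(0, 1))
    if (length(bad) > 0) row_fail(path, bad, fl, "must be 0 or 1")
    x[[fl]] <- x[[fl]] == 1
  }
  bad <- which(is.na(x$day) | x$day < 1 | x$day > study_days | x$day != trunc(x$day))
  if (length(bad) > 0) row_fail(path, bad, "day", paste0("must be an integer in 1..", study_days))
  x$day <- as.integer(x$day)
  for (mc in c("messages_sent", "messages_read")) {
    bad <- which(is.na(x[[mc]]) | x[[mc]] < 0 | x[[mc]] != trunc(x[[mc]]))
    if (length(bad) > 0) row_fail(path, bad, mc, "must be a non-negative integer")
    x[[mc]] <- as.integer(x[[mc]])
  }
  bad <- which(x$messages_read > x$messages_sent)
  if (length(bad) > 0) row_fail(path, bad, "messages_read", "exceeds messages_sent")
  dup <- which(duplicated(x[, c("participant_id", "day")]))
  if (length(dup) > 0) row_fail(path, dup, "participant_id/day", "duplicate record")
  x
}

#' @rdname cohort_io
#' @export
read_baseline <- function(path) {
  x <- read_checked(path, BASELINE_COLS,
                    readr::cols(participant_id = "c", sex = "c", .default = "d"))
  bad <- which(!x$sex %in% c("male", "female"))
  if (length(bad) > 0) row_fail(path, bad, "sex", "must be 'male' or 'female'")
  for (fl in c("smoker", "drinker", "insulin", "antihypertensive", "antidyslipidemic")) {
    bad <- which(!x[[fl]] %in% c(0, 1))
    if (length(bad) > 0) row_fail(path, bad, fl, "must be 0 or 1")
    x[[fl]] <- x[[fl]] == 1
  }
  bad <- which(is.na(x$hba1c_baseline) | x$hba1c_baseline <= 0)
  if (length(bad) > 0) row_fail(path, bad, "hba1c_baseline", "must be > 0")
  for (fl in c("age", "dm_duration")) {
    bad <- which(!is.na(x[[fl]]) & x[[fl]] < 0)
    if (length(bad) > 0) row_fail(path, bad, fl, "must be >= 0")
  }
  dup <- which(duplicated(x$participant_id))
  if (length(dup) > 0) row_fail(path, dup, "participant_id", "duplicate record")
  x
}

#' @rdname cohort_io
#' @export
read_visits <- function(path) {
  x <- read_checked(path, VISIT_COLS,
                    readr::cols(participant_id = "c", .default = "d"))
  bad <- which(!x$visit_month %in% VISIT_MONTHS)
  if (length(bad) > 0) {
    row_fail(path, bad, "visit_month",
             paste0("must be one of ", paste(VISIT_MONTHS, collapse = "/")))
  }
  x$visit_month <- as.integer(x$visit_month)
  bad <- which(!x$observed %in% c(0, 1))
  if (length(bad) > 0) row_fail(path, bad, "observed", "must be 0 or 1")
  x$observed <- x$observed == 1
  dup <- which(duplicated(x[, c("participant_id", "visit_month")]))
  if (length(dup) > 0) row_fail(path, dup, "participant_id/visit_month", "duplicate record")
  base <- x[x$visit_month == 0L, ]
  missing_base <- setdiff(unique(x$participant_id), base$participant_id)
  bad_base <- base$participant_id[!base$observed | is.na(base$hba1c)]
  if (length(missing_base) > 0 || length(bad_base) > 0) {
    abort(paste0("validation error in ", basename(path),
                 ": participants without an observed baseline HbA1c: ",
                 paste(head(c(missing_base, bad_base), 5), collapse = ", ")))
  }
  x
}

serialize_bools <- function(x) {
  x[] <- lapply(x, function(col) if (is.logical(col)) as.integer(col) else col)
  x
}

#' @param x table to write (logs, baseline, or visits).
#' @rdname cohort_io
#' @export
write_logs <- function(x, path) {
  readr::write_csv(serialize_bools(x[, LOG_COLS]), path, na = "")
  invisible(path)
}

#' @rdname cohort_io
#' @export
write_baseline <- function(x, path) {
  readr::write_csv(serialize_bools(x[, BASELINE_COLS]), path, na = "")
  invisible(path)
}

#' @rdname cohort_io
#' @export
write_visits <- function(x, path) {
  readr::write_csv(serialize_bools(x[, VISIT_COLS]), path, na = "")
  invisible(path)
}
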