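#' Last-observation-carried-forward imputation
#'
#' Replaces every missing post-baseline outcome value with the participant's
#' most recent earlier observed value of the same outcome. Observed values are
#' never altered and baseline rows are never touched, so the operation is
#' idempotent. Self-report scales (SDSCA subscales, ADS) are structurally
#' absent at month 3 — not missing — and are left untouched there.
#'
#' @param visits visit tibble (see [read_visits()] for the schema).
#' @return the visit tibble with missing values filled; which cells were
#'   imputed is recorded in the `"imputed"` attribute, a logical tibble with
#'   one column per outcome aligned row-for-row with the result.
#' @export
locf_impute <- function(visits) {
  visits <- dplyr::arrange(visits, .data$participant_id, .data$visit_month)
  imputed <- visits[, VISIT_OUTCOMES]
  imputed[] <- lapply(imputed, function(col) rep(FALSE, length(col)))

  base <- visits[visits$visit_month == 0L, ]
  no_base <- setdiff(unique(visits$participant_id), base$participant_id)
  if (length(no_base) > 0) {
    abort(paste0("locf_impute: participant ", no_base[1], " has no baseline visit"))
  }
  for (o in VISIT_OUTCOMES) {
    bad <- base$participant_id[is.na(base[[o]])]
    if (length(bad) > 0) {
      abort(paste0("locf_impute: participant ", bad[1],
                   " has no baseline value for outcome `", o, "`"))
    }
  }

  # Rows are sorted participant-major with the (always observed) baseline
  # first in each block, so a cummax last-non-missing index never carries a
  # value across participants.
  for (o in VISIT_OUTCOMES) {
    carry <- !(visits$visit_month == 3L & o %in% SCALE_OUTCOMES)
    vals <- visits[[o]][carry]
    idx <- seq_along(vals)
    idx[is.na(vals)] <- 0L
    filled <- vals[cummax(idx)]
    imputed[[o]][carry] <- is.na(vals) & !is.na(filled)
    visits[[o]][carry] <- filled
  }
  attr(visits, "imputed") <- imputed
  visits
}

#' Change from baseline for one outcome
#'
#' `delta(M) = value(M) - value(0)` for each follow-up month M present in the
#' table. Missing values propagate to missing deltas; cells filled by
#' [locf_impute()] carry `imputed = TRUE`.
#'
#' @param visits visit tibble, optionally LOCF-completed.
#' @param outcome outcome column name (default `"hba1c"`).
#' @return a tibble: `participant_id`, `visit_month`, `outcome`, `delta`,
#'   `imputed`.
#' @export
change_from_baseline <- function(visits, outcome = "hba1c") {
  if (!outcome %in% VISIT_OUTCOMES) {
    abort(paste0("change_from_baseline: unknown outcome `", outcome, "`"))
  }
  imputed <- attr(visits, "imputed")
  flag <- if (is.null(imputed)) rep(FALSE, nrow(visits)) else imputed[[outcome]]
  base <- visits[visits$visit_month == 0L, c("participant_id", outcome)]
  names(base)[2] <- ".baseline"
  fu <- visits[visits$visit_month != 0L, ]
  flag <- flag[visits$visit_month != 0L]
  fu <- dplyr::left_join(fu, base, by = "participant_id")
  delta <- fu[[outcome]] - fu$.baseline
  tibble::tibble(
    participant_id = fu$participant_id,
    visit_month = fu$visit_month,
    outcome = outcome,
    delta = delta,
    imputed = flag
  )
}

#' HbA1c reduction rate
#'
#' `100 * (followup - baseline) / baseline`, in percent of the baseline
#' value; negative values indicate improvement.
#'
#' @param baseline_hba1c baseline HbA1c (%), strictly positive.
#' @param followup_hba1c follow-up HbA1c (%).
#' @return signed percent reduction rate (vectorized).
#' @examples
#' reduction_rate(8.0, 7.2) # -10
#' @export
reduction_rate <- function(baseline_hba1c, followup_hba1c) {
  if (any(!is.na(baseline_hba1c) & baseline_hba1c <= 0)) {
    abort("reduction_rate: baseline HbA1c must be > 0")
  }
  100 * (followup_hba1c - baseline_hba1c) / baseline_hba1c
}
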