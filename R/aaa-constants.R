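# Engagement components making up the composite score, in canonical order.
UUS_COMPONENTS <- c("smbg_days", "diet_days", "exercise_days", "read_rate")

# Follow-up visits (months); month 0 is baseline.
VISIT_MONTHS <- c(0L, 3L, 6L, 12L)

# Outcome columns carried on the longitudinal visit table.
VISIT_OUTCOMES <- c(
  "hba1c", "bmi", "sbp", "dbp", "total_chol", "tg", "hdl", "ldl",
  "sdsca_diet", "sdsca_exercise", "sdsca_glucose", "sdsca_foot", "ads_total"
)

# Self-report scales are not administered at the 3-month visit; they are
# structurally absent there (never imputed).
SCALE_OUTCOMES <- c(
  "sdsca_diet", "sdsca_exercise", "sdsca_glucose", "sdsca_foot", "ads_total"
)

#' Derive a reproducible sub-stream seed for a pipeline stage
#'
#' One user-facing seed drives every stochastic stage; each stage mixes the
#' master seed with a stage label so stages are decoupled (adding participants
#' to one stage does not shift the draws of another) yet fully determined.
#'
#' @param seed master integer seed.
#' @param stage character stage label.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + h * 16807) %% 2147483647)
}
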