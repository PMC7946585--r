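#' Summarize engagement over the scoring window
#'
#' Collapses daily logs to the four UUS components: days with at least one
#' SMBG, diet, or exercise record within days 1..`window_days`, and the
#' message reading rate, `100 * sum(read) / sum(sent)`, over the same window.
#' A participant who was sent no messages (impossible under the twice-weekly
#' coaching schedule, but permitted by the schema) gets a read rate of 0 and
#' is flagged via the `no_messages` column.
#'
#' @param logs daily log tibble (see [read_logs()] for the schema).
#' @param window_days scoring window length in days (default 91, the first
#'   three months).
#' @return a tibble with one row per participant: `participant_id`,
#'   `smbg_days`, `diet_days`, `exercise_days`, `messages_sent`,
#'   `messages_read`, `read_rate`, `no_messages`.
#' @export
summarize_engagement <- function(logs, window_days = 91) {
  if (nrow(logs) == 0) abort("summarize_engagement: no participants in logs")
  win <- dplyr::filter(logs, .data$day >= 1, .data$day <= window_days)
  out <- dplyr::summarise(
    dplyr::group_by(win, .data$participant_id),
    smbg_days = sum(.data$smbg_recorded),
    diet_days = sum(.data$diet_recorded),
    exercise_days = sum(.data$exercise_recorded),
    messages_sent = sum(.data$messages_sent),
    messages_read = sum(.data$messages_read),
    .groups = "drop"
  )
  out$no_messages <- out$messages_sent == 0
  out$read_rate <- ifelse(out$no_messages, 0,
                          100 * out$messages_read / out$messages_sent)
  if (any(out$no_messages)) {
    warn(paste0(sum(out$no_messages),
                " participant(s) were sent no messages; read_rate set to 0"))
  }
  out[, c("participant_id", "smbg_days", "diet_days", "exercise_days",
          "messages_sent", "messages_read", "read_rate", "no_messages")]
}

#' Empirical tertile cut-points for one engagement component
#'
#' Cuts are the 1/3 and 2/3 empirical quantiles under the inverted-ECDF
#' (nearest lower rank, `quantile type = 1`) convention, which returns
#' observed values — integer day boundaries on integer data. Membership is
#' `value <= cut1` -> T1, `cut1 < value <= cut2` -> T2, `value > cut2` -> T3,
#' so ties at a cut fall in the lower tertile.
#'
#' @param values numeric vector of component values across the cohort (>= 3).
#' @param component component name (for reporting).
#' @return a list of class `uus_tertile_cuts`: `component`, `cut1`, `cut2`.
#' @examples
#' compute_tertile_cuts(1:9, "smbg_days") # cuts 3 and 6
#' @export
compute_tertile_cuts <- function(values, component = "component") {
  values <- values[!is.na(values)]
  if (length(values) < 3) {
    abort(paste0("compute_tertile_cuts: need >= 3 values for ", component))
  }
  cuts <- unname(quantile(values, probs = c(1, 2) / 3, type = 1))
  if (cuts[1] == cuts[2] && length(unique(values)) == 1) {
    warn(paste0("compute_tertile_cuts: all '", component,
                "' values identical; every score will be 0"))
  }
  structure(list(component = component, cut1 = cuts[1], cut2 = cuts[2]),
            class = "uus_tertile_cuts")
}

#' Score one component value against its tertile cuts
#'
#' T1/T2/T3 membership earns 0/1/2 points.
#'
#' @param value numeric value(s) on the component scale.
#' @param cuts a `uus_tertile_cuts` object.
#' @return integer score(s) in \{0, 1, 2\}.
#' @export
score_component <- function(value, cuts) {
  stopifnot(inherits(cuts, "uus_tertile_cuts"))
  ifelse(value <= cuts$cut1, 0L, ifelse(value <= cuts$cut2, 1L, 2L))
}

#' Compute the User Utility Score
#'
#' Scores each participant 0-2 on each of the four components (SMBG days,
#' diet days, exercise days, read rate) against the cohort tertile cuts and
#' sums to the composite UUS in 0-8.
#'
#' @param summaries engagement summary tibble from [summarize_engagement()].
#' @param cuts named list of `uus_tertile_cuts`, one per component
#'   (`smbg_days`, `diet_days`, `exercise_days`, `read_rate`).
#' @return a tibble with per-component scores (`score_<component>`), the
#'   component values, and `uus_total`; group labels are added by
#'   [split_by_median()].
#' @export
compute_uus <- function(summaries, cuts) {
  missing_cut <- setdiff(UUS_COMPONENTS, names(cuts))
  if (length(missing_cut) > 0) {
    abort(paste0("compute_uus: missing tertile cuts for: ",
                 paste(missing_cut, collapse = ", ")))
  }
  out <- summaries[, c("participant_id", UUS_COMPONENTS)]
  for (comp in UUS_COMPONENTS) {
    out[[paste0("score_", comp)]] <- score_component(summaries[[comp]], cuts[[comp]])
  }
  out$uus_total <- out$score_smbg_days + out$score_diet_days +
    out$score_exercise_days + out$score_read_rate
  stopifnot(all(out$uus_total >= 0 & out$uus_total <= 8))
  out
}

#' Split the cohort at the median UUS
#'
#' The cohort is dichotomized at its median UUS. When the median is not an
#' integer the threshold is its floor, giving the natural split of integer
#' scores (a median of 4.5 splits 0-4 vs 5-8); participants tied at the
#' threshold go to the low group.
#'
#' @param uus_records tibble from [compute_uus()] (>= 2 participants).
#' @return a list: `records` (input with a `group` factor `low`/`high` and
#'   human-readable `group_label` such as `"UUS:0-4"`), `threshold`, and
#'   `sizes` (named group counts).
#' @export
split_by_median <- function(uus_records) {
  if (nrow(uus_records) < 2) abort("split_by_median: need >= 2 participants")
  scores <- uus_records$uus_total
  if (length(unique(scores)) == 1) {
    abort("split_by_median: all UUS values identical; cannot split cohort")
  }
  med <- median(scores)
  threshold <- if (med == trunc(med)) med else floor(med)
  grp <- factor(ifelse(scores <= threshold, "low", "high"),
                levels = c("low", "high"))
  if (any(table(grp) == 0)) {
    abort("split_by_median: degenerate split (one group empty)")
  }
  records <- uus_records
  records$group <- grp
  records$group_label <- ifelse(grp == "low",
                                sprintf("UUS:0-%d", threshold),
                                sprintf("UUS:%d-8", threshold + 1))
  list(records = records, threshold = threshold,
       sizes = c(low = sum(grp == "low"), high = sum(grp == "high")))
}
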