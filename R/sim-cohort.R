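#' Generate daily engagement logs for a synthetic cohort
#'
#' Each participant gets a latent daily propensity per record type (SMBG,
#' diet, exercise) drawn from the configured Beta distribution, and a message
#' reading probability likewise; days are then independent Bernoulli draws,
#' so 91-day totals are over-dispersed (beta-binomial) counts with the heavy
#' tails and zero mass seen in real app usage. Coaching messages are sent on
#' a fixed weekly schedule (`messages_per_week` per week) and each is read
#' with the participant's reading probability.
#'
#' @param config a [sim_config()] object.
#' @return a tibble with one row per participant per study day:
#'   `participant_id`, `day`, logical `smbg_recorded`/`diet_recorded`/
#'   `exercise_recorded`, integer `messages_sent` and `messages_read`
#'   (`messages_read <= messages_sent`). Deterministic given the config seed.
#' @export
generate_engagement_logs <- function(config) {
  validate_sim_config(config)
  n <- config$n_participants
  days <- config$study_days
  ids <- participant_ids(n)

  withr::with_seed(stage_seed(config$seed, "engagement"), {
    draw_prop <- function(shapes) {
      # two Beta shapes, or a single fixed propensity in [0, 1]
      if (length(shapes) == 1) rep(shapes, n) else rbeta(n, shapes[1], shapes[2])
    }
    draw_flags <- function(shapes) {
      as.logical(rbinom(n * days, 1L, rep(draw_prop(shapes), each = days)))
    }
    smbg <- draw_flags(config$engagement_model$smbg)
    diet <- draw_flags(config$engagement_model$diet)
    exercise <- draw_flags(config$engagement_model$exercise)

    # messages go out on fixed weekdays, e.g. two per week over 13 weeks = 26
    day_seq <- seq_len(days)
    offsets <- unique(round(seq(2, 7, length.out = config$messages_per_week))) %% 7
    sent_day <- as.integer((day_seq %% 7) %in% offsets)
    sent <- rep(sent_day, times = n)
    p_read <- draw_prop(config$engagement_model$read)
    read <- ifelse(sent == 1L, rbinom(n * days, 1L, rep(p_read, each = days)), 0L)
  })

  tibble::tibble(
    participant_id = rep(ids, each = days),
    day = rep(seq_len(days), times = n),
    smbg_recorded = smbg,
    diet_recorded = diet,
    exercise_recorded = exercise,
    messages_sent = as.integer(sent),
    messages_read = as.integer(read)
  )
}

participant_ids <- function(n) sprintf("P%04d", seq_len(n))

#' Generate baseline covariates for a synthetic cohort
#'
#' Continuous covariates are Gaussian with the configured means/SDs, clamped
#' to physiologic lower bounds; binary covariates are Bernoulli with the
#' configured proportions. Covariates are drawn independently of engagement,
#' so crude and covariate-adjusted UUS coefficients share the same estimand.
#'
#' @param config a [sim_config()] object.
#' @return a tibble with one baseline row per participant.
#' @export
generate_baseline <- function(config) {
  validate_sim_config(config)
  n <- config$n_participants
  cm <- config$covariate_model
  withr::with_seed(stage_seed(config$seed, "baseline"), {
    cont <- function(nm, lo) pmax(rnorm(n, cm[[nm]][1], cm[[nm]][2]), lo)
    bin <- function(nm) as.logical(rbinom(n, 1L, cm[[nm]]))
    tibble::tibble(
      participant_id = participant_ids(n),
      age = round(cont("age", 20), 1),
      sex = ifelse(bin("sex_female"), "female", "male"),
      bmi = round(cont("bmi", 15), 2),
      sbp = round(cont("sbp", 80), 1),
      dbp = round(cont("dbp", 40), 1),
      hba1c_baseline = round(pmax(rnorm(n, cm$hba1c_baseline[1], cm$hba1c_baseline[2]), 5.0), 2),
      total_chol = round(cont("total_chol", 80), 1),
      tg = round(cont("tg", 30), 1),
      hdl = round(cont("hdl", 20), 1),
      ldl = round(cont("ldl", 30), 1),
      smoker = bin("smoker"),
      drinker = bin("drinker"),
      dm_duration = round(cont("dm_duration", 0), 1),
      insulin = bin("insulin"),
      antihypertensive = bin("antihypertensive"),
      antidyslipidemic = bin("antidyslipidemic"),
      sdsca_diet = round(cont("sdsca_diet", 0), 1),
      sdsca_exercise = round(cont("sdsca_exercise", 0), 1),
      sdsca_glucose = round(cont("sdsca_glucose", 0), 1),
      sdsca_foot = round(cont("sdsca_foot", 0), 1),
      ads_total = round(cont("ads_total", 1), 1)
    )
  })
}

#' Generate longitudinal outcome visits with known UUS effects
#'
#' HbA1c at follow-up month M is
#' `baseline + beta[M] * UUS + gamma * (baseline - mean(baseline)) + noise`,
#' i.e. the change from baseline is linear in UUS with the configured true
#' per-point effect plus regression to the mean. Under the rate mechanism
#' (see [true_effects()]) the percent reduction rate is linear in UUS instead
#' and HbA1c is back-computed from it. Secondary outcomes change by their
#' configured (default zero) UUS effects plus noise; self-report scales
#' (SDSCA, ADS) are structurally absent at month 3.
#'
#' @param config a [sim_config()] object.
#' @param uus_totals named integer vector, participant id -> UUS in 0..8.
#' @param baseline baseline tibble from [generate_baseline()].
#' @return a tibble of visit records at months 0/3/6/12 (all `observed`);
#'   apply [apply_dropout()] for month-12 loss to follow-up.
#' @export
generate_outcomes <- function(config, uus_totals, baseline) {
  validate_sim_config(config)
  if (any(uus_totals < 0 | uus_totals > 8)) {
    abort("generate_outcomes: uus_totals must lie in [0, 8]")
  }
  if (!all(baseline$participant_id %in% names(uus_totals))) {
    abort("generate_outcomes: uus_totals must cover every participant")
  }
  eff <- config$true_effects
  n <- nrow(baseline)
  u <- as.numeric(uus_totals[baseline$participant_id])
  b0 <- baseline$hba1c_baseline
  centred <- b0 - mean(b0)
  months <- as.integer(names(eff$beta_uus_by_visit))
  sec_names <- setdiff(VISIT_OUTCOMES, "hba1c")

  base_row <- tibble::tibble(
    participant_id = baseline$participant_id,
    visit_month = 0L,
    hba1c = b0,
    bmi = baseline$bmi, sbp = baseline$sbp, dbp = baseline$dbp,
    total_chol = baseline$total_chol, tg = baseline$tg,
    hdl = baseline$hdl, ldl = baseline$ldl,
    sdsca_diet = baseline$sdsca_diet, sdsca_exercise = baseline$sdsca_exercise,
    sdsca_glucose = baseline$sdsca_glucose, sdsca_foot = baseline$sdsca_foot,
    ads_total = baseline$ads_total,
    observed = TRUE
  )

  followups <- withr::with_seed(stage_seed(config$seed, "outcomes"), {
    lapply(months, function(m) {
      key <- as.character(m)
      if (!is.null(eff$rate_slope_by_visit)) {
        if (is.na(eff$rate_slope_by_visit[key])) {
          abort(paste0("generate_outcomes: no rate slope configured for month ", m))
        }
        rate <- eff$rate_slope_by_visit[key] * u +
          rnorm(n, 0, eff$rate_residual_sd_by_visit[key])
        hba1c <- b0 * (1 + rate / 100)
      } else {
        delta <- eff$beta_uus_by_visit[key] * u +
          eff$gamma_baseline_hba1c * centred +
          rnorm(n, 0, eff$residual_sd_by_visit[key])
        hba1c <- b0 + delta
      }
      row <- base_row
      row$visit_month <- m
      row$hba1c <- pmax(hba1c, 4.0)
      for (o in sec_names) {
        if (m == 3L && o %in% SCALE_OUTCOMES) {
          row[[o]] <- NA_real_
        } else {
          row[[o]] <- base_row[[o]] + eff$secondary_effects[o] * u +
            rnorm(n, 0, eff$secondary_change_sd[o])
        }
      }
      row
    })
  })

  dplyr::arrange(dplyr::bind_rows(c(list(base_row), followups)),
                 .data$participant_id, .data$visit_month)
}

#' Apply group-differential month-12 dropout
#'
#' Flags month-12 visits as lost to follow-up, missing completely at random
#' within UUS group with the configured group-specific probabilities.
#' Baseline and months 3/6 are never removed.
#'
#' @param visits visit tibble from [generate_outcomes()].
#' @param groups named character vector, participant id -> `"low"`/`"high"`.
#' @param config a [sim_config()] object (supplies `dropout_model`).
#' @param seed optional seed override (defaults to the config's sub-stream).
#' @return the visit tibble with dropped month-12 rows set to `observed =
#'   FALSE` and their outcome values missing.
#' @export
apply_dropout <- function(visits, groups, config, seed = NULL) {
  validate_sim_config(config)
  ids <- unique(visits$participant_id)
  if (!all(ids %in% names(groups))) {
    abort("apply_dropout: `groups` must assign every participant")
  }
  if (!all(groups[ids] %in% c("low", "high"))) {
    abort("apply_dropout: group labels must be 'low' or 'high'")
  }
  if (is.null(seed)) seed <- stage_seed(config$seed, "dropout")
  p <- unname(config$dropout_model[groups[ids]])
  lost <- withr::with_seed(seed, rbinom(length(ids), 1L, p) == 1L)
  lost_ids <- ids[lost]
  drop_row <- visits$visit_month == 12L & visits$participant_id %in% lost_ids
  visits[drop_row, setdiff(names(visits), c("participant_id", "visit_month", "observed"))] <- NA_real_
  visits$observed[drop_row] <- FALSE
  visits
}

#' Simulate a complete synthetic coaching cohort
#'
#' Runs the full generative chain: daily engagement logs, three-month
#' engagement summaries, cohort tertile cuts, per-participant UUS with the
#' median split, baseline covariates, longitudinal outcomes with the
#' configured true effects, and group-differential month-12 dropout.
#'
#' @param config a [sim_config()] object, e.g. from [sim_scenario()].
#' @return a list of class `uus_cohort` with elements `logs`, `summaries`,
#'   `cuts`, `uus` (scores with group labels), `threshold`, `baseline`,
#'   `visits`, and the `config` used.
#' @examples
#' cohort <- simulate_cohort(sim_scenario("calibrated", seed = 7))
#' table(cohort$uus$group)
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  logs <- generate_engagement_logs(config)
  summaries <- summarize_engagement(logs, window_days = config$study_days)
  cuts <- lapply(setNames(UUS_COMPONENTS, UUS_COMPONENTS), function(comp) {
    compute_tertile_cuts(summaries[[comp]], comp)
  })
  uus <- compute_uus(summaries, cuts)
  split <- split_by_median(uus)
  baseline <- generate_baseline(config)
  totals <- setNames(split$records$uus_total, split$records$participant_id)
  visits <- generate_outcomes(config, totals, baseline)
  groups <- setNames(as.character(split$records$group), split$records$participant_id)
  visits <- apply_dropout(visits, groups, config)
  structure(
    list(logs = logs, summaries = summaries, cuts = cuts,
         uus = split$records, threshold = split$threshold,
         baseline = baseline, visits = visits, config = config),
    class = "uus_cohort"
  )
}
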