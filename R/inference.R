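#' Two-sample t-test
#'
#' Equal-variance (Student) two-sided test by default, matching the group
#' comparisons of baseline characteristics and outcome changes; Welch's
#' unequal-variance form is available by flag.
#'
#' @param x,y numeric vectors (each of length >= 2 after removing NA).
#' @param welch use the Welch correction instead of pooled variance.
#' @return a list: `statistic`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @export
two_sample_t <- function(x, y, welch = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    abort("two_sample_t: each group needs >= 2 non-missing values")
  }
  tt <- t.test(x, y, var.equal = !welch)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' Pearson chi-square test of independence
#'
#' Pearson's statistic without continuity correction, as used for the
#' categorical baseline comparisons; df = (rows - 1)(cols - 1).
#'
#' @param counts matrix of non-negative integer counts.
#' @return a list: `statistic`, `df`, `p_value`.
#' @export
pearson_chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != trunc(counts))) {
    abort("pearson_chi_square: counts must be non-negative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("pearson_chi_square: table has a zero margin")
  }
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

#' Mixed between-within repeated-measures ANOVA
#'
#' One between-subject factor (UUS group) crossed with one within-subject
#' factor (visit time). The univariate tables use Type III sums of squares
#' with sum-to-zero contrasts (unweighted group means), the convention of
#' mainstream GLM repeated-measures software for unbalanced two-group
#' designs. No sphericity correction by default; Greenhouse-Geisser adjusted
#' p-values for the within and interaction effects by flag.
#'
#' @param values numeric matrix, participants x time points (e.g. HbA1c at
#'   months 0/3/6/12 after LOCF completion); no missing cells allowed.
#' @param groups factor of group labels, one per participant, two levels.
#' @param sphericity_correction apply the Greenhouse-Geisser epsilon
#'   adjustment to within-subject p-values.
#' @return a list of class `uus_anova` with elements `between`, `within`,
#'   `interaction` (each `F`, `df1`, `df2`, `p_value`), `gg_epsilon` (when
#'   corrected), and a `design` string.
#' @export
mixed_anova <- function(values, groups, sphericity_correction = FALSE) {
  values <- as.matrix(values)
  groups <- factor(groups)
  if (nlevels(groups) != 2) abort("mixed_anova: exactly two groups required")
  if (length(groups) != nrow(values)) {
    abort("mixed_anova: `groups` must have one label per row of `values`")
  }
  if (anyNA(values)) {
    abort("mixed_anova: missing cells; complete the data (e.g. LOCF) first")
  }
  dat <- data.frame(g = groups)
  mlm <- lm(values ~ g, data = dat, contrasts = list(g = "contr.sum"))
  idata <- data.frame(time = factor(seq_len(ncol(values))))
  av <- car::Anova(mlm, idata = idata, idesign = ~time, type = "III")
  # summary() also computes sphericity diagnostics, which warn on tiny or
  # degenerate designs; only the univariate table (and, on request, the GG
  # adjustment) is consumed here.
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  univ <- s$univariate.tests
  pick <- function(row) list(
    F = unname(univ[row, "F value"]),
    df1 = unname(univ[row, "num Df"]),
    df2 = unname(univ[row, "den Df"]),
    p_value = unname(univ[row, "Pr(>F)"])
  )
  res <- list(
    between = pick("g"),
    within = pick("time"),
    interaction = pick("g:time"),
    design = sprintf("mixed ANOVA: %d x 2 groups (between) x %d times (within), type III",
                     nrow(values), ncol(values))
  )
  if (sphericity_correction) {
    adj <- s$pval.adjustments
    if (is.null(adj) || !"GG eps" %in% colnames(adj) || anyNA(adj[, "GG eps"])) {
      abort("mixed_anova: sphericity corrections unavailable for this design")
    }
    res$gg_epsilon <- unname(adj["time", "GG eps"])
    res$within$p_value <- unname(adj["time", "Pr(>F[GG])"])
    res$interaction$p_value <- unname(adj["g:time", "Pr(>F[GG])"])
  }
  structure(res, class = "uus_anova")
}

# Covariate sets for the nested adjustment models. `crude` is UUS alone;
# model3 is the fully adjusted specification.
MODEL_COVARIATES <- list(
  crude = character(0),
  model1 = c("age", "sex_female"),
  model2 = c("age", "sex_female", "bmi", "sbp", "ldl", "hba1c_baseline",
             "dm_duration"),
  model3 = c("age", "sex_female", "bmi", "sbp", "ldl", "hba1c_baseline",
             "dm_duration", "smoker", "drinker", "ads_total")
)

#' Regress outcome change on UUS with nested covariate adjustment
#'
#' Ordinary least squares of the change from baseline at one visit on the
#' continuous UUS (0-8), under one of four nested adjustment sets: `crude`
#' (none), `model1` (age, sex), `model2` (+ BMI, systolic BP, LDL, baseline
#' HbA1c, diabetes duration), `model3` (+ smoking, alcohol, ADS score).
#' Binary covariates are coded female/current = 1.
#'
#' @param changes change tibble from [change_from_baseline()].
#' @param uus UUS tibble from [compute_uus()] (needs `participant_id`,
#'   `uus_total`).
#' @param baseline baseline covariate tibble.
#' @param visit_month follow-up month to analyse (3, 6 or 12).
#' @param model one of `"crude"`, `"model1"`, `"model2"`, `"model3"`.
#' @return a one-row `ModelResult` tibble: `model`, `outcome`, `visit_month`,
#'   `estimate` (UUS coefficient), `se`, `statistic`, `p_value`, `n`,
#'   `covariates`.
#' @export
fit_uus_model <- function(changes, uus, baseline, visit_month,
                          model = c("crude", "model1", "model2", "model3")) {
  model <- match.arg(model)
  covars <- MODEL_COVARIATES[[model]]
  dat <- changes[changes$visit_month == visit_month, c("participant_id", "outcome", "delta")]
  if (nrow(dat) == 0) {
    abort(paste0("fit_uus_model: no change records at month ", visit_month))
  }
  dat <- dplyr::left_join(dat, uus[, c("participant_id", "uus_total")],
                          by = "participant_id")
  bl <- baseline
  bl$sex_female <- as.numeric(bl$sex == "female")
  bl$smoker <- as.numeric(bl$smoker)
  bl$drinker <- as.numeric(bl$drinker)
  dat <- dplyr::left_join(dat, bl[, c("participant_id", unique(c(MODEL_COVARIATES$model3)))],
                          by = "participant_id")
  keep <- complete.cases(dat[, c("delta", "uus_total", covars)])
  dat <- dat[keep, ]
  rhs <- paste(c("uus_total", covars), collapse = " + ")
  fit <- lm(stats::as.formula(paste("delta ~", rhs)), data = dat)
  if (anyNA(coef(fit))) {
    abort(paste0("fit_uus_model: rank-deficient design; collinear column(s): ",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }
  sm <- summary(fit)$coefficients
  tibble::tibble(
    model = model,
    outcome = dat$outcome[1],
    visit_month = visit_month,
    estimate = sm["uus_total", "Estimate"],
    se = sm["uus_total", "Std. Error"],
    statistic = sm["uus_total", "t value"],
    p_value = sm["uus_total", "Pr(>|t|)"],
    n = nrow(dat),
    covariates = paste(covars, collapse = ",")
  )
}

#' Regress the HbA1c reduction rate on UUS
#'
#' Simple linear regression of the percent reduction rate at one visit on
#' the continuous UUS.
#'
#' @param rate numeric vector of reduction rates (percent of baseline).
#' @param uus numeric vector of UUS totals, aligned with `rate`.
#' @param visit_month follow-up month the rates refer to (for reporting).
#' @return a one-row `ModelResult` tibble as in [fit_uus_model()] with
#'   `model = "rate"`.
#' @export
fit_rate_model <- function(rate, uus, visit_month = NA_integer_) {
  keep <- !is.na(rate) & !is.na(uus)
  rate <- rate[keep]; uus <- uus[keep]
  if (length(rate) < 3) abort("fit_rate_model: need >= 3 complete pairs")
  fit <- lm(rate ~ uus)
  sm <- summary(fit)$coefficients
  tibble::tibble(
    model = "rate",
    outcome = "hba1c_reduction_rate",
    visit_month = as.integer(visit_month),
    estimate = sm["uus", "Estimate"],
    se = sm["uus", "Std. Error"],
    statistic = sm["uus", "t value"],
    p_value = sm["uus", "Pr(>|t|)"],
    n = length(rate),
    covariates = ""
  )
}

#' Bonferroni-adjusted significance threshold
#'
#' Familywise threshold `alpha / m` for `m` comparisons (here, the three
#' follow-up time points), reported both at full precision and truncated
#' (floored) to three decimals per the conventional reporting style
#' (0.05 / 3 prints as .016).
#'
#' @param alpha familywise significance level in (0, 1).
#' @param m number of comparisons (>= 1).
#' @return a list: `full`, `truncated`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 3) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("bonferroni_threshold: alpha must lie in (0, 1)")
  }
  if (!is.numeric(m) || m < 1 || m != trunc(m)) {
    abort("bonferroni_threshold: m must be a positive integer")
  }
  full <- alpha / m
  list(full = full, truncated = floor(full * 1000) / 1000)
}
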