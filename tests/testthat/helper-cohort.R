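# Fixtures and independent oracles shared across the suite.

# Minimal daily-log table from per-participant totals: `smbg`, `diet`, `exer`
# are day counts (records land on days 1..count), `sent`/`read` message totals
# (one message per day on days 1..sent, read on days 1..read).
make_logs <- function(spec, days = 91) {
  dplyr::bind_rows(lapply(names(spec), function(id) {
    s <- spec[[id]]
    tibble::tibble(
      participant_id = id,
      day = seq_len(days),
      smbg_recorded = seq_len(days) <= s[["smbg"]],
      diet_recorded = seq_len(days) <= s[["diet"]],
      exercise_recorded = seq_len(days) <= s[["exer"]],
      messages_sent = as.integer(seq_len(days) <= s[["sent"]]),
      messages_read = as.integer(seq_len(days) <= s[["read"]])
    )
  }))
}

# Visit table from named HbA1c trajectories over months 0/3/6/12 (NA = not
# observed); other outcomes held constant, self-report scales absent at month 3.
make_visits <- function(traj, months = c(0L, 3L, 6L, 12L)) {
  dplyr::bind_rows(lapply(names(traj), function(id) {
    tibble::tibble(
      participant_id = id, visit_month = months, hba1c = traj[[id]],
      bmi = 25, sbp = 130, dbp = 80, total_chol = 170, tg = 140,
      hdl = 50, ldl = 95,
      sdsca_diet = ifelse(months == 3L, NA_real_, 10),
      sdsca_exercise = ifelse(months == 3L, NA_real_, 6),
      sdsca_glucose = ifelse(months == 3L, NA_real_, 4),
      sdsca_foot = ifelse(months == 3L, NA_real_, 3),
      ads_total = ifelse(months == 3L, NA_real_, 19),
      observed = !is.na(traj[[id]])
    )
  }))
}

make_cuts <- function(cut1, cut2, component = "x") {
  structure(list(component = component, cut1 = cut1, cut2 = cut2),
            class = "uus_tertile_cuts")
}

# Brute-force tertile scoring: rank into equal thirds (valid when n is a
# multiple of 3 and there are no ties at the third boundaries).
oracle_thirds <- function(values) {
  k <- length(values) / 3
  r <- rank(values, ties.method = "first")
  ifelse(r <= k, 0L, ifelse(r <= 2 * k, 1L, 2L))
}

# Normal-equations least squares with classical standard errors.
lm_oracle <- function(X, y) {
  XtX <- crossprod(X)
  b <- solve(XtX, crossprod(X, y))
  res <- y - X %*% b
  s2 <- sum(res^2) / (length(y) - ncol(X))
  list(b = drop(b), se = sqrt(diag(solve(XtX)) * s2))
}

# Partitioned sums-of-squares mixed ANOVA for balanced two-group designs
# (balance makes every sums-of-squares type coincide).
anova_oracle <- function(Y, g) {
  Y <- as.matrix(Y); g <- factor(g)
  n <- nrow(Y); tt <- ncol(Y)
  grand <- mean(Y)
  subj <- rowMeans(Y)
  ng <- as.vector(table(g))
  gm <- tapply(subj, g, mean)
  ss_bs <- tt * sum((subj - grand)^2)
  ss_group <- tt * sum(ng * (gm - grand)^2)
  ss_subj <- ss_bs - ss_group
  ss_time <- n * sum((colMeans(Y) - grand)^2)
  cells <- apply(Y, 2, function(col) tapply(col, g, mean))
  ss_cells <- sum(sweep((cells - grand)^2, 1, ng, `*`))
  ss_int <- ss_cells - ss_group - ss_time
  ss_total <- sum((Y - grand)^2)
  ss_err <- ss_total - ss_bs - ss_time - ss_int
  df_g <- nlevels(g) - 1; df_s <- n - nlevels(g)
  df_t <- tt - 1; df_i <- df_g * df_t; df_e <- df_s * df_t
  list(
    between = (ss_group / df_g) / (ss_subj / df_s),
    within = (ss_time / df_t) / (ss_err / df_e),
    interaction = (ss_int / df_i) / (ss_err / df_e)
  )
}
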