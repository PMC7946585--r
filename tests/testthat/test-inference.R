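test_that("Student t-test matches its closed form", {
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_lt(two_sample_t(c(1, 2, 3), c(11, 12, 13))$p_value, 0.01)

  withr::with_seed(5, {
    for (i in 1:10) {
      x <- rnorm(7); y <- rnorm(9, mean = 0.5)
      res <- two_sample_t(x, y)
      sp <- sqrt(((6 * stats::var(x)) + (8 * stats::var(y))) / 14)
      t_hand <- (mean(x) - mean(y)) / (sp * sqrt(1 / 7 + 1 / 9))
      expect_equal(res$statistic, t_hand, tolerance = 1e-10)
      expect_equal(res$p_value, 2 * pt(-abs(t_hand), 14), tolerance = 1e-10)
    }
  })
  expect_error(two_sample_t(1, c(1, 2)), ">= 2")
})

test_that("Pearson chi-square matches the hand-computed statistic", {
  flat <- pearson_chi_square(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  diag2 <- pearson_chi_square(matrix(c(20, 0, 0, 20), 2))
  expect_equal(diag2$statistic, 40) # sum (O-E)^2/E with all E = 10
  expect_equal(diag2$df, 1)

  tab <- matrix(c(12, 5, 7, 9), 2)
  expect_equal(pearson_chi_square(2 * tab)$statistic,
               2 * pearson_chi_square(tab)$statistic)

  expect_error(pearson_chi_square(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("mixed ANOVA agrees with a partitioned sums-of-squares oracle", {
  # 6 participants, 4 times, balanced two groups
  Y <- rbind(
    c(8.0, 7.6, 7.4, 7.5), c(8.4, 8.1, 7.9, 7.8), c(7.9, 7.9, 7.6, 7.7),
    c(8.2, 7.4, 7.0, 6.8), c(8.6, 7.9, 7.5, 7.2), c(8.1, 7.3, 7.1, 7.0)
  )
  g <- rep(c("low", "high"), each = 3)
  res <- mixed_anova(Y, g)
  orc <- anova_oracle(Y, g)
  expect_equal(res$between$F, orc$between, tolerance = 1e-8)
  expect_equal(res$within$F, orc$within, tolerance = 1e-8)
  expect_equal(res$interaction$F, orc$interaction, tolerance = 1e-8)
  expect_equal(res$between$df1, 1)
  expect_equal(res$between$df2, 4)
  expect_equal(res$within$df1, 3)
  expect_equal(res$within$df2, 12)

  # identical group trajectories: no between-group effect
  Y2 <- rbind(Y[1:3, ], Y[1:3, ])
  res2 <- mixed_anova(Y2, g)
  expect_lt(res2$between$F, 1e-20)
  expect_equal(res2$between$p_value, 1, tolerance = 1e-6)

  # equal time means (zero time effect) with nonzero subject-level error
  eps <- rbind(c(.1, -.1, 0, 0), c(-.1, .1, 0, 0), c(0, 0, .1, -.1),
               c(0, 0, -.1, .1), c(.05, 0, -.05, 0), c(-.05, 0, .05, 0))
  Y3 <- matrix(rep(c(8, 7.5, 9, 8.2, 7.1, 8.8), 4), ncol = 4) + eps
  expect_lt(mixed_anova(Y3, g)$within$F, 1e-12)

  gg <- mixed_anova(Y, g, sphericity_correction = TRUE)
  expect_true(gg$gg_epsilon > 0 && gg$gg_epsilon <= 1)
  expect_gte(gg$within$p_value, res$within$p_value)

  expect_error(mixed_anova(Y, rep("low", 6)), "two groups")
  Yna <- Y; Yna[1, 4] <- NA
  expect_error(mixed_anova(Yna, g), "missing cells")
})

make_fit_fixture <- function(n = 40, seed = 13, beta = -0.5, noise_sd = 0) {
  cfg <- sim_config(n_participants = n, seed = seed)
  bl <- generate_baseline(cfg)
  u <- withr::with_seed(seed + 1, sample(0:8, n, replace = TRUE))
  delta <- withr::with_seed(seed + 2,
                            beta * u + 0.02 * bl$age + rnorm(n, 0, noise_sd))
  ch <- tibble::tibble(participant_id = bl$participant_id, visit_month = 12L,
                       outcome = "hba1c", delta = delta, imputed = FALSE)
  uu <- tibble::tibble(participant_id = bl$participant_id, uus_total = u)
  list(changes = ch, uus = uu, baseline = bl)
}

test_that("UUS regressions match the normal-equations oracle", {
  fx <- make_fit_fixture(noise_sd = 0.4)
  res <- fit_uus_model(fx$changes, fx$uus, fx$baseline, 12, "model3")
  bl <- fx$baseline
  X <- cbind(1, fx$uus$uus_total, bl$age, as.numeric(bl$sex == "female"),
             bl$bmi, bl$sbp, bl$ldl, bl$hba1c_baseline, bl$dm_duration,
             as.numeric(bl$smoker), as.numeric(bl$drinker), bl$ads_total)
  orc <- lm_oracle(X, fx$changes$delta)
  expect_equal(res$estimate, orc$b[2], tolerance = 1e-8)
  expect_equal(res$se, orc$se[2], tolerance = 1e-8)
  expect_equal(res$n, nrow(bl))

  # noise-free linear data is interpolated exactly
  exact <- make_fit_fixture(noise_sd = 0)
  res0 <- suppressWarnings( # exact interpolation: zero residual by design
    fit_uus_model(exact$changes, exact$uus, exact$baseline, 12, "model1"))
  expect_equal(res0$estimate, -0.5, tolerance = 1e-10)

  # the UUS coefficient is invariant to participant order and covariate centering
  perm <- withr::with_seed(4, sample(nrow(fx$changes)))
  res_perm <- fit_uus_model(fx$changes[perm, ], fx$uus, fx$baseline, 12, "model3")
  expect_equal(res_perm$estimate, res$estimate, tolerance = 1e-12)
  centred <- fx$baseline
  for (v in c("age", "bmi", "sbp", "ldl", "hba1c_baseline", "dm_duration",
              "ads_total")) {
    centred[[v]] <- centred[[v]] - mean(centred[[v]])
  }
  res_c <- fit_uus_model(fx$changes, fx$uus, centred, 12, "model3")
  expect_equal(res_c$estimate, res$estimate, tolerance = 1e-10)
  expect_equal(res_c$se, res$se, tolerance = 1e-10)

  # collinear covariates are reported, not silently dropped
  coll <- fx$baseline
  coll$ldl <- 2 * coll$sbp
  expect_error(fit_uus_model(fx$changes, fx$uus, coll, 12, "model3"),
               "collinear")
})

test_that("the rate regression matches the simple-regression closed form", {
  expect_equal(suppressWarnings(fit_rate_model(rep(5, 10), 0:9))$estimate, 0)

  u <- 0:9
  expect_equal(suppressWarnings(fit_rate_model(-3 * u + 2, u))$estimate, -3,
               tolerance = 1e-12)

  withr::with_seed(21, {
    u <- sample(0:8, 30, replace = TRUE)
    r <- -2 * u + rnorm(30, 0, 5)
    res <- fit_rate_model(r, u, 12)
    expect_equal(res$estimate,
                 sum((u - mean(u)) * (r - mean(r))) / sum((u - mean(u))^2),
                 tolerance = 1e-12)
  })
})

test_that("Bonferroni thresholds divide alpha and truncate for reporting", {
  expect_equal(bonferroni_threshold(0.05, 1)$full, 0.05)
  b3 <- bonferroni_threshold(0.05, 3)
  expect_equal(b3$full, 0.05 / 3)
  expect_equal(b3$truncated, 0.016)
  expect_equal(bonferroni_threshold(0.05, 5)$truncated, 0.01)
  expect_error(bonferroni_threshold(0.05, 0), "positive integer")
  expect_error(bonferroni_threshold(1.2, 3), "alpha")
})
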