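test_that("engagement summaries count record days and message reading", {
  logs <- make_logs(list(
    A = c(smbg = 91, diet = 10, exer = 40, sent = 26, read = 13),
    B = c(smbg = 5, diet = 0, exer = 0, sent = 26, read = 26),
    C = c(smbg = 50, diet = 50, exer = 91, sent = 0, read = 0)
  ))
  s <- suppressWarnings(summarize_engagement(logs, window_days = 91))
  s <- s[order(s$participant_id), ]
  expect_equal(s$smbg_days, c(91, 5, 50))
  expect_equal(s$diet_days, c(10, 0, 50))
  expect_equal(s$exercise_days, c(40, 0, 91))
  expect_equal(s$read_rate, c(50, 100, 0))
  expect_equal(s$no_messages, c(FALSE, FALSE, TRUE))
  expect_warning(summarize_engagement(logs), "no messages")
  expect_error(summarize_engagement(logs[0, ]), "no participants")

  # a shorter window only counts the first days
  s30 <- suppressWarnings(summarize_engagement(logs, window_days = 30))
  expect_equal(s30$smbg_days[s30$participant_id == "A"], 30)
})

test_that("tertile cuts follow the inverted-ECDF convention with ties going low", {
  cuts <- compute_tertile_cuts(1:9, "x")
  expect_equal(c(cuts$cut1, cuts$cut2), c(3, 6))
  expect_equal(score_component(1:9, cuts), rep(0:2, each = 3))

  expect_warning(cd <- compute_tertile_cuts(rep(7, 6), "x"), "identical")
  expect_equal(c(cd$cut1, cd$cut2), c(7, 7))
  expect_equal(score_component(c(7, 7), cd), c(0L, 0L))

  expect_error(compute_tertile_cuts(c(1, 2), "x"), "3 values")

  # engineered cohort whose SMBG cuts are (33, 75) days
  smbg <- compute_tertile_cuts(c(10, 33, 50, 75, 90, 91), "smbg_days")
  expect_equal(c(smbg$cut1, smbg$cut2), c(33, 75))
  expect_equal(score_component(c(33, 34, 76), smbg), c(0L, 1L, 2L))

  # engineered cohort whose read-rate cuts are (73, 97) percent
  rr <- compute_tertile_cuts(c(50, 73, 80, 97, 99, 100), "read_rate")
  expect_equal(c(rr$cut1, rr$cut2), c(73, 97))
  expect_equal(score_component(c(73, 74, 98), rr), c(0L, 1L, 2L))

  # any value scores 0 when both cuts sit at the scale maximum
  top <- make_cuts(100, 100)
  expect_equal(score_component(c(0, 50, 100), top), c(0L, 0L, 0L))
})

test_that("UUS totals are component sums in 0..8", {
  comps <- c("smbg_days", "diet_days", "exercise_days", "read_rate")
  cuts <- lapply(setNames(comps, comps), function(comp) make_cuts(10, 20, comp))
  s <- tibble::tibble(
    participant_id = c("hi", "lo", "mix"),
    smbg_days = c(25, 5, 25), diet_days = c(30, 10, 15),
    exercise_days = c(21, 1, 5), read_rate = c(99, 10, 50)
  )
  u <- compute_uus(s, cuts)
  expect_equal(setNames(u$uus_total, u$participant_id),
               c(hi = 8L, lo = 0L, mix = 5L))
  expect_error(compute_uus(s, cuts[-1]), "missing tertile cuts")
})

test_that("median split reproduces the 0-4 vs 5-8 grouping and degenerate cases error", {
  rec <- tibble::tibble(participant_id = as.character(1:8),
                        uus_total = c(2L, 3L, 4L, 4L, 5L, 6L, 7L, 8L))
  sp <- split_by_median(rec) # median 4.5
  expect_equal(sp$threshold, 4)
  expect_equal(unname(sp$sizes), c(4L, 4L))
  expect_setequal(unique(sp$records$group_label), c("UUS:0-4", "UUS:5-8"))
  expect_true(all(sp$records$uus_total[sp$records$group == "low"] <= 4))
  expect_true(all(sp$records$uus_total[sp$records$group == "high"] >= 5))

  two <- split_by_median(tibble::tibble(participant_id = c("a", "b"),
                                        uus_total = c(0L, 8L)))
  expect_equal(as.character(two$records$group), c("low", "high"))

  expect_error(split_by_median(tibble::tibble(participant_id = c("a", "b"),
                                              uus_total = c(4L, 4L))),
               "identical")
})

test_that("median split partitions every attainable score multiset", {
  for (size in 2:6) {
    grid <- as.matrix(do.call(expand.grid, rep(list(0:8), size)))
    grid <- grid[rowSums(grid[, -1, drop = FALSE] <
                           grid[, -size, drop = FALSE]) == 0, , drop = FALSE]
    for (i in seq_len(nrow(grid))) {
      scores <- as.integer(grid[i, ])
      rec <- tibble::tibble(participant_id = as.character(seq_len(size)),
                            uus_total = scores)
      med <- median(scores)
      thr <- if (med == trunc(med)) med else floor(med)
      if (length(unique(scores)) == 1 || max(scores) <= thr) {
        expect_error(split_by_median(rec))
      } else {
        sp <- split_by_median(rec)
        expect_equal(sum(sp$sizes), size)
        expect_true(all(sp$sizes > 0))
        expect_true(max(scores) > sp$threshold)
        expect_true(all(scores[sp$records$group == "low"] <= sp$threshold))
        expect_true(all(scores[sp$records$group == "high"] > sp$threshold))
      }
    }
  }
})

test_that("scoring is monotone in raw values and permutation invariant", {
  withr::with_seed(7, {
    for (rep in 1:25) {
      vals <- sample(0:91, 12, replace = TRUE)
      cuts <- compute_tertile_cuts(vals, "x")
      sc <- score_component(vals, cuts)
      bumped <- score_component(vals + sample(0:20, 12, replace = TRUE), cuts)
      expect_true(all(bumped >= sc))
      perm <- sample(12)
      expect_equal(compute_tertile_cuts(vals[perm], "x"), cuts)
    }
  })
})

test_that("scores agree with the rank-into-thirds oracle when no ties at the cut", {
  withr::with_seed(11, {
    checked <- 0
    while (checked < 60) {
      n <- sample(c(3, 6, 9, 12), 1)
      vals <- sample(0:91, n, replace = TRUE)
      srt <- sort(vals)
      k <- n / 3
      if (srt[k] == srt[k + 1] || srt[2 * k] == srt[2 * k + 1]) next
      cuts <- compute_tertile_cuts(vals, "x")
      expect_equal(score_component(vals, cuts), oracle_thirds(vals))
      checked <- checked + 1
    }
  })
})
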