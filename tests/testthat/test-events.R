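test_that("a flat trace yields no events and a boxcar yields exactly one", {
  expect_equal(nrow(detect_events(make_dff(rep(0, 100)), 5)), 0)

  d <- make_dff(c(rep(0, 10), rep(8, 6), rep(0, 10)))  # 8% from t=10 to t=16
  ev <- detect_events(d, 5)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$amplitude_pct, 8)
  expect_equal(ev$onset_s, 10)
  expect_equal(ev$duration_s, 6, tolerance = 1)
  expect_false(ev$truncated)
})

test_that("events never merge across sub-threshold gaps", {
  d <- make_dff(c(rep(0, 5), rep(8, 4), rep(0, 3), rep(8, 4), rep(0, 5)))
  ev <- detect_events(d, 5)
  expect_equal(nrow(ev), 2)
  expect_true(all(diff(ev$onset_s) > 0))
})

test_that("events touching a recording edge are kept and flagged truncated", {
  d <- make_dff(c(rep(8, 4), rep(0, 10), rep(8, 3)))
  ev <- detect_events(d, 5)
  expect_equal(nrow(ev), 2)
  expect_true(all(ev$truncated))
})

test_that("cumulative tiers nest and band mode partitions by peak", {
  tri12 <- c(seq(0, 12, 2), seq(10, 0, -2))
  tri7 <- c(seq(0, 7, 1.4), seq(5.6, 0, -1.4))
  d <- make_dff(c(rep(0, 5), tri12, rep(0, 5), tri7, rep(0, 5)))

  tiers <- classify_tiers(d, tiers = c(5, 10))
  expect_equal(sum(tiers$tier == 5), 2)   # both pulses cross 5%
  expect_equal(sum(tiers$tier == 10), 1)  # only the 12% pulse crosses 10%

  bands <- classify_tiers(d, tiers = c(5, 10), mode = "band")
  expect_equal(sort(bands$tier), c(5, 10))
  expect_equal(bands$tier[which.max(bands$amplitude_pct)], 10)
})

test_that("tier counts are nested on random traces", {
  withr::local_seed(31)
  for (i in 1:50) {
    d <- make_dff(pmax(0, rnorm(150, 2, 6)))
    n5 <- nrow(detect_events(d, 5))
    n10 <- nrow(detect_events(d, 10))
    expect_lte(n10, n5)
  }
})

test_that("the seizure-exclusion filter applies the conjunction rule", {
  ev <- tibble::tibble(
    larva_id = "L1", group = "g",
    onset_s = c(0, 100, 200), offset_s = c(60, 105, 260),
    peak_time_s = c(10, 101, 210),
    amplitude_pct = c(120, 120, 40), duration_s = c(60, 5, 60),
    detect_threshold_pct = 5, truncated = FALSE
  )
  kept <- exclude_seizure_like(ev)
  expect_equal(kept$onset_s, c(100, 200))  # only big AND long removed

  kept_or <- exclude_seizure_like(ev, rule = "or")
  expect_equal(nrow(kept_or), 0)
})

test_that("the AND rule never removes events with amplitude at or below 50%", {
  withr::local_seed(5)
  ev <- tibble::tibble(
    larva_id = "L1", group = "g",
    onset_s = seq(0, 990, 10), offset_s = seq(0, 990, 10) + runif(100, 1, 40),
    peak_time_s = seq(0, 990, 10) + 1,
    amplitude_pct = runif(100, 1, 50), duration_s = runif(100, 1, 120),
    detect_threshold_pct = 5, truncated = FALSE
  )
  ev$duration_s <- ev$offset_s - ev$onset_s
  expect_equal(nrow(exclude_seizure_like(ev)), 100)
})

test_that("AUC is the trapezoidal integral with window averaging", {
  d <- make_dff(rep(10, 61))  # constant 10% for 60 s
  expect_equal(compute_auc(d)$auc_pct_s, 600)
  expect_equal(compute_auc(make_dff(rep(0, 61)))$auc_pct_s, 0)

  # windows mode averages the per-window integrals
  d2 <- make_dff(c(rep(10, 30), rep(20, 31)))
  w <- compute_auc(d2, windows = list(c(0, 20), c(40, 60)))
  expect_equal(w$auc_pct_s, mean(c(10 * 19, 20 * 19)))
  expect_error(compute_auc(d2, windows = list()), "non-empty")
  expect_error(compute_auc(d2, windows = list(c(40, 100))), "outside")
})

test_that("AUC is linear, additive over disjoint windows, and reversal-invariant", {
  withr::local_seed(13)
  y <- rnorm(200, 5, 3)
  d <- make_dff(y)
  a <- compute_auc(d)$auc_pct_s
  expect_equal(compute_auc(make_dff(2.5 * y))$auc_pct_s, 2.5 * a)
  expect_equal(compute_auc(make_dff(rev(y)))$auc_pct_s, a)
  halves <- compute_auc(d, windows = list(c(0, 100), c(100, 200)))
  # each window's integral spans its own frames; sum of window integrals
  # differs from the whole only by the single bridging trapezoid
  bridging <- (y[100] + y[101]) / 2
  expect_equal(2 * halves$auc_pct_s + bridging, a, tolerance = 1e-8)
})

test_that("per-larva summaries aggregate events and normalize AUC to control", {
  ev <- tibble::tibble(
    larva_id = c("a", "a"), group = "control", tier = 5,
    onset_s = c(1, 10), offset_s = c(3, 14), peak_time_s = c(2, 11),
    amplitude_pct = c(6, 10), duration_s = c(2, 4),
    detect_threshold_pct = 5, truncated = FALSE
  )
  auc <- tibble::tibble(larva_id = c("a", "b"), group = c("control", "mutant"),
                        auc_pct_s = c(500, 750))
  s <- summarize_larvae(ev, auc, control_group = "control")
  expect_equal(nrow(s), 2)
  a <- s[s$larva_id == "a", ]
  expect_equal(a$event_count, 2L)
  expect_equal(a$mean_amplitude_pct, 8)
  expect_equal(a$mean_duration_s, 3)
  expect_equal(a$auc_normalized, 1)  # equals the control mean
  b <- s[s$larva_id == "b", ]
  expect_equal(b$event_count, 0L)    # no events: count 0, means missing
  expect_true(is.na(b$mean_amplitude_pct) && is.na(b$mean_duration_s))
  expect_equal(b$auc_normalized, 1.5)
  expect_error(summarize_larvae(ev, auc, control_group = "nope"), "control group")
})
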