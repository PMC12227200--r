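test_that("the 100% peak rule gates seizure detection and is inclusive", {
  # peaks at 80%: crosses the 50% boundary but never the peak threshold
  d80 <- make_dff(c(rep(0, 5), seq(0, 80, 10), seq(70, 0, -10), rep(0, 5)))
  expect_equal(nrow(detect_seizures(d80)), 0)

  # plateau exactly at 100% for 10 s: "at least" is inclusive
  d100 <- make_dff(c(rep(0, 5), rep(100, 10), rep(0, 5)))
  sz <- detect_seizures(d100)
  expect_equal(nrow(sz), 1)
  expect_equal(sz$amplitude_pct, 100)
})

test_that("seizure boundaries are the 50% crossings of a triangular waveform", {
  # linear rise 0->150% over 30 s, fall over 30 s; 50% crossings at t=10 and 50
  tri <- c(seq(0, 150, 5), seq(145, 0, -5))
  d <- make_dff(c(rep(0, 10), tri, rep(0, 10)))
  sz <- detect_seizures(d)
  expect_equal(nrow(sz), 1)
  expect_equal(sz$amplitude_pct, 150)
  expect_equal(sz$onset_s, 10 + 10, tolerance = 1)
  expect_equal(sz$offset_s, 10 + 50, tolerance = 1)
  expect_equal(sz$duration_s, 40, tolerance = 1)
  expect_false(sz$truncated)
  # alignment point: first frame at >= 50% of the 150% maximum
  expect_equal(sz$align_time_s, 10 + 15, tolerance = 1)
})

test_that("a seizure running into the end of the trace is flagged truncated", {
  d <- make_dff(c(rep(0, 10), seq(0, 150, 10), rep(140, 10)))
  sz <- detect_seizures(d)
  expect_equal(nrow(sz), 1)
  expect_true(sz$truncated)
  expect_equal(sz$offset_s, max(d$time_s) + 1)
})

test_that("seizures agree with 50%-threshold events whose amplitude reaches 100%", {
  withr::local_seed(77)
  for (i in 1:10) {
    sim <- simulate_recording(
      quiet_cfg(900, seizure = list(count = sample(0:2, 1),
                                    amplitude_pct_range = c(110, 180),
                                    rise_s = 15, plateau_s = 5, decay_s = 25,
                                    decay_shape = "abrupt")),
      seed = 1000 + i)
    dff <- compute_dff(sim$recording, window_s = 300)
    sz <- detect_seizures(dff)
    ev50 <- detect_events(dff, 50)
    big <- ev50[ev50$amplitude_pct >= 100, ]
    expect_equal(nrow(sz), nrow(big))
    if (nrow(sz) > 0) {
      expect_equal(sz$onset_s, big$onset_s)
      expect_equal(sz$offset_s, big$offset_s)
    }
  }
})

test_that("aligning one seizure reproduces its own segment with zero SEM", {
  tri <- c(seq(0, 150, 5), seq(145, 0, -5))
  d <- make_dff(c(rep(0, 10), tri, rep(0, 30)))
  sz <- detect_seizures(d)
  al <- align_seizures(sz, d, pre_s = 0, post_s = 30)
  expect_equal(al$n_traces, 1)
  i_align <- which(d$time_s == sz$align_time_s)
  expect_equal(al$mean_trace, d$dff_pct[i_align:(i_align + 29)])
  expect_equal(al$sem_trace, rep(0, 30))
})

test_that("identical seizures average to the common waveform with SEM 0", {
  tri <- c(seq(0, 150, 5), seq(145, 0, -5))
  one <- c(rep(0, 10), tri, rep(0, 10))
  d <- dplyr::bind_rows(make_dff(one, larva_id = "L1"),
                        make_dff(one, larva_id = "L2"))
  sz <- detect_seizures(d)
  expect_equal(nrow(sz), 2)
  al <- align_seizures(sz, d, pre_s = 5, post_s = 40)
  expect_equal(al$sem_trace, rep(0, 45))
  expect_equal(dim(al$traces), c(2, 45))
  expect_equal(al$traces[1, ], al$traces[2, ], ignore_attr = TRUE)
})

test_that("time to peak of a symmetric triangle is half the rise from the 50% crossing", {
  tri <- c(seq(0, 150, 5), seq(145, 0, -5))
  d <- make_dff(c(rep(0, 10), tri, rep(0, 10)))
  sz <- detect_seizures(d)
  al <- align_seizures(sz, d, pre_s = 0, post_s = 30)
  m <- seizure_metrics(al)
  # align at 75% (=0.5*150) on the rise (t=25), apex at t=40
  expect_equal(m$time_to_peak_s, 15, tolerance = 1)
})

test_that("aligned-segment AUC matches closed forms and scales linearly", {
  # rectangle: 120% for 10 s at 10 Hz, aligned with pre_s = 0
  rect <- c(rep(0, 50), rep(120, 100), rep(0, 50))
  d <- make_dff(rect, fs = 10)
  sz <- detect_seizures(d)
  al <- align_seizures(sz, d, pre_s = 0, post_s = 10)
  m <- seizure_metrics(al)
  expect_equal(m$auc_pct_s, 1200, tolerance = 12)  # one-frame discretisation
  expect_equal(m$time_to_peak_s, 0)                # first frame is maximal

  d2 <- make_dff(2 * rect, fs = 10)
  m2 <- seizure_metrics(align_seizures(detect_seizures(d2), d2,
                                       pre_s = 0, post_s = 10))
  expect_equal(m2$auc_pct_s, 2 * m$auc_pct_s)
  expect_equal(m2$time_to_peak_s, m$time_to_peak_s)

  # triangle: area over the aligned window matches the analytic integral
  tri <- c(seq(0, 150, 5), seq(145, 0, -5))
  d3 <- make_dff(c(rep(0, 10), tri, rep(0, 10)))
  sz3 <- detect_seizures(d3)
  al3 <- align_seizures(sz3, d3, pre_s = 0, post_s = 36)
  m3 <- seizure_metrics(al3)
  # piecewise-linear waveform: trapezoid rule is exact on the sampled grid
  seg <- d3$dff_pct[d3$time_s >= sz3$align_time_s &
                    d3$time_s < sz3$align_time_s + 36]
  expect_equal(m3$auc_pct_s, pracma::trapz(seq_along(seg) - 1, seg))
})

test_that("SEM shrinks as 1/sqrt(n) for independent noise", {
  withr::local_seed(41)
  base <- c(rep(0, 10), seq(0, 150, 10), rep(150, 5), seq(140, 0, -10), rep(0, 10))
  make_cohort <- function(n) {
    dplyr::bind_rows(lapply(seq_len(n), function(i) {
      make_dff(base + rnorm(length(base), 0, 5), larva_id = sprintf("L%02d", i))
    }))
  }
  d4 <- make_cohort(4); d16 <- make_cohort(16)
  a4 <- align_seizures(detect_seizures(d4), d4, pre_s = 0, post_s = 20)
  a16 <- align_seizures(detect_seizures(d16), d16, pre_s = 0, post_s = 20)
  ratio <- mean(a4$sem_trace) / mean(a16$sem_trace)
  expect_gt(ratio, 1.4)  # ideal 2
  expect_lt(ratio, 2.8)
})

test_that("seizing fractions reproduce printed percentages and guard inputs", {
  expect_equal(seizing_fraction(12, 21), 57.14)
  expect_equal(seizing_fraction(21, 35), 60)
  expect_equal(seizing_fraction(20, 39, digits = 1), 51.3)
  expect_equal(seizing_fraction(6, 38, digits = 1), 15.8)
  expect_equal(seizing_fraction(0, 10), 0)
  expect_equal(seizing_fraction(38, 38), 100)
  expect_error(seizing_fraction(5, 0), "positive")
  expect_error(seizing_fraction(11, 10), "n_total")
})
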