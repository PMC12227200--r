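test_that("a silent configuration yields a constant trace at the baseline level", {
  cfg <- quiet_cfg(120, small_event = list(rate_per_min = 0,
                                           amplitude_pct_range = c(5, 10),
                                           rise_s = 1.5, decay_s = 4),
                   large_event = list(rate_per_min = 0,
                                      amplitude_pct_range = c(10, 50),
                                      rise_s = 1.5, decay_s = 6))
  sim <- simulate_recording(cfg, seed = 5)
  expect_equal(unique(sim$recording$f), 1000)
  expect_equal(nrow(sim$truth$events), 0)
  expect_equal(nrow(sim$truth$seizures), 0)
})

test_that("the seed fully determines the recording", {
  cfg <- sim_config(duration_s = 300)
  a <- simulate_recording(cfg, seed = 99)
  b <- simulate_recording(cfg, seed = 99)
  expect_identical(a$recording, b$recording)
  expect_identical(a$truth, b$truth)
  c <- simulate_recording(cfg, seed = 100)
  expect_false(identical(a$recording$f, c$recording$f))
})

test_that("seeded amplitudes respect the configured ranges", {
  cfg <- sim_config(duration_s = 1200,
                    small_event = list(rate_per_min = 3,
                                       amplitude_pct_range = c(5, 10),
                                       rise_s = 1.5, decay_s = 4),
                    large_event = list(rate_per_min = 1.5,
                                       amplitude_pct_range = c(10, 50),
                                       rise_s = 1.5, decay_s = 6))
  tr <- simulate_recording(cfg, seed = 17)$truth$events
  small <- tr$amplitude_pct[tr$kind == "small"]
  large <- tr$amplitude_pct[tr$kind == "large"]
  expect_gt(length(small), 10)
  expect_true(all(small >= 5 & small <= 10))
  expect_true(all(large >= 10 & large <= 50))
})

test_that("noiseless seeded seizures are recovered exactly by the detector", {
  cfg <- quiet_cfg(1200, seizure = list(count = 3,
                                        amplitude_pct_range = c(120, 180),
                                        rise_s = 15, plateau_s = 5,
                                        decay_s = 25, decay_shape = "abrupt"))
  sim <- simulate_recording(cfg, seed = 12)
  expect_equal(nrow(sim$truth$seizures), 3)
  dff <- compute_dff(sim$recording, window_s = 300)
  sz <- detect_seizures(dff)
  expect_equal(nrow(sz), 3)
  truth <- truth_crossings(sim$truth$seizures, 50)
  dt <- 1 / 1.33
  expect_true(all(abs(sz$onset_s - truth$onset_s) <= dt))
  expect_true(all(abs(sz$duration_s - truth$duration_s) <= dt))
})

test_that("group rate multipliers shift detected event counts as configured", {
  # short kernels keep the trace sparse enough that placement never thins
  # the doubled-rate group
  cfg <- quiet_cfg(900,
                   small_event = list(rate_per_min = 0.8,
                                      amplitude_pct_range = c(6, 9),
                                      rise_s = 1.5, decay_s = 2),
                   large_event = list(rate_per_min = 0,
                                      amplitude_pct_range = c(10, 50),
                                      rise_s = 1.5, decay_s = 6),
                   group_effects = list(fast = list(small_rate = 2)))
  coh <- simulate_cohort(cfg, c(control = 15, fast = 15), seed = 21)
  dff <- compute_dff(coh$recordings, window_s = 150)
  ev <- detect_events(dff, 5)
  counts <- dplyr::count(dplyr::left_join(coh$truth$larvae,
                                          dplyr::count(ev, larva_id),
                                          by = "larva_id"),
                         group, wt = n)
  ratio <- counts$n[counts$group == "fast"] / counts$n[counts$group == "control"]
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
})

test_that("reordering the groups argument permutes the cohort without changing traces", {
  cfg <- sim_config(duration_s = 180)
  a <- simulate_cohort(cfg, c(g1 = 2, g2 = 3), seed = 33)
  b <- simulate_cohort(cfg, c(g2 = 3, g1 = 2), seed = 33)
  fa <- dplyr::arrange(a$recordings, larva_id, frame)
  fb <- dplyr::arrange(b$recordings, larva_id, frame)
  expect_identical(fa$f, fb$f)
  expect_identical(fa$larva_id, fb$larva_id)
})

test_that("tiny cohorts are valid but the stats gate refuses n < 3", {
  cfg <- quiet_cfg(120)
  coh <- simulate_cohort(cfg, c(a = 1, b = 1), seed = 2)
  expect_equal(dplyr::n_distinct(coh$recordings$larva_id), 2)
  d <- data.frame(g = c("a", "b"), v = c(1, 2))
  expect_error(normality_gate(d, v, g), "n >= 3")
})

test_that("fixed per-larva seizure counts override the stochastic draw", {
  cfg <- quiet_cfg(900, seizure = list(rate_per_recording = 0,
                                       amplitude_pct_range = c(120, 160),
                                       rise_s = 15, plateau_s = 5, decay_s = 25,
                                       decay_shape = "abrupt"))
  coh <- simulate_cohort(cfg, c(m = 4), seed = 6,
                         seizure_counts = list(m = c(1, 0, 2, 0)))
  n_by_larva <- table(factor(coh$truth$seizures$larva_id,
                             levels = sort(unique(coh$truth$larvae$larva_id))))
  expect_equal(unname(as.integer(n_by_larva)), c(1, 0, 2, 0))
})
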