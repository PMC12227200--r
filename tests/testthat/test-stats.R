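test_that("normality report flags heavy tails and handles degenerate samples", {
  withr::local_seed(19)
  rejections <- sum(vapply(1:100, function(i) {
    d <- data.frame(g = "a", v = rcauchy(50))
    normality_gate(d, v, g)$p_value < 0.05
  }, logical(1)))
  expect_gte(rejections, 90)

  const <- data.frame(g = "a", v = rep(3, 10))
  out <- normality_gate(const, v, g)
  expect_true(out$degenerate)
  expect_true(is.na(out$p_value))
  expect_error(normality_gate(data.frame(g = "a", v = 1:2), v, g), "n >= 3")
})

test_that("Shapiro-Wilk p-values are uniform under the null", {
  withr::local_seed(23)
  pvals <- vapply(1:200, function(i) {
    normality_gate(data.frame(g = "a", v = rnorm(100)), v, g)$p_value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("rank-sum test gives the enumerated p for separated small samples", {
  d <- data.frame(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 10, 11, 12))
  res <- tidy(rank_sum_test(d, y, g))
  expect_equal(res$p_value, 0.1)  # 2/20 enumerated assignments
  expect_equal(res$effect, 9)     # median difference b - a
  expect_equal(res$test, "rank_sum")
})

test_that("exchangeable groups give the maximal p and shift leaves U unchanged", {
  d <- data.frame(g = rep(c("a", "b"), each = 3), y = rep(c(1, 2, 3), 2))
  expect_gt(tidy(rank_sum_test(d, y, g))$p_value, 0.9)

  withr::local_seed(3)
  y <- c(rnorm(6), rnorm(7, 1))
  d1 <- data.frame(g = rep(c("a", "b"), c(6, 7)), y = y)
  d2 <- transform(d1, y = y + 100)
  r1 <- tidy(rank_sum_test(d1, y, g)); r2 <- tidy(rank_sum_test(d2, y, g))
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("exact rank-sum p equals brute-force enumeration for tie-free samples", {
  withr::local_seed(47)
  for (i in 1:30) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    y <- sample(seq_len(100), n1 + n2)  # tie-free by construction
    a <- y[seq_len(n1)]; b <- y[n1 + seq_len(n2)]
    d <- data.frame(g = rep(c("a", "b"), c(n1, n2)), y = c(a, b))
    got <- tidy(rank_sum_test(d, y, g))$p_value
    expect_equal(got, mw_enum_p(a, b), tolerance = 1e-12)
  }
})

test_that("negative-binomial model recovers symmetric and two-fold rate contrasts", {
  counts <- c(3, 5, 2, 8, 4, 6)
  d <- data.frame(g = rep(c("a", "b"), each = 6), y = c(counts, counts))
  res <- negbin_count_model(d, y, g)
  expect_equal(tidy(res)$effect, 1, tolerance = 1e-8)
  expect_equal(tidy(res)$effect_name, "rate_ratio")

  withr::local_seed(61)
  d2 <- data.frame(g = rep(c("a", "b"), each = 30),
                   y = c(rnb(30, 4, 1), rnb(30, 8, 1)))
  r2 <- tidy(negbin_count_model(d2, y, g, ref = "a"))
  expect_gt(r2$effect, 1.3)
  expect_lt(r2$effect, 3.2)
  # Wald and LRT agree in order of magnitude
  r2l <- tidy(negbin_count_model(d2, y, g, ref = "a", p_method = "lrt"))
  expect_lt(abs(log10(r2$p_value) - log10(r2l$p_value)), 1.5)
})

test_that("Poisson-like and all-zero counts are handled without crashing", {
  withr::local_seed(71)
  d <- data.frame(g = rep(c("a", "b"), each = 25),
                  y = c(rpois(25, 5), rpois(25, 10)))
  r <- negbin_count_model(d, y, g, ref = "a")  # theta at the boundary
  expect_gt(tidy(r)$effect, 1.5)
  expect_lt(tidy(r)$p_value, 0.05)

  dz <- data.frame(g = rep(c("a", "b"), each = 8), y = c(rep(0, 8), rpois(8, 4) + 1))
  rz <- negbin_count_model(dz, y, g)
  expect_true(glance(rz)$unstable)

  expect_error(negbin_count_model(data.frame(g = c("a", "b"), y = c(1.5, 2)), y, g),
               "integer")
})

test_that("significance labels follow the thresholds and are monotone in p", {
  expect_equal(label_significance(c(0.04, 0.0005, 0.5, 0.009)),
               c("*", "***", "ns", "**"))
  expect_error(label_significance(1.2), "\\[0, 1\\]")
  p <- sort(runif(50))
  lab <- label_significance(p)
  rank_of <- c("***" = 1, "**" = 2, "*" = 3, "ns" = 4)
  expect_true(!is.unsorted(rank_of[lab]))
})
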