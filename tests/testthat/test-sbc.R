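test_that("rank statistic counts draws below the truth", {
  expect_equal(rank_statistic(2.5, c(1, 2, 3, 4)), 2L)
  expect_equal(rank_statistic(-10, c(1, 2, 3, 4)), 0L)
  expect_equal(rank_statistic(10, c(1, 2, 3, 4)), 4L)
  expect_error(rank_statistic(1, numeric(0)), "empty")
  # tie randomisation stays within the tied block
  set.seed(1)
  r <- replicate(200, rank_statistic(2, c(1, 2, 2, 3)))
  expect_true(all(r %in% 1:3))
  expect_true(length(unique(r)) == 3)
})

test_that("ranks are invariant to monotone reparameterisation", {
  set.seed(2)
  for (i in 1:25) {
    draws <- rnorm(200)
    true <- rnorm(1)
    expect_equal(rank_statistic(true, draws),
                 rank_statistic(exp(true), exp(draws)))
  }
})

test_that("uniformity diagnostics behave at the extremes", {
  # perfectly balanced bins
  ranks <- rep(seq(5, 95, 10), each = 10)
  d <- uniformity_diagnostics(ranks, D = 100, n_bins = 10)
  expect_equal(d$statistic, 0)
  expect_equal(d$p_value, 1)
  # total collapse
  d2 <- uniformity_diagnostics(rep(50, 100), D = 100, n_bins = 10)
  expect_lt(d2$p_value, 1e-10)
  expect_false(d2$ecdf_ok)
  expect_error(uniformity_diagnostics(1:5, D = 10, n_bins = 20), "bins")
  expect_error(uniformity_diagnostics(c(1, 200), D = 100, n_bins = 2),
               "outside")
})

test_that("chi-square p-values are themselves calibrated under uniform ranks", {
  set.seed(3)
  ps <- replicate(1000, {
    ranks <- sample.int(201, 100, replace = TRUE) - 1L
    uniformity_diagnostics(ranks, D = 200, n_bins = 10)$p_value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("an exact-posterior adapter passes and a shifted one fails", {
  r_ok <- sbc_run(conjugate_adapter(), n_datasets = 200, thinning = 1, seed = 5)
  expect_gt(r_ok$diagnostics$m$p_value, 0.01)
  expect_true(r_ok$diagnostics$m$ecdf_ok)
  expect_equal(r_ok$D, 400)

  r_bad <- sbc_run(sbc_adapter_biased(conjugate_adapter(), shift_sd = 1),
                   n_datasets = 200, thinning = 1, seed = 5)
  expect_lt(r_bad$diagnostics$m$p_value, 0.01)
  expect_false(r_bad$diagnostics$m$ecdf_ok)
  # shifted posteriors push true values toward low ranks
  expect_lt(mean(r_bad$ranks[, "m"]), mean(r_ok$ranks[, "m"]))
})

test_that("SBC runs are reproducible under a fixed seed", {
  r1 <- sbc_run(conjugate_adapter(), n_datasets = 50, thinning = 2, seed = 6)
  r2 <- sbc_run(conjugate_adapter(), n_datasets = 50, thinning = 2, seed = 6)
  expect_identical(r1$ranks, r2$ranks)
  expect_identical(r1$diagnostics, r2$diagnostics)
})
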