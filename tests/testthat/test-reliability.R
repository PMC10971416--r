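test_that("pseudo-R2 has its closed-form identities", {
  expect_equal(pseudo_r2(44 * log(0.5), 44), 0)
  expect_equal(pseudo_r2(0, 44), 1)
  expect_equal(pseudo_r2(22 * log(0.5), 44), 0.5)
  # monotone decreasing in L for fixed chance likelihood
  Ls <- seq(-30, -1, length.out = 10)
  vals <- vapply(Ls, pseudo_r2, numeric(1), n_trials = 44)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals <= 1))
  expect_error(pseudo_r2(1, 44), "<= 0")
  expect_error(pseudo_r2(-1, 0), "positive")
})

test_that("posterior predictive accuracy matches a brute-force replicator", {
  set.seed(70)
  co <- small_re_cohort(n = 3, seed = 71)
  fit <- fixture_re_fit(rep(0, 100), n_subjects = 3, subj_value = 2)
  # saturated parameters reproduce deterministic data almost perfectly
  d <- co$data
  d$choice_hi <- as.integer(plogis(2 * (d$reward_hi - d$reward_lo) -
                                     2 * (d$effort_hi - d$effort_lo)) > 0.5)
  fit_sat <- fixture_re_fit(rep(0, 100), n_subjects = 3, subj_value = 50)
  acc_sat <- posterior_predictive_accuracy(fit_sat, d, n_replications = 20,
                                           seed = 1)
  expect_gt(acc_sat$mean, 0.97)
  # chance parameters on balanced data sit at one half
  fit_chance <- fixture_re_fit(rep(0, 100), n_subjects = 3, subj_value = 0)
  acc_ch <- posterior_predictive_accuracy(fit_chance, co$data,
                                          n_replications = 200, seed = 2)
  expect_lt(abs(acc_ch$mean - 0.5), 3 * sqrt(0.25 / (84 * 200 / 10)))
  # brute-force oracle with a shared seed
  oracle <- local({
    set.seed(3)
    dd <- co$data[co$data$is_catch == 0, ]
    ids <- 1:3
    acc <- numeric(3)
    for (pi in ids) {
      dsub <- dd[dd$subject_id == pi, ]
      p <- plogis(2 * (dsub$reward_hi - dsub$reward_lo) -
                    2 * (dsub$effort_hi - dsub$effort_lo))
      reps <- replicate(50, mean(rbinom(nrow(dsub), 1, p) == dsub$choice_hi))
      acc[pi] <- mean(reps)
    }
    list(mean = mean(acc), per = acc)
  })
  got <- posterior_predictive_accuracy(fit, co$data, n_replications = 50,
                                       seed = 3)
  expect_equal(got$per_subject$accuracy, oracle$per, tolerance = 1e-12)
  expect_equal(got$mean, oracle$mean, tolerance = 1e-12)
})

test_that("accuracy is insensitive to trial ordering", {
  co <- small_re_cohort(n = 4, seed = 72)
  fit <- fixture_re_fit(rep(0, 100), n_subjects = 4, subj_value = 1)
  a1 <- posterior_predictive_accuracy(fit, co$data, n_replications = 400,
                                      seed = 4)
  set.seed(5)
  shuffled <- co$data[sample(nrow(co$data)), ]
  a2 <- posterior_predictive_accuracy(fit, shuffled, n_replications = 400,
                                      seed = 6)
  expect_lt(abs(a1$mean - a2$mean), 0.02)
})

test_that("test-retest reliability recovers a near-degenerate copy", {
  des <- generate_task_design(seed = 73)
  cc <- cohort_config(n_subjects = 100, seed = 74)
  dat <- simulate_reward_effort_cohort(des, cc)
  dat$choice_hi[dat$session == 2] <- dat$choice_hi[dat$session == 1]
  rel <- suppressWarnings(
    estimate_test_retest(dat, "reward_effort",
                         mcmc = quick_mcmc(iter = 1000, warmup = 400,
                                           seed = 75)))
  expect_true(all(rel$R_mu > 0.9))
  expect_true(all(abs(attr(rel, "draws")) <= 1))
  # single-session data is rejected
  expect_error(estimate_test_retest(dat[dat$session == 1, ], "reward_effort"),
               "both sessions")
})

test_that("reliability increases with the simulated cross-session correlation", {
  mus <- numeric(0)
  for (R in c(0.0, 0.8)) {
    des <- generate_task_design(seed = 76)
    cc <- cohort_config(n_subjects = 80, seed = 77,
                        reward_effort = list(R = c(rewSens = R, effSens = R)))
    dat <- simulate_reward_effort_cohort(des, cc)
    rel <- suppressWarnings(
      estimate_test_retest(dat, "reward_effort",
                           mcmc = quick_mcmc(iter = 600, warmup = 250,
                                             seed = 78)))
    mus <- c(mus, rel$R_mu[rel$parameter == "R_rewSens"])
  }
  expect_gt(mus[2], mus[1])
})

test_that("fit metrics combine accuracy, pseudo-R2 and convergence", {
  co <- small_re_cohort(n = 16, seed = 79)
  fit <- suppressWarnings(
    fit_reward_effort(co$data, mcmc = quick_mcmc(iter = 500, warmup = 200,
                                                 seed = 80)))
  m <- fit_metrics(fit, co$data, n_replications = 20, seed = 81)
  expect_true(m$ppa_mean > 0.4 && m$ppa_mean < 1)
  expect_true(m$pseudo_r2 <= 1)
  expect_lt(m$L, 0)
  expect_equal(m$C, sum(co$data$is_catch == 0) * log(0.5))
  m2 <- fit_metrics(fit, co$data, n_replications = 20, seed = 81,
                    likelihood = "draws")
  expect_lt(m2$pseudo_r2, 1)
})
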