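test_that("seeded cohort simulation is byte-identical on rerun", {
  co <- small_re_cohort(seed = 11)
  co2 <- small_re_cohort(seed = 11)
  expect_identical(co$data, co2$data)
  at <- small_att_cohort(seed = 12)
  at2 <- small_att_cohort(seed = 12)
  expect_identical(at$data, at2$data)
  bank <- default_item_bank("A")
  tr <- data.frame(subject_id = 1:10, theta_A = rnorm(10))
  expect_identical(simulate_item_responses(tr, bank, seed = 3),
                   simulate_item_responses(tr, bank, seed = 3))
})

test_that("extreme sensitivities saturate choices; zero gives chance", {
  des <- generate_task_design(seed = 4)
  cc <- cohort_config(n_subjects = 10, seed = 5,
                      reward_effort = list(mu = matrix(c(1000, 1000, 0, 0), 2,
                                                       byrow = TRUE),
                                           sd = c(1e-9, 1e-9)))
  d <- simulate_reward_effort_cohort(des, cc)
  expect_true(all(d$choice_hi[d$is_catch == 0] == 1))

  cc0 <- cohort_config(n_subjects = 50, seed = 6,
                       reward_effort = list(mu = matrix(0, 2, 2),
                                            sd = c(1e-9, 1e-9)))
  d0 <- simulate_reward_effort_cohort(des, cc0)
  n <- nrow(d0)
  expect_lt(abs(mean(d0$choice_hi) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("positive sensitivities choose the dominant catch option above chance", {
  des <- generate_task_design(seed = 8)
  cc <- cohort_config(n_subjects = 250, seed = 9)
  d <- simulate_reward_effort_cohort(des, cc)
  ctch <- d[d$is_catch == 1, ]
  expect_gte(nrow(ctch), 500)
  expect_gt(mean(ctch$choice_hi), 0.5)
})

test_that("simulated choice rates converge to the Bernoulli-logit closed form", {
  # one fixed parameter vector, many subjects: each trial row is a cell with
  # n = n_subjects * 2 sessions observations
  des <- generate_task_design(n_blocks = 1, trials_per_block = 10, n_catch = 0,
                              seed = 10)
  P <- 5000
  cc <- cohort_config(n_subjects = P, seed = 11,
                      reward_effort = list(mu = matrix(c(0.5, 0.5, 1, 1), 2,
                                                       byrow = TRUE),
                                           sd = c(1e-9, 1e-9)))
  d <- simulate_reward_effort_cohort(des, cc)
  for (t in unique(d$trial)) {
    dt <- d[d$trial == t, ]
    p_exp <- plogis(0.5 * (dt$reward_hi[1] - dt$reward_lo[1]) -
                      1 * (dt$effort_hi[1] - dt$effort_lo[1]))
    se <- sqrt(p_exp * (1 - p_exp) / nrow(dt))
    expect_lt(abs(mean(dt$choice_hi) - p_exp), 3 * se + 1e-12)
  }
})

test_that("generated cross-session parameter correlation matches the config", {
  des <- generate_task_design(seed = 13)
  cc <- cohort_config(n_subjects = 500, seed = 14,
                      reward_effort = list(R = c(rewSens = 0.6, effSens = 0.6)))
  d <- simulate_reward_effort_cohort(des, cc)
  tp <- attr(d, "true_params")
  ctrl <- attr(d, "arm") == "control"
  expect_lt(abs(cor(tp[ctrl, 1, 1], tp[ctrl, 1, 2]) - 0.6), 0.1)
  expect_lt(abs(cor(tp[ctrl, 2, 1], tp[ctrl, 2, 2]) - 0.6), 0.1)
})

test_that("attribution simulation respects the latent link", {
  des <- generate_attribution_design(seed = 15)
  # all latent means zero, negligible spread -> endorsement rate 1/2
  cc <- cohort_config(n_subjects = 100, seed = 16,
                      attribution = list(mu = matrix(0, 4, 2),
                                         sd = rep(1e-9, 4)))
  d <- simulate_attribution_cohort(des, cc)
  n <- nrow(d)
  expect_lt(abs(mean(d$choice_internal) - 0.5), 3 * sqrt(0.25 / n))
  # saturated latent tendency -> all internal
  cc2 <- cohort_config(n_subjects = 10, seed = 17,
                       attribution = list(mu = matrix(c(50, 0, 50, 0), 4, 2),
                                          sd = rep(1e-9, 4)))
  d2 <- simulate_attribution_cohort(des, cc2)
  expect_true(all(d2$choice_internal == 1))
})

test_that("cross-trait latent correlation shows up in endorsement rates", {
  des <- generate_attribution_design(seed = 18)
  corr <- kronecker(matrix(c(1, 0.7, 0.7, 1), 2), matrix(c(1, 0.9, 0.9, 1), 2))
  cc <- cohort_config(n_subjects = 200, seed = 19,
                      attribution = list(corr = corr))
  d <- simulate_attribution_cohort(des, cc)
  d1 <- d[d$session == 1 & d$valence == "neg", ]
  rate_int <- tapply(d1$choice_internal, d1$subject_id, mean)
  rate_glob <- tapply(d1$choice_global, d1$subject_id, mean)
  expect_gt(cor(rate_int, rate_glob), 0.5)
})

test_that("item responses follow the graded response model", {
  bank <- default_item_bank("A")[1, ]
  # discrimination zero: response distribution independent of the trait
  bank0 <- bank
  bank0$discrimination <- 1e-12
  lo <- simulate_item_responses(data.frame(subject_id = 1:2000,
                                           theta_A = rep(-3, 2000)),
                                bank0, seed = 20)
  hi <- simulate_item_responses(data.frame(subject_id = 1:2000,
                                           theta_A = rep(3, 2000)),
                                bank0, seed = 21)
  K <- bank$n_categories
  tab <- rbind(table(factor(lo$response, levels = 0:(K - 1))),
               table(factor(hi$response, levels = 0:(K - 1))))
  expect_gt(suppressWarnings(chisq.test(tab))$p.value, 0.01)
  # saturation: very high trait -> top category everywhere
  bankA <- default_item_bank("A")
  top <- simulate_item_responses(data.frame(subject_id = 1:50,
                                            theta_A = rep(50, 50)),
                                 bankA, seed = 22)
  expect_true(all(top$response ==
                    bankA$n_categories[match(top$item_id, bankA$item_id)] - 1L))
})

test_that("exclusion rules apply the published boundaries", {
  co <- small_re_cohort(seed = 23)
  d <- co$data
  # force subject 1 to fail one of two catch trials only -> retained
  i1 <- which(d$subject_id == 1 & d$is_catch == 1)
  d$choice_hi[i1] <- c(0L, 1L, 0L, 1L)[seq_along(i1)]
  # subject 2 fails all catch trials -> excluded
  i2 <- which(d$subject_id == 2 & d$is_catch == 1)
  d$choice_hi[i2] <- 0L
  res <- apply_exclusion_rules(d, "reward_effort")
  expect_false(1 %in% res$excluded)
  expect_true(2 %in% res$excluded)
  expect_true(all(res$report$reason == "catch"))

  at <- small_att_cohort(seed = 24)$data
  at$rt_s[at$subject_id == 1] <- 1.9          # median not > 2 s
  at$option_position[at$subject_id == 2] <- 0L # 100% one position
  # subject 3: exactly 75% in one position (strict "< 75%" rule -> excluded)
  i3 <- which(at$subject_id == 3)
  at$option_position[i3] <- rep(c(0L, 0L, 0L, 1L), length.out = length(i3))
  res2 <- apply_exclusion_rules(at, "attribution")
  expect_true(all(c(1, 2, 3) %in% res2$excluded))
  expect_true("rt" %in% res2$report$reason[res2$report$subject_id == 1])
  expect_true("position" %in% res2$report$reason[res2$report$subject_id == 2])
  expect_true("position" %in% res2$report$reason[res2$report$subject_id == 3])
  expect_error(apply_exclusion_rules(at[, -match("rt_s", names(at))],
                                     "attribution"), "missing")
})
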