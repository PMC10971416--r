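test_that("reward-effort fit recovers group structure on a small cohort", {
  co <- small_re_cohort(n = 40, seed = 50)
  fit <- suppressWarnings(
    fit_reward_effort(co$data, mcmc = quick_mcmc(iter = 700, warmup = 300,
                                                 seed = 51)))
  s <- summary(fit)
  mu_rew <- s$mean[s$parameter == "mu_rewSens[1]"]
  mu_eff <- s$mean[s$parameter == "mu_effSens[1]"]
  expect_lt(abs(mu_rew - 0.35), 0.2)
  expect_lt(abs(mu_eff - 0.7), 0.5)
  expect_true(all(abs(s$mean[s$parameter %in% c("R_rewSens", "R_effSens")]) <= 1))
  # every subject and session has draws
  expect_true(all(sprintf("effSens[%d,%d]", rep(1:40, each = 2), 1:2) %in%
                    s$parameter))
})

test_that("fit refuses unbalanced or malformed inputs", {
  co <- small_re_cohort(n = 6, seed = 52)
  single_arm <- co$data[co$data$arm == "active", ]
  expect_error(fit_reward_effort(single_arm, mcmc = quick_mcmc()), "per arm")
  expect_error(fit_reward_effort(co$data[, 1:4], mcmc = quick_mcmc()),
               "missing columns")
})

test_that("attribution fit identifies the sign of saturated data", {
  at <- small_att_cohort(n = 16, seed = 53)$data
  at$choice_internal <- 1L
  at$choice_global <- 1L
  fit <- suppressWarnings(
    fit_attribution(at, mcmc = quick_mcmc(iter = 400, warmup = 200, seed = 54)))
  s <- summary(fit)
  subj <- s[grepl("^theta_", s$parameter), ]
  expect_true(all(subj$mean > 0))
  # endorsement probabilities live in (0, 1) and are high here
  es <- endorsement_summary(fit)
  expect_true(all(es$probability > 0 & es$probability < 1))
  expect_gt(min(es$probability), 0.5)
})

test_that("the two response codes are conditionally independent", {
  at <- small_att_cohort(n = 16, seed = 55)$data
  m <- quick_mcmc(iter = 600, warmup = 250, seed = 56)
  fit1 <- suppressWarnings(fit_attribution(at, mcmc = m))
  at2 <- at
  set.seed(57)
  # shuffle the global codes within subject x session x valence cells
  key <- paste(at2$subject_id, at2$session, at2$valence)
  for (k in unique(key)) {
    i <- which(key == k)
    at2$choice_global[i] <- sample(at2$choice_global[i])
  }
  fit2 <- suppressWarnings(fit_attribution(at2, mcmc = m))
  g1 <- summary(fit1)
  g2 <- summary(fit2)
  int_pars <- sprintf("mu_int_%s[%d]", rep(c("neg", "pos"), each = 2), 1:2)
  for (p in int_pars) {
    m1 <- g1$mean[g1$parameter == p]
    m2 <- g2$mean[g2$parameter == p]
    expect_identical(m1, m2)  # cell counts are unchanged by within-cell shuffles
  }
})

test_that("valence blocks are fitted separately", {
  at <- small_att_cohort(n = 16, seed = 58)$data
  m <- quick_mcmc(iter = 600, warmup = 250, seed = 59)
  fit1 <- suppressWarnings(fit_attribution(at, mcmc = m))
  at2 <- at
  flip <- at2$valence == "neg" & at2$session == 1
  at2$choice_internal[flip] <- 1L - at2$choice_internal[flip]
  fit2 <- suppressWarnings(fit_attribution(at2, mcmc = m))
  s1 <- summary(fit1)
  s2 <- summary(fit2)
  pos_pars <- c(sprintf("mu_int_pos[%d]", 1:2), sprintf("mu_glob_pos[%d]", 1:2))
  for (p in pos_pars) {
    sd1 <- s1$sd[s1$parameter == p]
    expect_lt(abs(s1$mean[s1$parameter == p] - s2$mean[s2$parameter == p]),
              4 * sd1)
  }
  # the perturbed negative-event mean must move
  expect_gt(abs(s1$mean[s1$parameter == "mu_int_neg[1]"] -
                  s2$mean[s2$parameter == "mu_int_neg[1]"]), 0.3)
})

test_that("GRM fitting recovers item structure", {
  set.seed(60)
  bank <- default_item_bank("N")
  traits <- data.frame(subject_id = 1:150, theta_N = rnorm(150))
  items <- simulate_item_responses(traits, bank, seed = 61)
  fit <- suppressWarnings(fit_grm(items, trait = "N",
                                  mcmc = quick_mcmc(iter = 700, warmup = 300,
                                                    seed = 62)))
  s <- summary(fit)
  est_a <- s$mean[match(sprintf("disc[%s]", bank$item_id), s$parameter)]
  expect_gt(cor(bank$discrimination, est_a, method = "spearman"), 0.5)
  te <- trait_estimates(fit)
  expect_gt(cor(traits$theta_N, te$estimate), 0.8)
  expect_lt(abs(mean(te$estimate)), 0.1)
  # degenerate single-category items are flagged
  bad <- items
  bad$response[bad$item_id == "DAS_1"] <- 2L
  expect_error(fit_grm(bad, trait = "N", mcmc = quick_mcmc()), "degenerate")
})

test_that("two items with identical parameters get exchangeable estimates", {
  set.seed(63)
  bank <- default_item_bank("A")[c(1, 1), ]
  bank$item_id <- c("twin_a", "twin_b")
  bank <- rbind(bank, default_item_bank("A")[2:5, ])
  traits <- data.frame(subject_id = 1:150, theta_A = rnorm(150))
  items <- simulate_item_responses(traits, bank, seed = 64)
  fit <- suppressWarnings(fit_grm(items, trait = "A",
                                  mcmc = quick_mcmc(iter = 700, warmup = 300,
                                                    seed = 65)))
  s <- summary(fit)
  a1 <- s[s$parameter == "disc[twin_a]", ]
  a2 <- s[s$parameter == "disc[twin_b]", ]
  expect_lt(abs(a1$mean - a2$mean), 2 * sqrt(a1$sd^2 + a2$sd^2))
})

test_that("intervention effect summaries match quantile oracles", {
  set.seed(66)
  # constant draws: interval degenerates to the point
  fit_const <- fixture_re_fit(rep(-0.3, 400))
  eff <- intervention_effect_summary(fit_const)
  expect_equal(eff$mean, rep(-0.3, 2))
  expect_equal(eff$lower, rep(-0.3, 2))
  expect_true(all(eff$excludes_zero))
  # symmetric draws around zero: no exclusion
  x <- rnorm(2000)
  sym <- fixture_re_fit(c(x, -x))
  expect_false(any(intervention_effect_summary(sym)$excludes_zero))
  # CI endpoints equal independent quantiles on a 4000-draw fixture
  dr <- rt(4000, df = 5) - 0.2
  fit4k <- fixture_re_fit(dr)
  eff4k <- intervention_effect_summary(fit4k, level = 0.90)
  expect_equal(eff4k$lower[1], unname(quantile(dr, 0.05)), tolerance = 1e-12)
  expect_equal(eff4k$upper[1], unname(quantile(dr, 0.95)), tolerance = 1e-12)
  # SMD scaling divides by the subject-level session-2 posterior SD
  fit_sc <- fixture_re_fit(rep(-0.3, 400), subj_noise = 0.5)
  eff_sc <- intervention_effect_summary(fit_sc)
  v2 <- mean(apply(fit_sc$draws[, sprintf("rewSens[%d,2]", 1:4)], 2, var))
  expect_equal(eff_sc$smd[1], -0.3 / sqrt(v2))
})

test_that("standardized_beta rescales draws and intervals linearly", {
  d <- rnorm(1000, 0.5, 0.1)
  expect_equal(standardized_beta(d, 1, 1)$draws, d)
  expect_equal(standardized_beta(0.5, 2, 1)$mean, 1.0)
  s1 <- standardized_beta(d, 1, 1)
  s2 <- standardized_beta(d, 3, 1.5)
  expect_equal(s2$lower, s1$lower * 2)
  expect_equal(s2$upper, s1$upper * 2)
  expect_error(standardized_beta(d, 0, 1), "positive")
})
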