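test_that("change scores standardise by the baseline SD", {
  set.seed(90)
  fit <- fixture_re_fit(rep(0, 50), n_subjects = 4)
  # hand-built subject posterior means: sessions equal -> change zero
  ids <- 1:4
  for (p in ids)
    for (k in c("rewSens", "effSens")) {
      fit$draws[, sprintf("%s[%d,1]", k, p)] <- p / 2
      fit$draws[, sprintf("%s[%d,2]", k, p)] <- p / 2
    }
  fit$summaries$mean <- colMeans(fit$draws)
  cs <- change_scores(fit)
  expect_true(all(cs$change == 0))
  # printed 4-subject fixture: baseline means 1,2,3,4 (SD = sd(1:4)),
  # session-2 means 2,2,4,5 -> changes 1,0,1,1
  for (p in ids) {
    fit$draws[, sprintf("effSens[%d,1]", p)] <- p
    fit$draws[, sprintf("effSens[%d,2]", p)] <- c(2, 2, 4, 5)[p]
  }
  fit$summaries$mean <- colMeans(fit$draws)
  cs2 <- change_scores(fit)
  eff <- cs2[cs2$parameter == "effSens", ]
  expect_equal(eff$change, c(1, 0, 1, 1))
  expect_equal(eff$change_std, c(1, 0, 1, 1) / sd(1:4))
  # uniform +1 baseline-SD shift in the active arm only
  arm <- fit$data_info$arm
  for (p in ids) {
    fit$draws[, sprintf("effSens[%d,1]", p)] <- p
    fit$draws[, sprintf("effSens[%d,2]", p)] <- p +
      ifelse(arm[p] == "active", sd(1:4), 0)
  }
  fit$summaries$mean <- colMeans(fit$draws)
  cs3 <- change_scores(fit)
  eff3 <- cs3[cs3$parameter == "effSens", ]
  expect_equal(mean(eff3$change_std[eff3$arm == "active"]), 1)
  expect_equal(mean(eff3$change_std[eff3$arm == "control"]), 0)
})

test_that("SD of individual responses follows the stated arithmetic", {
  h0 <- sd_individual_response(0.4, 0.4, 50, 50)
  expect_equal(h0$sd_ir, 0)
  expect_equal(h0$effect_class, "none")

  h <- sd_individual_response(0.5, 0.3, 99, 99)
  expect_equal(h$sd_ir, 0.4)
  expect_equal(h$sd_ir_se, sqrt(2 * (0.5^4 / 99 + 0.3^4 / 99)))
  expect_equal(round(h$sd_ir_se, 4), 0.0378)
  expect_equal(round(h$ci95, 3), c(0.326, 0.474))
  expect_equal(h$effect_class, "moderate")
  # exact variance decomposition whenever the root is real
  expect_equal(h$sd_ir^2 + h$sd_con^2, h$sd_act^2)
  # clamping and the signed alternative
  hneg <- sd_individual_response(0.3, 0.5, 99, 99)
  expect_equal(hneg$sd_ir, 0)
  expect_true(hneg$no_heterogeneity)
  hsgn <- sd_individual_response(0.3, 0.5, 99, 99, clamp_negative = FALSE)
  expect_equal(hsgn$sd_ir, -0.4)
  expect_error(sd_individual_response(-0.1, 0.3, 10, 10), "nonnegative")
  expect_error(sd_individual_response(0.4, 0.3, 0, 10), "DF")
})

test_that("the normal-theory CI agrees with a bootstrap on simulated arms", {
  set.seed(91)
  n <- 500
  act <- rnorm(n, 0, 0.5)   # change scores with extra individual response
  con <- rnorm(n, 0, 0.3)
  h <- sd_individual_response(sd(act), sd(con), n - 1, n - 1)
  boot <- replicate(600, {
    a <- sample(act, replace = TRUE)
    c_ <- sample(con, replace = TRUE)
    d2 <- sd(a)^2 - sd(c_)^2
    if (d2 > 0) sqrt(d2) else 0
  })
  bw <- diff(quantile(boot, c(0.025, 0.975)))
  nw <- diff(h$ci95)
  expect_lt(abs(bw - nw) / nw, 0.2)
  expect_lt(abs(h$sd_ir - median(boot)), 0.05)
})

test_that("interaction power reproduces its closed-form properties", {
  expect_equal(rm_interaction_power(0, 40, 2, 0.5, 0.05), 0.05)
  # strictly increasing in N, d and rho
  expect_true(all(diff(sapply(c(20, 40, 80, 160),
                              function(n) rm_interaction_power(0.4, n, 2, 0.5))) > 0))
  expect_true(all(diff(sapply(c(0.2, 0.4, 0.6),
                              function(d) rm_interaction_power(d, 50, 2, 0.5))) > 0))
  expect_true(all(diff(sapply(c(0.1, 0.5, 0.8),
                              function(r) rm_interaction_power(0.4, 50, 2, r))) > 0))
})

test_that("required sample size is the smallest N meeting the target", {
  n <- required_sample_size(0.48, 0.95, 2, 0.6, 0.05)
  expect_lte(n, 48)
  expect_gte(rm_interaction_power(0.48, n, 2, 0.6), 0.95)
  expect_lt(rm_interaction_power(0.48, n - 2, 2, 0.6), 0.95)
  # monotone: larger effects never need more subjects
  ns <- sapply(c(0.3, 0.5, 0.7, 0.9), required_sample_size,
               target_power = 0.9, m = 2, rho = 0.5)
  expect_true(all(diff(ns) <= 0))
  expect_error(required_sample_size(0, 0.9), "zero")
})

test_that("computed power matches simulated rejection rates", {
  # for two measures the interaction F test is the two-sample t test on
  # change scores; d maps to a raw change-score shift of 2 * d
  set.seed(92)
  d_eff <- 0.6; n <- 60; rho <- 0.5
  target <- rm_interaction_power(d_eff, n, 2, rho, 0.05)
  nsim <- 4000
  rej <- replicate(nsim, {
    ch_con <- rnorm(n / 2, 0, sqrt(2 * (1 - rho)))
    ch_act <- rnorm(n / 2, 2 * d_eff, sqrt(2 * (1 - rho)))
    t.test(ch_act, ch_con, var.equal = TRUE)$p.value < 0.05
  })
  mc_se <- sqrt(target * (1 - target) / nsim)
  expect_lt(abs(mean(rej) - target), 3 * mc_se + 0.01)
})

test_that("power tables cover the requested grid", {
  tab <- power_table(d = c(0.3, 0.5), n = c(40, 80), rho = 0.5)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$power > 0 & tab$power < 1))
})
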