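test_that("joint fit exposes moderation coefficients with the CI decision rule", {
  set.seed(100)
  des <- generate_task_design(seed = 101)
  cc <- cohort_config(n_subjects = 60, seed = 102,
                      joint = list(trait = "A", target = "effSens",
                                   beta_base = 0.3, beta_int = 0))
  dat <- simulate_reward_effort_cohort(des, cc)
  items <- simulate_item_responses(
    data.frame(subject_id = 1:60, theta_A = attr(dat, "traits")),
    default_item_bank("A"), seed = 103)
  fit <- suppressWarnings(
    fit_joint(dat, items, target = "effSens", traits = "A",
              mcmc = quick_mcmc(iter = 700, warmup = 300, seed = 104)))
  co <- joint_coefficients(fit)
  expect_equal(nrow(co), 2)
  expect_setequal(co$parameter, c("beta_base_A", "beta_int_A"))
  expect_equal(co$excludes_zero, co$lower > 0 | co$upper < 0)
  # traits are estimated on an approximately standard scale
  th <- fit$summaries$mean[grepl("^theta_A", fit$summaries$parameter)]
  expect_lt(abs(mean(th)), 0.25)
})

test_that("with null moderation the joint fit nests the plain behavioural fit", {
  set.seed(105)
  des <- generate_task_design(seed = 106)
  cc <- cohort_config(n_subjects = 40, seed = 107)
  dat <- simulate_reward_effort_cohort(des, cc)
  traits <- data.frame(subject_id = 1:40, theta_A = rnorm(40))
  items <- simulate_item_responses(traits, default_item_bank("A"), seed = 108)
  m <- quick_mcmc(iter = 700, warmup = 300, seed = 109)
  plain <- suppressWarnings(fit_reward_effort(dat, mcmc = m))
  joint <- suppressWarnings(fit_joint(dat, items, target = "effSens",
                                      traits = "A", mcmc = m))
  for (p in c("mu_rewSens[1]", "mu_effSens[1]", "mu_rewSens[2]",
              "mu_effSens[2]")) {
    m1 <- plain$summaries[plain$summaries$parameter == p, ]
    m2 <- joint$summaries[joint$summaries$parameter == p, ]
    mcse <- sqrt(m1$sd^2 + m2$sd^2) / 2
    expect_lt(abs(m1$mean - m2$mean), m1$sd + m2$sd)
  }
})

test_that("two-step mode plugs in GRM trait estimates", {
  set.seed(110)
  des <- generate_task_design(seed = 111)
  cc <- cohort_config(n_subjects = 40, seed = 112,
                      joint = list(trait = "A", target = "effSens",
                                   beta_base = 0.4, beta_int = -0.3))
  dat <- simulate_reward_effort_cohort(des, cc)
  items <- simulate_item_responses(
    data.frame(subject_id = 1:40, theta_A = attr(dat, "traits")),
    default_item_bank("A"), seed = 113)
  fit <- suppressWarnings(
    fit_joint(dat, items, target = "effSens", traits = "A",
              mcmc = quick_mcmc(iter = 500, warmup = 250, seed = 114),
              method = "two_step"))
  co <- joint_coefficients(fit)
  expect_true(all(is.finite(co$mean)))
  # moderation weights should at least carry the simulated signs
  expect_gt(co$mean[co$parameter == "beta_base_A"], 0)
  expect_lt(co$mean[co$parameter == "beta_int_A"], 0)
})

test_that("joint fitting rejects misconfigured targets and disjoint subjects", {
  co <- small_re_cohort(n = 8, seed = 115)
  items <- simulate_item_responses(data.frame(subject_id = 1:8,
                                              theta_A = rnorm(8)),
                                   default_item_bank("A"), seed = 116)
  expect_error(fit_joint(co$data, items, target = "nonsense"), "unknown target")
  items_far <- items
  items_far$subject_id <- items_far$subject_id + 1000
  expect_error(suppressWarnings(fit_joint(co$data, items_far,
                                          target = "effSens")))
})

test_that("attribution joint fit targets a dimension-valence cell", {
  set.seed(117)
  des <- generate_attribution_design(seed = 118)
  cc <- cohort_config(n_subjects = 60, seed = 119,
                      joint = list(trait = "N",
                                   target = list(valence = "pos",
                                                 dimension = "internal"),
                                   beta_base = -0.5, beta_int = 0))
  dat <- simulate_attribution_cohort(des, cc)
  items <- simulate_item_responses(
    data.frame(subject_id = 1:60, theta_N = attr(dat, "traits")),
    default_item_bank("N"), seed = 120)
  fit <- suppressWarnings(
    fit_joint(dat, items, target = "internal_pos", traits = "N",
              mcmc = quick_mcmc(iter = 700, warmup = 300, seed = 121)))
  co <- joint_coefficients(fit)
  expect_lt(co$mean[co$parameter == "beta_base_N"], 0)
})
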