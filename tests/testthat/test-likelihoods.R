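test_that("option values and choice probabilities follow the linear-logit rule", {
  expect_equal(option_value(1, 1, 5, 0.5), 4.5)
  expect_equal(option_value(0, 0, 3, 0.9), 0)
  expect_equal(option_value(2, 3, 7, 0.95), 11.15)
  expect_equal(choice_probability(1, 1), 0.5)
  expect_equal(choice_probability(log(3), 0), 0.75)
  expect_gte(choice_probability(50, 0), 1 - 1e-20)
  expect_gt(choice_probability(-700, 0), 0)
  # translation invariance: shifting both options leaves probability unchanged
  for (shift in c(-10, 0.3, 42))
    expect_equal(choice_probability(1.2 + shift, -0.4 + shift),
                 choice_probability(1.2, -0.4))
  # monotone in the value difference
  p <- choice_probability(seq(-3, 3, 0.5), 0)
  expect_true(all(diff(p) > 0))
})

test_that("dataset log likelihood matches direct summation", {
  co <- small_re_cohort(n = 3, seed = 30)
  d <- co$data
  params <- expand.grid(subject_id = 1:3, session = 1:2)
  params$rewSens <- c(0.4, 0.9, 1.3, 0.2, 0.7, 1.1)
  params$effSens <- c(1.5, 0.3, 0.8, 2.0, 0.5, 1.2)
  # independent per-trial oracle
  oracle <- 0
  dd <- d[d$is_catch == 0, ]
  for (i in seq_len(nrow(dd))) {
    row <- dd[i, ]
    pr <- params[params$subject_id == row$subject_id &
                   params$session == row$session, ]
    p_hi <- plogis(pr$rewSens * (row$reward_hi - row$reward_lo) -
                     pr$effSens * (row$effort_hi - row$effort_lo))
    oracle <- oracle + log(ifelse(row$choice_hi == 1, p_hi, 1 - p_hi))
  }
  expect_equal(dataset_loglik(params, d), oracle, tolerance = 1e-10)
  # chance model
  zero <- params
  zero$rewSens <- 0
  zero$effSens <- 0
  expect_equal(dataset_loglik(zero, d), nrow(dd) * log(0.5))
  # missing subject errors
  expect_error(dataset_loglik(params[params$subject_id != 2, ], d), "cover")
})

test_that("attribution probabilities and log likelihood are Bernoulli-logit", {
  expect_equal(attribution_probability(0), 0.5)
  expect_equal(attribution_probability(log(9)), 0.9)
  th <- seq(-4, 4, 0.25)
  expect_true(all(diff(attribution_probability(th)) > 0))

  at <- small_att_cohort(n = 2, seed = 31)$data
  traits <- expand.grid(subject_id = 1:2, session = 1:2,
                        valence = c("neg", "pos"), stringsAsFactors = FALSE)
  traits$theta_internal <- seq(-0.8, 0.6, length.out = 8)
  traits$theta_global <- seq(0.5, -0.9, length.out = 8)
  oracle <- 0
  for (i in seq_len(nrow(at))) {
    row <- at[i, ]
    tr <- traits[traits$subject_id == row$subject_id &
                   traits$session == row$session &
                   traits$valence == row$valence, ]
    p_i <- plogis(tr$theta_internal)
    p_g <- plogis(tr$theta_global)
    oracle <- oracle + log(ifelse(row$choice_internal == 1, p_i, 1 - p_i)) +
      log(ifelse(row$choice_global == 1, p_g, 1 - p_g))
  }
  expect_equal(attribution_loglik(traits, at), oracle, tolerance = 1e-10)
  zero <- traits
  zero$theta_internal <- 0
  zero$theta_global <- 0
  one_session <- at[at$subject_id == 1 & at$session == 1, ]  # 32 trials
  expect_equal(attribution_loglik(zero, one_session), 64 * log(0.5))
})

test_that("GRM category probabilities normalise and saturate correctly", {
  # closed form: a = 1, thresholds (-1, 1), trait 0 -> middle category
  p <- grm_category_probabilities(0, 1, c(-1, 1))
  expect_equal(p[2], plogis(1) - plogis(-1), tolerance = 1e-12)
  expect_equal(sum(p), 1)
  expect_equal(round(p[2], 3), 0.462)
  # discrimination zero: independent of theta
  expect_equal(grm_category_probabilities(-5, 0, c(-1, 0, 1)),
               grm_category_probabilities(5, 0, c(-1, 0, 1)))
  # normalisation on random grids
  set.seed(1)
  for (i in 1:50) {
    K <- sample(3:6, 1)
    kap <- sort(rnorm(K - 1, sd = 2))
    if (any(diff(kap) == 0)) next
    p <- grm_category_probabilities(rnorm(1, sd = 2), runif(1, 0.2, 3), kap)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
  expect_error(grm_category_probabilities(0, 1, c(1, -1)), "increasing")
})
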