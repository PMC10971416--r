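test_that("default reward-effort design reproduces the published dimensions", {
  des <- generate_task_design(seed = 1)
  expect_equal(nrow(des), 44)
  expect_equal(length(unique(des$block)), 4)
  expect_equal(sum(des$is_catch), 2)
  expect_true(all(des$reward_hi >= 3 & des$reward_hi <= 7))
  expect_true(all(des$reward_lo >= 3 & des$reward_lo <= 7))
  expect_true(all(des$effort_hi >= 0.25 & des$effort_hi <= 0.95))
  expect_true(all(des$effort_lo >= 0.25 & des$effort_lo <= 0.95))
})

test_that("non-catch offers are nondominated and catch offers dominant", {
  for (seed in 1:5) {
    des <- generate_task_design(seed = seed)
    reg <- des[des$is_catch == 0, ]
    expect_true(all(reg$reward_hi > reg$reward_lo))
    expect_true(all(reg$effort_hi > reg$effort_lo))
    ctch <- des[des$is_catch == 1, ]
    expect_true(all(ctch$reward_hi == 7 & ctch$effort_hi == 0.25))
    expect_true(all(ctch$effort_lo == 0.95))
    # catch trials land in distinct blocks
    expect_equal(length(unique(ctch$block)), nrow(ctch))
  }
})

test_that("custom configurations and seeded determinism work", {
  d3 <- generate_task_design(n_blocks = 1, trials_per_block = 3, n_catch = 0,
                             seed = 5)
  expect_equal(nrow(d3), 3)
  expect_true(all(d3$effort_hi > d3$effort_lo))
  expect_identical(generate_task_design(seed = 42), generate_task_design(seed = 42))
  expect_false(identical(generate_task_design(seed = 42),
                         generate_task_design(seed = 43)))
})

test_that("degenerate design requests error", {
  expect_error(generate_task_design(reward_levels = 5, effort_levels = 0.5),
               "degenerate")
  expect_error(generate_task_design(n_blocks = 1, trials_per_block = 4,
                                    n_catch = 5))
})

test_that("attribution design has the published structure", {
  des <- generate_attribution_design(seed = 2)
  expect_equal(nrow(des), 32)
  expect_equal(sum(des$valence == "pos"), 16)
  expect_equal(sum(des$valence == "neg"), 16)
  expect_equal(length(unique(des$block)), 2)
  expect_identical(generate_attribution_design(seed = 9),
                   generate_attribution_design(seed = 9))
  expect_error(generate_attribution_design(n_scenarios = 10, n_positive = 12))
})

test_that("default item banks mirror the instrument structure", {
  bank <- default_item_bank()
  a <- bank[bank$trait == "A", ]
  n <- bank[bank$trait == "N", ]
  expect_equal(sum(a$instrument == "AMI"), 6)
  expect_equal(sum(a$instrument == "PHQ9"), 2)
  expect_equal(sum(n$instrument == "DAS"), 8)
  expect_equal(sum(n$instrument == "PHQ9"), 2)
  expect_silent(validate_item_bank(bank))
  bad <- bank
  bad$kappa_2[1] <- bad$kappa_1[1] - 1
  expect_error(validate_item_bank(bad), "increasing")
})
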