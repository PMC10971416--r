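# short sampler settings for unit tests (acceptance tests set their own)
quick_mcmc <- function(chains = 2, iter = 500, warmup = 200, seed = 1) {
  mcmc_control(chains = chains, iter = iter, warmup = warmup, seed = seed)
}

# a small simulated choice cohort shared by several tests
small_re_cohort <- function(n = 24, seed = 7, phi = c(rewSens = 0, effSens = 0)) {
  des <- generate_task_design(seed = seed)
  cc <- cohort_config(n_subjects = n, seed = seed + 1,
                      reward_effort = list(phi_int = phi))
  list(design = des, data = simulate_reward_effort_cohort(des, cc), config = cc)
}

small_att_cohort <- function(n = 24, seed = 7) {
  des <- generate_attribution_design(seed = seed)
  cc <- cohort_config(n_subjects = n, seed = seed + 1)
  list(design = des, data = simulate_attribution_cohort(des, cc), config = cc)
}

# hand-built fit object with known draws, for summary-level functions
fixture_re_fit <- function(phi_draws, n_subjects = 4, subj_value = 1,
                           subj_noise = 0) {
  nm <- cbtmech:::re_param_names(n_subjects, intervention = TRUE)
  n <- length(phi_draws)
  draws <- matrix(0, n, length(nm), dimnames = list(NULL, nm))
  draws[, "phi_rewSens"] <- phi_draws
  draws[, "phi_effSens"] <- phi_draws
  subj_cols <- grep("^(rewSens|effSens)\\[", nm, value = TRUE)
  for (cn in subj_cols)
    draws[, cn] <- subj_value + subj_noise * rnorm(n)
  summaries <- data.frame(parameter = nm, mean = colMeans(draws),
                          sd = apply(draws, 2, sd),
                          q05 = apply(draws, 2, quantile, 0.05),
                          q50 = apply(draws, 2, quantile, 0.5),
                          q95 = apply(draws, 2, quantile, 0.95),
                          rhat = 1)
  structure(list(chains = list(draws), draws = draws, summaries = summaries,
                 model = "reward_effort",
                 data_info = list(subject_ids = seq_len(n_subjects),
                                  arm = rep(c("active", "control"),
                                            length.out = n_subjects),
                                  intervention = TRUE),
                 mcmc = NULL, group_params = grep("^(mu_|sigma_|R_|phi_)", nm,
                                                  value = TRUE),
                 converged = TRUE),
            class = c("reward_effort_fit", "hb_fit"))
}

# conjugate normal-mean adapter: posterior is exact, so SBC must be uniform
conjugate_adapter <- function(n_obs = 30, n_draws = 400) {
  list(
    sample_prior = function() list(pars = c(m = rnorm(1))),
    simulate_data = function(prior) rnorm(n_obs, prior$pars[["m"]], 1),
    fit = function(data) {
      post_m <- sum(data) / (n_obs + 1)
      post_s <- sqrt(1 / (n_obs + 1))
      matrix(rnorm(n_draws, post_m, post_s), ncol = 1,
             dimnames = list(NULL, "m"))
    })
}
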