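#' Prior settings for the reward-effort model
#'
#' Group means are centred on zero with scales matched to the predictor
#' units (rewards are in coins, efforts in fractions of maximum, so the
#' effort-sensitivity scale is wider); subject SDs are half-normal(1); the
#' cross-session correlation is uniform on \[-1, 1\]; the intervention effect
#' and any trait moderation weights are standard normal.
#'
#' @param mu_scale length-2 prior SD of the group means (rewSens, effSens).
#' @param sd_scale length-2 half-normal scale of the subject SDs.
#' @param phi_scale prior SD of the intervention effect.
#' @param beta_scale prior SD of moderation weights in joint models.
#' @return list of class `"re_priors"`.
#' @export
re_priors <- function(mu_scale = c(rewSens = 2, effSens = 5),
                      sd_scale = c(rewSens = 1, effSens = 1),
                      phi_scale = 1, beta_scale = 1) {
  structure(list(mu_scale = mu_scale, sd_scale = sd_scale,
                 phi_scale = phi_scale, beta_scale = beta_scale),
            class = "re_priors")
}

# prepare choice data for the sampler: 0-based ids, catch trials dropped
re_prepare <- function(data, include_catch = FALSE) {
  need <- c("subject_id", "session", "reward_hi", "reward_lo",
            "effort_hi", "effort_lo", "choice_hi")
  if (!all(need %in% names(data)))
    stop("choice data is missing columns: ",
         paste(setdiff(need, names(data)), collapse = ", "), call. = FALSE)
  if (!include_catch && "is_catch" %in% names(data))
    data <- data[data$is_catch == 0, , drop = FALSE]
  ids <- sort(unique(data$subject_id))
  sess <- sort(unique(data$session))
  if (!identical(as.integer(sess), 1:2))
    stop("expected exactly sessions 1 and 2", call. = FALSE)
  arm <- if ("arm" %in% names(data))
    vapply(ids, function(i) as.character(data$arm[data$subject_id == i][1]),
           character(1))
  else rep("control", length(ids))
  list(data = data, ids = ids, arm = arm,
       subj0 = match(data$subject_id, ids) - 1L,
       sess0 = as.integer(data$session) - 1L,
       dr = data$reward_hi - data$reward_lo,
       de = data$effort_hi - data$effort_lo,
       y = as.integer(data$choice_hi),
       active = as.integer(arm == "active"))
}

re_param_names <- function(P, intervention, traits = character(0),
                           item_ids = NULL, item_K = NULL) {
  nm <- c(sprintf("mu_rewSens[%d]", 1:2), sprintf("mu_effSens[%d]", 1:2),
          sprintf("sigma_rewSens[%d]", 1:2), sprintf("sigma_effSens[%d]", 1:2),
          "R_rewSens", "R_effSens")
  if (intervention) nm <- c(nm, "phi_rewSens", "phi_effSens")
  for (tr in traits) nm <- c(nm, sprintf("beta_base_%s", tr), sprintf("beta_int_%s", tr))
  if (!is.null(item_ids))
    for (j in seq_along(item_ids))
      nm <- c(nm, sprintf("disc[%s]", item_ids[j]),
              sprintf("kappa[%s,%d]", item_ids[j], seq_len(item_K[j] - 1)))
  if (!is.null(item_ids))
    for (tr in traits) nm <- c(nm, sprintf("theta_%s[%d]", tr, seq_len(P)))
  subj <- as.vector(vapply(seq_len(P), function(p)
    c(sprintf("rewSens[%d,1]", p), sprintf("rewSens[%d,2]", p),
      sprintf("effSens[%d,1]", p), sprintf("effSens[%d,2]", p)),
    character(4)))
  c(nm, subj)
}

#' Fit the hierarchical reward-effort choice model
#'
#' Two-session Bernoulli-logit value model: per subject and session, the
#' logit of choosing the higher-reward option is
#' `rewSens * (reward_hi - reward_lo) - effSens * (effort_hi - effort_lo)`.
#' Subject parameters are bivariate normal across sessions (non-centred
#' parameterization), and allocation to the active arm adds a group-level
#' effect to each parameter at session 2. Sampling is by adaptive
#' Metropolis-within-Gibbs (see the package vignette for the algorithm and
#' its validation by simulation-based calibration).
#'
#' Catch trials are excluded from the likelihood by default: they are
#' dominated choices serving attention checking and would otherwise distort
#' sensitivity estimates.
#'
#' @param data choice dataset (schema of [simulate_reward_effort_cohort()]);
#'   expected to have passed [apply_exclusion_rules()].
#' @param mcmc an [mcmc_control()].
#' @param priors an [re_priors()].
#' @param intervention estimate a group-level active-arm effect at session 2?
#'   Set `FALSE` for single-arm (e.g. test-retest) data.
#' @param include_catch include catch trials in the likelihood?
#' @return An object of class `c("reward_effort_fit", "hb_fit")`; inspect
#'   with `print()`, `summary()`, [posterior_draws()],
#'   [intervention_effect_summary()].
#' @export
fit_reward_effort <- function(data, mcmc = mcmc_control(), priors = re_priors(),
                              intervention = TRUE, include_catch = FALSE) {
  prep <- re_prepare(data, include_catch)
  if (intervention && (sum(prep$active) < 2 || sum(!prep$active) < 2))
    stop("need at least 2 subjects per arm to estimate an intervention effect",
         call. = FALSE)
  if (!is.null(mcmc$seed)) set.seed(mcmc$seed)
  P <- length(prep$ids)
  n_keep <- (mcmc$iter - mcmc$warmup) %/% mcmc$thin
  chains <- lapply(seq_len(mcmc$chains), function(ch)
    sample_re_cpp(prep$subj0, prep$sess0, prep$dr, prep$de, prep$y,
                  prep$active, intervention, list(), -1L, 0L,
                  c(priors$mu_scale, priors$sd_scale, priors$phi_scale,
                    priors$beta_scale),
                  mcmc$warmup, n_keep, mcmc$thin, numeric(0)))
  nm <- re_param_names(P, intervention)
  group <- nm[seq_len(10 + if (intervention) 2 else 0)]
  fit <- new_hb_fit(chains, nm, "reward_effort",
                    list(subject_ids = prep$ids, arm = prep$arm,
                         n_trials = nrow(prep$data), intervention = intervention),
                    mcmc, group)
  if (!is.na(fit$converged) && !fit$converged)
    warning("reward-effort fit: R-hat > 1.05 on at least one group-level parameter",
            call. = FALSE)
  fit
}
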