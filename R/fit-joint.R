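#' Jointly fit a behavioural task model with symptom-trait moderation
#'
#' Extends the behavioural model (reward-effort or attribution, detected from
#' the columns of `task_data`) with a graded-response measurement model for
#' the ordinal symptom items, and regression weights that let each latent
#' trait shift the target parameter at baseline (`beta_base`) and modulate
#' the magnitude of the active-intervention effect at session 2 (`beta_int`).
#' The group-level intervention effect then plays the role of an intercept.
#' A 90% credible interval excluding zero on a weight is the package's
#' decision rule for a meaningful moderation.
#'
#' In the default single-stage mode the trait estimates and behavioural
#' parameters are estimated in one posterior, so measurement uncertainty in
#' the traits propagates into the moderation weights. The `"two_step"` mode
#' (a diagnostic) first fits the GRM alone and then plugs posterior-mean
#' traits into the behavioural model as fixed covariates.
#'
#' @param task_data a choice dataset (`choice_hi` column) or an attribution
#'   dataset (`choice_internal` column).
#' @param item_data ordinal item responses (`subject_id`, `item_id`, `trait`,
#'   `response`); subjects are matched to `task_data` by `subject_id` and
#'   must overlap.
#' @param target moderated parameter: for choice data `"effSens"` (default)
#'   or `"rewSens"`; for attribution data a string `"internal_pos"`,
#'   `"internal_neg"`, `"global_pos"` or `"global_neg"` (default
#'   `"internal_pos"`).
#' @param traits trait labels entering the model, subset of `c("A", "N")`.
#' @param mcmc an [mcmc_control()].
#' @param priors an [re_priors()] or [att_priors()] matching the task.
#' @param method `"joint"` (single stage) or `"two_step"`.
#' @return An `hb_fit` whose parameters include `beta_base_<trait>` and
#'   `beta_int_<trait>`; summarise with [joint_coefficients()].
#' @export
fit_joint <- function(task_data, item_data, target = NULL,
                      traits = c("A"), mcmc = mcmc_control(), priors = NULL,
                      method = c("joint", "two_step")) {
  method <- match.arg(method)
  traits <- match.arg(traits, c("A", "N"), several.ok = TRUE)
  is_choice <- "choice_hi" %in% names(task_data)
  if (!is_choice && !"choice_internal" %in% names(task_data))
    stop("task_data is neither a choice nor an attribution dataset", call. = FALSE)

  if (is_choice) {
    if (is.null(target)) target <- "effSens"
    target_k <- match(target, c("rewSens", "effSens"))
    if (is.na(target_k)) stop("unknown target parameter: ", target, call. = FALSE)
    if (is.null(priors)) priors <- re_priors()
    prep <- re_prepare(task_data)
  } else {
    if (is.null(target)) target <- "internal_pos"
    parts <- strsplit(target, "_", fixed = TRUE)[[1]]
    target_d <- match(parts[1], c("internal", "global"))
    target_v <- match(parts[2], c("neg", "pos"))
    if (is.na(target_d) || is.na(target_v))
      stop("unknown target parameter: ", target, call. = FALSE)
    if (is.null(priors)) priors <- att_priors()
    prep <- att_prepare(task_data)
  }

  gprep <- grm_prepare(item_data, traits, subject_ids = prep$ids)
  if (!length(intersect(gprep$subject_ids, prep$ids)))
    stop("no overlapping subjects between task and item data", call. = FALSE)
  grm <- list(subj = gprep$subj, item = gprep$item, y = gprep$y, K = gprep$K,
              trait = gprep$trait)

  if (!is.null(mcmc$seed)) set.seed(mcmc$seed)
  P <- length(prep$ids)
  n_keep <- (mcmc$iter - mcmc$warmup) %/% mcmc$thin
  n_traits <- length(traits)

  theta_fixed <- numeric(0)
  if (method == "two_step") {
    if (!is_choice)
      stop("two_step mode is only implemented for choice data", call. = FALSE)
    # plug-in traits: one GRM per trait, posterior means
    step_mcmc <- mcmc
    step_mcmc$seed <- NULL
    theta_fixed <- unlist(lapply(traits, function(tr) {
      gf <- fit_grm(item_data[item_data$subject_id %in% prep$ids, , drop = FALSE],
                    trait = tr, mcmc = step_mcmc)
      est <- trait_estimates(gf)
      est$estimate[match(prep$ids, est$subject_id)]
    }))
    theta_fixed[is.na(theta_fixed)] <- 0
    grm <- list()
  }

  if (is_choice) {
    chains <- lapply(seq_len(mcmc$chains), function(ch)
      sample_re_cpp(prep$subj0, prep$sess0, prep$dr, prep$de, prep$y,
                    prep$active, TRUE, grm, target_k - 1L, n_traits,
                    c(priors$mu_scale, priors$sd_scale, priors$phi_scale,
                      priors$beta_scale),
                    mcmc$warmup, n_keep, mcmc$thin, theta_fixed))
    nm <- re_param_names(P, TRUE, traits,
                         if (length(grm)) gprep$item_ids else NULL,
                         if (length(grm)) gprep$K else NULL)
    n_group <- 12 + 2 * n_traits
    model <- "reward_effort_joint"
  } else {
    chains <- lapply(seq_len(mcmc$chains), function(ch)
      sample_att_cpp(prep$n_cell, prep$k_cell, prep$active, TRUE,
                     grm, target_v - 1L, target_d - 1L, n_traits,
                     c(priors$mu_scale, priors$sd_scale, priors$phi_scale,
                       priors$beta_scale),
                     mcmc$warmup, n_keep, mcmc$thin))
    nm <- att_param_names(P, TRUE, traits, gprep$item_ids, gprep$K)
    n_group <- 32 + 2 * n_traits
    model <- "attribution_joint"
  }
  group <- nm[seq_len(n_group)]
  fit <- new_hb_fit(chains, nm, model,
                    list(subject_ids = prep$ids, arm = prep$arm,
                         intervention = TRUE, target = target, traits = traits,
                         method = method),
                    mcmc, group)
  if (!is.na(fit$converged) && !fit$converged)
    warning("joint fit: R-hat > 1.05 on at least one group-level parameter",
            call. = FALSE)
  fit
}

#' Moderation coefficients of a joint fit
#'
#' @param fit a fit from [fit_joint()].
#' @param level credible level for the central interval.
#' @return data frame with one row per (trait, role) coefficient: posterior
#'   mean, central interval, and whether the interval excludes zero.
#' @export
joint_coefficients <- function(fit, level = 0.90) {
  stopifnot(inherits(fit, "hb_fit"))
  traits <- fit$data_info$traits
  rows <- list()
  a <- (1 - level) / 2
  for (tr in traits)
    for (role in c("base", "int")) {
      pn <- sprintf("beta_%s_%s", role, tr)
      d <- posterior_draws(fit, pn)
      q <- quantile(d, c(a, 1 - a), names = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        trait = tr, role = role, parameter = pn, mean = mean(d),
        lower = q[1], upper = q[2],
        excludes_zero = q[1] > 0 || q[2] < 0)
    }
  do.call(rbind, rows)
}
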