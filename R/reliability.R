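#' Model-based test-retest reliability
#'
#' Fits the two-session hierarchical model with separate group means per
#' session, no intervention term, and a uniform prior on the cross-session
#' correlation of subject parameters, then reports the posterior of that
#' correlation as the reliability estimate. This propagates per-subject
#' measurement uncertainty instead of correlating noisy point estimates.
#'
#' @param data a two-session dataset (choice or attribution schema); every
#'   subject must have both sessions.
#' @param model `"reward_effort"` or `"attribution"`.
#' @param mcmc an [mcmc_control()].
#' @param level credible level for the reported interval.
#' @return data frame of class `"reliability_estimate"`: `parameter`, `R_mu`
#'   (posterior mean), `lower`, `upper`; the full draws are kept in the
#'   `"draws"` attribute and the fit in `"fit"`.
#' @export
estimate_test_retest <- function(data, model = c("reward_effort", "attribution"),
                                 mcmc = mcmc_control(), level = 0.90) {
  model <- match.arg(model)
  per_subj <- tapply(data$session, data$subject_id,
                     function(s) length(unique(s)))
  if (any(per_subj < 2))
    stop("every subject needs data from both sessions", call. = FALSE)
  if (model == "reward_effort") {
    fit <- fit_reward_effort(data, mcmc = mcmc, intervention = FALSE)
    pars <- c("R_rewSens", "R_effSens")
  } else {
    fit <- fit_attribution(data, mcmc = mcmc, intervention = FALSE)
    # cross-session correlations of the same dimension
    pars <- c("R_neg[int1,int2]", "R_neg[glob1,glob2]",
              "R_pos[int1,int2]", "R_pos[glob1,glob2]")
  }
  a <- (1 - level) / 2
  rows <- lapply(pars, function(p) {
    d <- posterior_draws(fit, p)
    q <- quantile(d, c(a, 1 - a), names = FALSE)
    data.frame(parameter = p, R_mu = mean(d), lower = q[1], upper = q[2])
  })
  out <- do.call(rbind, rows)
  attr(out, "draws") <- fit$draws[, pars, drop = FALSE]
  attr(out, "fit") <- fit
  class(out) <- c("reliability_estimate", "data.frame")
  out
}

#' Posterior predictive accuracy
#'
#' Replicates each subject's responses stochastically from their posterior
#' parameter estimates and scores the fraction of trials on which the
#' replicate matches the observed response, averaged over replications.
#' For attribution data the internal and global codes are scored as two
#' separate accuracy streams.
#'
#' @param fit a `reward_effort_fit` or `attribution_fit`.
#' @param data the dataset the fit was computed from.
#' @param n_replications stochastic replicates per subject.
#' @param seed integer seed.
#' @param use `"mean"` replicates from posterior-mean parameters;
#'   `"draws"` redraws parameters from the posterior per replication.
#' @return list with `per_subject` (data frame) and `mean`/`sd` across
#'   subjects (per stream for attribution data).
#' @export
posterior_predictive_accuracy <- function(fit, data, n_replications = 100,
                                          seed = 1L, use = c("mean", "draws")) {
  use <- match.arg(use)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ids <- fit$data_info$subject_ids
  if (inherits(fit, "reward_effort_fit")) {
    d <- data[data$is_catch == 0, , drop = FALSE]
    p_i <- match(d$subject_id, ids)
    acc <- numeric(length(ids))
    for (pi in seq_along(ids)) {
      rows <- which(p_i == pi)
      dd <- d[rows, ]
      a_rep <- numeric(n_replications)
      for (r in seq_len(n_replications)) {
        if (use == "mean") {
          rs <- fit$summaries$mean[match(sprintf("rewSens[%d,%d]", pi, dd$session),
                                         fit$summaries$parameter)]
          es <- fit$summaries$mean[match(sprintf("effSens[%d,%d]", pi, dd$session),
                                         fit$summaries$parameter)]
        } else {
          k <- sample.int(nrow(fit$draws), 1L)
          rs <- fit$draws[k, sprintf("rewSens[%d,%d]", pi, dd$session)]
          es <- fit$draws[k, sprintf("effSens[%d,%d]", pi, dd$session)]
        }
        pr <- plogis(rs * (dd$reward_hi - dd$reward_lo) -
                       es * (dd$effort_hi - dd$effort_lo))
        rep_choice <- rbinom(nrow(dd), 1L, pr)
        a_rep[r] <- mean(rep_choice == dd$choice_hi)
      }
      acc[pi] <- mean(a_rep)
    }
    per_subject <- data.frame(subject_id = ids, accuracy = acc)
    list(per_subject = per_subject, mean = mean(acc), sd = sd(acc))
  } else {
    d <- data
    p_i <- match(d$subject_id, ids)
    v_i <- match(d$valence, c("neg", "pos"))
    acc_int <- acc_glob <- numeric(length(ids))
    d_short <- c("int", "glob")
    for (pi in seq_along(ids)) {
      rows <- which(p_i == pi)
      dd <- d[rows, ]
      vl <- c("neg", "pos")[v_i[rows]]
      a_int <- a_glob <- numeric(n_replications)
      for (r in seq_len(n_replications)) {
        get_theta <- function(dim) {
          nm <- sprintf("theta_%s_%s[%d,%d]", dim, vl, pi, dd$session)
          if (use == "mean")
            fit$summaries$mean[match(nm, fit$summaries$parameter)]
          else fit$draws[sample.int(nrow(fit$draws), 1L), nm]
        }
        a_int[r] <- mean(rbinom(nrow(dd), 1L, plogis(get_theta("int"))) ==
                           dd$choice_internal)
        a_glob[r] <- mean(rbinom(nrow(dd), 1L, plogis(get_theta("glob"))) ==
                            dd$choice_global)
      }
      acc_int[pi] <- mean(a_int)
      acc_glob[pi] <- mean(a_glob)
    }
    per_subject <- data.frame(subject_id = ids, accuracy_internal = acc_int,
                              accuracy_global = acc_glob)
    list(per_subject = per_subject,
         mean = c(internal = mean(acc_int), global = mean(acc_glob)),
         sd = c(internal = sd(acc_int), global = sd(acc_glob)))
  }
}

#' Likelihood-based pseudo-R-squared
#'
#' `1 - L / C`, where `L` is the model's summed log likelihood and `C` the
#' chance log likelihood `n_trials * log(1 / n_options)`: 0 at chance, 1 at
#' perfect prediction.
#'
#' @param L summed log likelihood (<= 0).
#' @param n_trials number of Bernoulli/choice observations in `L`.
#' @param n_options options per trial (2 for binary codes).
#' @return scalar pseudo-R2 (<= 1).
#' @export
pseudo_r2 <- function(L, n_trials, n_options = 2) {
  if (L > 0) stop("log likelihood must be <= 0", call. = FALSE)
  if (n_trials <= 0) stop("n_trials must be positive", call. = FALSE)
  C <- n_trials * log(1 / n_options)
  1 - L / C
}

#' Goodness-of-fit metrics for a behavioural fit
#'
#' Combines posterior predictive accuracy and pseudo-R2 (computed at the
#' posterior-mean subject parameters, with a draws-averaged option) with the
#' worst group-level R-hat.
#'
#' @param fit a `reward_effort_fit` or `attribution_fit`.
#' @param data the fitted dataset.
#' @param n_replications replicates for the accuracy computation.
#' @param seed integer seed.
#' @param likelihood `"mean"` evaluates L at posterior-mean subject
#'   parameters; `"draws"` averages the log likelihood over posterior draws.
#' @return list: `ppa_mean`, `ppa_sd`, `pseudo_r2`, `L`, `C`, `max_rhat`.
#' @export
fit_metrics <- function(fit, data, n_replications = 100, seed = 1L,
                        likelihood = c("mean", "draws")) {
  likelihood <- match.arg(likelihood)
  ids <- fit$data_info$subject_ids
  if (inherits(fit, "reward_effort_fit")) {
    d <- data[data$is_catch == 0, , drop = FALSE]
    grid <- expand.grid(session = 1:2, subject_id = ids)
    nm_r <- sprintf("rewSens[%d,%d]", match(grid$subject_id, ids), grid$session)
    nm_e <- sprintf("effSens[%d,%d]", match(grid$subject_id, ids), grid$session)
    if (likelihood == "mean") {
      params <- data.frame(subject_id = grid$subject_id, session = grid$session,
                           rewSens = fit$summaries$mean[match(nm_r, fit$summaries$parameter)],
                           effSens = fit$summaries$mean[match(nm_e, fit$summaries$parameter)])
      L <- dataset_loglik(params, d)
    } else {
      ndr <- nrow(fit$draws)
      take <- seq(1, ndr, length.out = min(200, ndr))
      L <- mean(vapply(take, function(k) {
        params <- data.frame(subject_id = grid$subject_id, session = grid$session,
                             rewSens = fit$draws[k, nm_r], effSens = fit$draws[k, nm_e])
        dataset_loglik(params, d)
      }, numeric(1)))
    }
    n_tr <- nrow(d)
  } else {
    grid <- expand.grid(valence = c("neg", "pos"), session = 1:2,
                        subject_id = ids, stringsAsFactors = FALSE)
    nm_i <- sprintf("theta_int_%s[%d,%d]", grid$valence,
                    match(grid$subject_id, ids), grid$session)
    nm_g <- sprintf("theta_glob_%s[%d,%d]", grid$valence,
                    match(grid$subject_id, ids), grid$session)
    traits <- data.frame(subject_id = grid$subject_id, session = grid$session,
                         valence = grid$valence,
                         theta_internal = fit$summaries$mean[match(nm_i, fit$summaries$parameter)],
                         theta_global = fit$summaries$mean[match(nm_g, fit$summaries$parameter)])
    L <- attribution_loglik(traits, data)
    n_tr <- 2L * nrow(data)  # two binary codes per trial
  }
  ppa <- posterior_predictive_accuracy(fit, data, n_replications, seed)
  gp_rhat <- fit$summaries$rhat[fit$summaries$parameter %in% fit$group_params]
  list(ppa_mean = ppa$mean, ppa_sd = ppa$sd,
       pseudo_r2 = pseudo_r2(L, n_tr), L = L, C = n_tr * log(0.5),
       max_rhat = if (all(is.na(gp_rhat))) NA_real_ else max(gp_rhat, na.rm = TRUE))
}
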