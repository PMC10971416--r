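#' Rank of a true value within posterior draws
#'
#' The number of draws strictly below the true value, with ties broken by
#' uniform randomisation (relevant only for discrete or degenerate
#' posteriors). Under a correctly calibrated sampler the rank is uniform on
#' `0..D` where `D` is the number of draws.
#'
#' @param true_value scalar.
#' @param draws numeric vector of posterior draws.
#' @return integer rank in `[0, length(draws)]`.
#' @export
rank_statistic <- function(true_value, draws) {
  if (!length(draws)) stop("empty draws", call. = FALSE)
  n_lt <- sum(draws < true_value)
  n_eq <- sum(draws == true_value)
  if (n_eq > 0) n_lt <- n_lt + sample.int(n_eq + 1L, 1L) - 1L
  as.integer(n_lt)
}

#' Uniformity diagnostics for SBC ranks
#'
#' Chi-square goodness-of-fit over equal-width bins of `0..D`, plus a
#' distribution-free ECDF envelope check (Dvoretzky-Kiefer-Wolfowitz bound
#' at the given level).
#'
#' @param ranks integer ranks in `[0, D]`.
#' @param D number of posterior draws each rank was computed against.
#' @param n_bins number of equal-width bins (must not exceed the number of
#'   ranks).
#' @param ecdf_alpha level of the ECDF envelope.
#' @return list: `statistic`, `df`, `p_value`, `bin_counts`, `ecdf_ok`.
#' @export
uniformity_diagnostics <- function(ranks, D, n_bins = 10, ecdf_alpha = 0.01) {
  N <- length(ranks)
  if (n_bins > N) stop("more bins than ranks", call. = FALSE)
  if (any(ranks < 0 | ranks > D)) stop("ranks outside [0, D]", call. = FALSE)
  # D + 1 possible values split into equal-probability bins
  br <- seq(0, D + 1, length.out = n_bins + 1)
  counts <- table(cut(ranks + 0.5, breaks = br, include.lowest = TRUE))
  expected <- N / n_bins
  stat <- sum((counts - expected)^2 / expected)
  p <- pchisq(stat, df = n_bins - 1, lower.tail = FALSE)
  u <- (ranks + 0.5) / (D + 1)
  dev <- max(abs(sort(u) - (seq_len(N) - 0.5) / N))
  crit <- sqrt(log(2 / ecdf_alpha) / (2 * N))
  list(statistic = as.numeric(stat), df = n_bins - 1, p_value = p,
       bin_counts = as.integer(counts), ecdf_ok = dev < crit + 0.5 / N)
}

#' Simulation-based calibration of a model's inference procedure
#'
#' Repeatedly draws ground truth from the prior, simulates a dataset from it,
#' fits the model, and records the rank of each monitored true value within
#' the (thinned) posterior draws. If simulation and inference are mutually
#' consistent the ranks are uniform; [uniformity_diagnostics()] quantifies
#' departures. Draws are thinned before ranking to mitigate the
#' autocorrelation of MCMC output.
#'
#' @param adapter a model adapter: a list with functions
#'   `sample_prior()` (returns a named vector of monitored true values plus
#'   whatever state `simulate_data` needs), `simulate_data(prior)` and
#'   `fit(data)` (returns a matrix of posterior draws with columns named
#'   like the prior vector; may carry a `converged` attribute). See
#'   [sbc_adapter_reward_effort()].
#' @param n_datasets number of simulated datasets.
#' @param thinning keep every `thinning`-th draw before ranking.
#' @param seed integer root seed; every dataset derives its own stream.
#' @return list of class `"sbc_result"`: `ranks` (dataset x parameter
#'   matrix), `D`, `n_datasets`, `n_excluded`, `diagnostics` (per-parameter
#'   [uniformity_diagnostics()]).
#' @export
sbc_run <- function(adapter, n_datasets = 200, thinning = 4, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  dataset_seeds <- sample.int(.Machine$integer.max, n_datasets)
  ranks <- NULL
  D <- NULL
  n_excluded <- 0L
  for (i in seq_len(n_datasets)) {
    set.seed(dataset_seeds[i])
    prior <- adapter$sample_prior()
    data <- adapter$simulate_data(prior)
    draws <- adapter$fit(data)
    if (identical(attr(draws, "converged"), FALSE)) {
      n_excluded <- n_excluded + 1L
      next
    }
    keep <- seq(thinning, nrow(draws), by = thinning)
    draws <- draws[keep, , drop = FALSE]
    pars <- intersect(names(prior$pars), colnames(draws))
    r <- vapply(pars, function(p) rank_statistic(prior$pars[[p]], draws[, p]),
                integer(1))
    if (is.null(ranks)) {
      ranks <- matrix(NA_integer_, n_datasets, length(pars),
                      dimnames = list(NULL, pars))
      D <- nrow(draws)
    }
    ranks[i, ] <- r
  }
  ranks <- ranks[rowSums(is.na(ranks)) == 0, , drop = FALSE]
  diagnostics <- lapply(colnames(ranks), function(p)
    uniformity_diagnostics(ranks[, p], D, n_bins = max(5, min(10, nrow(ranks) %/% 20))))
  names(diagnostics) <- colnames(ranks)
  structure(list(ranks = ranks, D = D, n_datasets = n_datasets,
                 n_excluded = n_excluded, diagnostics = diagnostics,
                 thinning = thinning, seed = seed),
            class = "sbc_result")
}

#' @export
print.sbc_result <- function(x, ...) {
  cat(sprintf("SBC: %d datasets (%d excluded), D = %d thinned draws\n",
              x$n_datasets, x$n_excluded, x$D))
  p <- vapply(x$diagnostics, `[[`, numeric(1), "p_value")
  out <- data.frame(parameter = names(p), chisq_p = round(p, 4),
                    ecdf_ok = vapply(x$diagnostics, `[[`, logical(1), "ecdf_ok"))
  print(out, row.names = FALSE)
  invisible(x)
}

#' SBC adapter for the reward-effort model
#'
#' Ground truth for the group-level quantities is drawn from the model's own
#' priors (the self-consistency requirement of the method), a cohort is
#' simulated from the generative model, and the model is refitted with the
#' same priors. Monitored parameters are all group-level quantities plus a
#' fixed random subset of subject-level parameters.
#'
#' @param n_subjects cohort size per simulated dataset.
#' @param design trial array (defaults to the published 44-trial design).
#' @param mcmc sampler settings for each refit (short chains by default:
#'   calibration needs many fits, not long ones).
#' @param priors an [re_priors()].
#' @param intervention include the intervention arm and effect?
#' @param n_subject_monitor how many subject-level parameters to monitor.
#' @return an adapter list for [sbc_run()].
#' @export
sbc_adapter_reward_effort <- function(n_subjects = 20,
                                      design = generate_task_design(),
                                      mcmc = mcmc_control(chains = 2, iter = 650,
                                                          warmup = 250),
                                      priors = re_priors(),
                                      intervention = TRUE,
                                      n_subject_monitor = 5) {
  monitor_subj <- unique(round(seq(1, n_subjects,
                                   length.out = min(n_subject_monitor, n_subjects))))
  list(
    name = "reward_effort",
    sample_prior = function() {
      mu <- matrix(c(rnorm(2, 0, priors$mu_scale[1]),
                     rnorm(2, 0, priors$mu_scale[2])), 2, byrow = TRUE)
      sdm <- matrix(abs(rnorm(4, 0, rep(priors$sd_scale, each = 2))), 2,
                    byrow = TRUE)
      R <- runif(2, -1, 1)
      phi <- if (intervention) rnorm(2, 0, priors$phi_scale) else c(0, 0)
      # subject-level truth is part of the generative hierarchy and is
      # monitored for a fixed subset of subjects
      P <- n_subjects
      arm <- assign_arms(P)
      spars <- array(NA_real_, c(P, 2, 2))
      for (k in 1:2) {
        s1 <- sdm[k, 1]; s2 <- sdm[k, 2]
        Sig <- matrix(c(s1^2, R[k] * s1 * s2, R[k] * s1 * s2, s2^2), 2)
        spars[, k, ] <- mvn_draw(P, mu[k, ], Sig)
        spars[arm == "active", k, 2] <- spars[arm == "active", k, 2] + phi[k]
      }
      pars <- c(mu[1, 1], mu[1, 2], mu[2, 1], mu[2, 2],
                sdm[1, ], sdm[2, ], R, if (intervention) phi)
      names(pars) <- re_param_names(0, intervention)[seq_along(pars)]
      extra <- setNames(spars[monitor_subj, 2, 1],
                        sprintf("effSens[%d,1]", monitor_subj))
      list(pars = c(pars, extra), spars = spars, arm = arm)
    },
    simulate_data = function(prior) {
      sim_choices_from_params(design, prior$spars, prior$arm)
    },
    fit = function(data) {
      fit <- suppressWarnings(
        fit_reward_effort(data, mcmc = mcmc, intervention = intervention,
                          priors = priors))
      d <- fit$draws
      rh <- fit$summaries$rhat[fit$summaries$parameter %in% fit$group_params]
      attr(d, "converged") <- all(is.na(rh)) || all(rh < 1.2)
      d
    },
    monitor_extra = monitor_subj
  )
}

#' SBC adapter for the attribution model
#'
#' @inheritParams sbc_adapter_reward_effort
#' @param design scenario schedule (defaults to the published 32-scenario
#'   design).
#' @return an adapter list for [sbc_run()].
#' @export
sbc_adapter_attribution <- function(n_subjects = 20,
                                    design = generate_attribution_design(),
                                    mcmc = mcmc_control(chains = 2, iter = 650,
                                                        warmup = 250),
                                    priors = att_priors(),
                                    intervention = TRUE) {
  list(
    name = "attribution",
    sample_prior = function() {
      mu <- matrix(rnorm(8, 0, priors$mu_scale), 4, 2)
      sdv <- matrix(abs(rnorm(8, 0, priors$sd_scale)), 4, 2)
      corr <- lapply(1:2, function(v) rlkj_corr(4))
      phi <- if (intervention) matrix(rnorm(4, 0, priors$phi_scale), 2, 2)
        else matrix(0, 2, 2)
      pars <- c()
      for (v in 1:2) {
        vl <- c("neg", "pos")[v]
        pars <- c(pars,
                  setNames(mu[, v], c(sprintf("mu_int_%s[1]", vl),
                                      sprintf("mu_glob_%s[1]", vl),
                                      sprintf("mu_int_%s[2]", vl),
                                      sprintf("mu_glob_%s[2]", vl))),
                  setNames(sdv[, v], c(sprintf("sigma_int_%s[1]", vl),
                                       sprintf("sigma_glob_%s[1]", vl),
                                       sprintf("sigma_int_%s[2]", vl),
                                       sprintf("sigma_glob_%s[2]", vl))))
        if (intervention)
          pars <- c(pars, setNames(phi[, v], c(sprintf("phi_int_%s", vl),
                                               sprintf("phi_glob_%s", vl))))
      }
      P <- n_subjects
      arm <- assign_arms(P)
      theta <- array(NA_real_, c(P, 2, 4))
      for (v in 1:2) {
        Sig <- diag(sdv[, v]) %*% corr[[v]] %*% diag(sdv[, v])
        theta[, v, ] <- mvn_draw(P, mu[, v], Sig)
        for (d in 1:2)
          theta[arm == "active", v, d + 2] <-
            theta[arm == "active", v, d + 2] + phi[d, v]
      }
      extra <- setNames(theta[1:3, 1, 1], sprintf("theta_int_neg[%d,1]", 1:3))
      list(pars = c(pars, extra), theta = theta, arm = arm)
    },
    simulate_data = function(prior) {
      sim_attributions_from_theta(design, prior$theta, prior$arm)
    },
    fit = function(data) {
      fit <- suppressWarnings(
        fit_attribution(data, mcmc = mcmc, intervention = intervention,
                        priors = priors))
      d <- fit$draws
      rh <- fit$summaries$rhat[fit$summaries$parameter %in% fit$group_params]
      attr(d, "converged") <- all(is.na(rh)) || all(rh < 1.2)
      d
    }
  )
}

#' Deliberately miscalibrated adapter (negative control)
#'
#' Wraps an adapter and shifts every posterior draw by `shift_sd` posterior
#' SDs. A correct SBC procedure must reject uniformity for such an adapter;
#' this is the package's built-in negative control.
#'
#' @param adapter an adapter as for [sbc_run()].
#' @param shift_sd shift in posterior-SD units.
#' @return a wrapped adapter.
#' @export
sbc_adapter_biased <- function(adapter, shift_sd = 1) {
  out <- adapter
  out$fit <- function(data) {
    d <- adapter$fit(data)
    conv <- attr(d, "converged")
    d <- sweep(d, 2, shift_sd * apply(d, 2, sd), "+")
    attr(d, "converged") <- conv
    d
  }
  out
}

# random correlation matrix from the LKJ(1) distribution via the vine of
# canonical partial correlations (matches the sampler's prior exactly)
rlkj_corr <- function(K) {
  cz <- numeric(K * (K - 1) / 2)
  pos <- 1
  for (i in seq_len(K - 1))
    for (j in (i + 1):K) {
      b <- 1 + (K - 1 - (j - i)) / 2
      cz[pos] <- atanh(2 * rbeta(1, b, b) - 1)
      pos <- pos + 1
    }
  cpc_chol(cz, K)
}

# lower Cholesky -> correlation matrix from atanh partial correlations,
# mirroring the C++ construction
cpc_chol <- function(cz, K) {
  zc <- matrix(0, K, K)
  pos <- 1
  for (i in seq_len(K - 1))
    for (j in (i + 1):K) { zc[i, j] <- tanh(cz[pos]); pos <- pos + 1 }
  L <- matrix(0, K, K)
  L[1, 1] <- 1
  for (i in 2:K) {
    s <- 0
    for (j in seq_len(i - 1)) {
      L[i, j] <- zc[j, i] * sqrt(1 - s)
      s <- s + L[i, j]^2
    }
    L[i, i] <- sqrt(1 - s)
  }
  L %*% t(L)
}

# simulate choices for given subject parameter array (P x 2 x 2)
sim_choices_from_params <- function(design, pars, arm) {
  P <- dim(pars)[1]
  n_trials <- nrow(design)
  idx_p <- rep(seq_len(P), each = 2 * n_trials)
  idx_s <- rep(rep(1:2, each = n_trials), times = P)
  idx_t <- rep(seq_len(n_trials), times = 2 * P)
  logit <- pars[cbind(idx_p, 1, idx_s)] *
    (design$reward_hi[idx_t] - design$reward_lo[idx_t]) -
    pars[cbind(idx_p, 2, idx_s)] *
    (design$effort_hi[idx_t] - design$effort_lo[idx_t])
  data.frame(subject_id = idx_p, arm = arm[idx_p], session = idx_s,
             block = design$block[idx_t], trial = design$trial[idx_t],
             reward_hi = design$reward_hi[idx_t],
             reward_lo = design$reward_lo[idx_t],
             effort_hi = design$effort_hi[idx_t],
             effort_lo = design$effort_lo[idx_t],
             is_catch = design$is_catch[idx_t],
             choice_hi = rbinom(length(logit), 1L, plogis(logit)),
             rt_s = rlnorm(length(logit), log(3), 0.4))
}

# simulate attribution responses for a given latent array (P x 2 x 4)
sim_attributions_from_theta <- function(design, theta, arm) {
  P <- dim(theta)[1]
  n_trials <- nrow(design)
  idx_p <- rep(seq_len(P), each = 2 * n_trials)
  idx_s <- rep(rep(1:2, each = n_trials), times = P)
  idx_t <- rep(seq_len(n_trials), times = 2 * P)
  v_i <- match(design$valence[idx_t], c("neg", "pos"))
  th_int <- theta[cbind(idx_p, v_i, (idx_s - 1) * 2 + 1)]
  th_glob <- theta[cbind(idx_p, v_i, (idx_s - 1) * 2 + 2)]
  data.frame(subject_id = idx_p, arm = arm[idx_p], session = idx_s,
             trial = design$trial[idx_t], valence = design$valence[idx_t],
             choice_internal = rbinom(length(th_int), 1L, plogis(th_int)),
             choice_global = rbinom(length(th_glob), 1L, plogis(th_glob)),
             option_position = sample(0:3, length(th_int), replace = TRUE),
             rt_s = rlnorm(length(th_int), log(3), 0.4))
}
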