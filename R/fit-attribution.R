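#' Prior settings for the attribution model
#'
#' Group means for the latent attribution tendencies are normal(0, 2) (on the
#' logit scale this spans near-0 to near-1 endorsement probabilities);
#' subject SDs half-normal(1); the 4 x 4 correlation across
#' dimension-by-session cells is LKJ(1) (uniform over correlation matrices,
#' which reduces to uniform \[-1, 1\] marginals in the bivariate case); the
#' intervention effect and moderation weights are standard normal.
#'
#' @param mu_scale prior SD of the group means.
#' @param sd_scale half-normal scale of the subject SDs.
#' @param phi_scale prior SD of the intervention effects.
#' @param beta_scale prior SD of moderation weights in joint models.
#' @return list of class `"att_priors"`.
#' @export
att_priors <- function(mu_scale = 2, sd_scale = 1, phi_scale = 1,
                       beta_scale = 1) {
  structure(list(mu_scale = mu_scale, sd_scale = sd_scale,
                 phi_scale = phi_scale, beta_scale = beta_scale),
            class = "att_priors")
}

# aggregate an attribution dataset to per-cell counts: cells are
# (dimension x session) within valence, order int_s1, glob_s1, int_s2, glob_s2
att_prepare <- function(data) {
  need <- c("subject_id", "session", "valence", "choice_internal", "choice_global")
  if (!all(need %in% names(data)))
    stop("attribution data is missing columns: ",
         paste(setdiff(need, names(data)), collapse = ", "), call. = FALSE)
  ids <- sort(unique(data$subject_id))
  P <- length(ids)
  arm <- if ("arm" %in% names(data))
    vapply(ids, function(i) as.character(data$arm[data$subject_id == i][1]),
           character(1))
  else rep("control", P)
  n_cell <- k_cell <- array(0L, c(P, 2, 4))  # p, v (neg, pos), cell
  p_i <- match(data$subject_id, ids)
  v_i <- match(data$valence, c("neg", "pos"))
  s_i <- as.integer(data$session)
  for (d in 1:2) {
    y <- if (d == 1) data$choice_internal else data$choice_global
    c_i <- (s_i - 1) * 2 + d
    tab_n <- tapply(rep(1L, nrow(data)), list(p_i, v_i, c_i), sum, default = 0L)
    tab_k <- tapply(as.integer(y), list(p_i, v_i, c_i), sum, default = 0L)
    for (vv in 1:2) for (ss in 1:2) {
      cc <- (ss - 1) * 2 + d
      n_cell[, vv, cc] <- tab_n[, vv, as.character(cc)]
      k_cell[, vv, cc] <- tab_k[, vv, as.character(cc)]
    }
  }
  # flatten in the sampler's order: ((p * 2 + v) * 4 + c)
  flat_n <- integer(P * 8); flat_k <- integer(P * 8)
  for (p in 1:P) for (v in 1:2) for (cc in 1:4) {
    i <- ((p - 1) * 2 + (v - 1)) * 4 + cc
    flat_n[i] <- n_cell[p, v, cc]
    flat_k[i] <- k_cell[p, v, cc]
  }
  list(ids = ids, arm = arm, active = as.integer(arm == "active"),
       n_cell = flat_n, k_cell = flat_k)
}

att_cell_labels <- c("int1", "glob1", "int2", "glob2")

att_param_names <- function(P, intervention, traits = character(0),
                            item_ids = NULL, item_K = NULL) {
  nm <- character(0)
  for (v in c("neg", "pos")) {
    nm <- c(nm,
            sprintf("mu_int_%s[1]", v), sprintf("mu_glob_%s[1]", v),
            sprintf("mu_int_%s[2]", v), sprintf("mu_glob_%s[2]", v),
            sprintf("sigma_int_%s[1]", v), sprintf("sigma_glob_%s[1]", v),
            sprintf("sigma_int_%s[2]", v), sprintf("sigma_glob_%s[2]", v))
    for (i in 1:3) for (j in (i + 1):4)
      nm <- c(nm, sprintf("R_%s[%s,%s]", v, att_cell_labels[i], att_cell_labels[j]))
    if (intervention) nm <- c(nm, sprintf("phi_int_%s", v), sprintf("phi_glob_%s", v))
  }
  for (tr in traits) nm <- c(nm, sprintf("beta_base_%s", tr), sprintf("beta_int_%s", tr))
  if (!is.null(item_ids))
    for (j in seq_along(item_ids))
      nm <- c(nm, sprintf("disc[%s]", item_ids[j]),
              sprintf("kappa[%s,%d]", item_ids[j], seq_len(item_K[j] - 1)))
  if (!is.null(item_ids))
    for (tr in traits) nm <- c(nm, sprintf("theta_%s[%d]", tr, seq_len(P)))
  subj <- character(0)
  for (p in seq_len(P))
    for (v in c("neg", "pos"))
      subj <- c(subj, sprintf("theta_int_%s[%d,1]", v, p),
                sprintf("theta_glob_%s[%d,1]", v, p),
                sprintf("theta_int_%s[%d,2]", v, p),
                sprintf("theta_glob_%s[%d,2]", v, p))
  c(nm, subj)
}

#' Fit the hierarchical causal attribution model
#'
#' Each trial contributes two Bernoulli-logit observations: the choice of an
#' internal (versus external) and of a global (versus specific) explanation.
#' Per valence (negative/positive events), the four latent tendencies per
#' subject (internal/global x session 1/2) are drawn from a 4-dimensional
#' multivariate normal with freely estimated covariance, and allocation to
#' the active arm adds a group-level effect per dimension at session 2.
#'
#' @param data attribution dataset (schema of
#'   [simulate_attribution_cohort()]); expected to have passed
#'   [apply_exclusion_rules()].
#' @param mcmc an [mcmc_control()].
#' @param priors an [att_priors()].
#' @param intervention estimate group-level active-arm effects at session 2?
#' @return An object of class `c("attribution_fit", "hb_fit")`.
#' @export
fit_attribution <- function(data, mcmc = mcmc_control(), priors = att_priors(),
                            intervention = TRUE) {
  prep <- att_prepare(data)
  if (intervention && (sum(prep$active) < 2 || sum(!prep$active) < 2))
    stop("need at least 2 subjects per arm to estimate an intervention effect",
         call. = FALSE)
  if (!is.null(mcmc$seed)) set.seed(mcmc$seed)
  P <- length(prep$ids)
  n_keep <- (mcmc$iter - mcmc$warmup) %/% mcmc$thin
  chains <- lapply(seq_len(mcmc$chains), function(ch)
    sample_att_cpp(prep$n_cell, prep$k_cell, prep$active, intervention,
                   list(), -1L, -1L, 0L,
                   c(priors$mu_scale, priors$sd_scale, priors$phi_scale,
                     priors$beta_scale),
                   mcmc$warmup, n_keep, mcmc$thin))
  nm <- att_param_names(P, intervention)
  n_group <- 2 * (14 + if (intervention) 2 else 0)
  fit <- new_hb_fit(chains, nm, "attribution",
                    list(subject_ids = prep$ids, arm = prep$arm,
                         intervention = intervention),
                    mcmc, nm[seq_len(n_group)])
  if (!is.na(fit$converged) && !fit$converged)
    warning("attribution fit: R-hat > 1.05 on at least one group-level parameter",
            call. = FALSE)
  fit
}
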