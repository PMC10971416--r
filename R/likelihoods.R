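#' Subjective value of a reward-effort option
#'
#' `V = rewSens * reward - effSens * effort`: a linear trade-off between the
#' offered reward (coins) and the required effort (fraction of calibrated
#' maximum).
#'
#' @param rew_sens,eff_sens sensitivity weights (sign-free).
#' @param reward offered reward, coins.
#' @param effort required effort, fraction of maximum.
#' @return numeric value(s).
#' @export
option_value <- function(rew_sens, eff_sens, reward, effort) {
  stopifnot(is.finite(rew_sens), is.finite(eff_sens),
            is.finite(reward), is.finite(effort))
  rew_sens * reward - eff_sens * effort
}

#' Probability of choosing the higher-value option
#'
#' Bernoulli-logit choice rule: `plogis(V_hi - V_lo)`, computed stably for
#' large value differences.
#'
#' @param v_hi,v_lo option values.
#' @return probability in (0, 1).
#' @export
choice_probability <- function(v_hi, v_lo) {
  stopifnot(is.finite(v_hi), is.finite(v_lo))
  plogis(v_hi - v_lo)
}

#' Log likelihood of a choice dataset under given subject parameters
#'
#' Sums Bernoulli log probabilities over trials, with the logit equal to the
#' difference in option values. Catch trials can be excluded (the default, as
#' in the fitted model, where they serve attention checking only).
#'
#' @param params data frame with columns `subject_id`, `session`, `rewSens`,
#'   `effSens` covering every subject x session in `data`.
#' @param data a choice dataset (schema of [simulate_reward_effort_cohort()]).
#' @param include_catch include catch trials in the sum?
#' @return scalar log likelihood (<= 0).
#' @export
dataset_loglik <- function(params, data, include_catch = FALSE) {
  if (!include_catch && "is_catch" %in% names(data))
    data <- data[data$is_catch == 0, , drop = FALSE]
  key <- paste(data$subject_id, data$session)
  pkey <- paste(params$subject_id, params$session)
  m <- match(key, pkey)
  if (anyNA(m))
    stop("params do not cover all subject/session pairs in data", call. = FALSE)
  logit <- params$rewSens[m] * (data$reward_hi - data$reward_lo) -
    params$effSens[m] * (data$effort_hi - data$effort_lo)
  bern_logit_ll_cpp(logit, as.integer(data$choice_hi))
}

#' Probability of endorsing an attribution
#'
#' The latent tendencies are unbounded; a logistic link maps them to
#' endorsement probabilities.
#'
#' @param theta latent tendency (real).
#' @return probability in (0, 1).
#' @export
attribution_probability <- function(theta) {
  stopifnot(is.finite(theta))
  plogis(theta)
}

#' Log likelihood of an attribution dataset under given latent traits
#'
#' Each trial contributes two independent Bernoulli terms: one for the
#' internal/external code and one for the global/specific code.
#'
#' @param traits data frame with columns `subject_id`, `session`, `valence`,
#'   `theta_internal`, `theta_global` covering every cell in `data`.
#' @param data an attribution dataset.
#' @return scalar log likelihood.
#' @export
attribution_loglik <- function(traits, data) {
  key <- paste(data$subject_id, data$session, data$valence)
  tkey <- paste(traits$subject_id, traits$session, traits$valence)
  m <- match(key, tkey)
  if (anyNA(m))
    stop("traits do not cover all subject/session/valence cells in data",
         call. = FALSE)
  bern_logit_ll_cpp(traits$theta_internal[m], as.integer(data$choice_internal)) +
    bern_logit_ll_cpp(traits$theta_global[m], as.integer(data$choice_global))
}

#' Category probabilities of a graded response model item
#'
#' For an item with discrimination `a` and ordered thresholds `kappa`,
#' the probability of responding in category `k` (0-based) is the difference
#' of logistic CDFs: `P(y >= k) = plogis(a * theta - kappa_k)`.
#'
#' @param theta latent trait value.
#' @param a item discrimination (> 0 in fitted banks; 0 is allowed here and
#'   makes the item uninformative).
#' @param kappa strictly increasing thresholds (length K - 1).
#' @return numeric vector of K probabilities summing to 1.
#' @export
grm_category_probabilities <- function(theta, a, kappa) {
  if (any(diff(kappa) <= 0))
    stop("thresholds must be strictly increasing", call. = FALSE)
  cum <- c(1, plogis(a * theta - kappa), 0)
  pmax(cum[-length(cum)] - cum[-1], 0)
}
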