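#' Simulate a two-session reward-effort cohort
#'
#' Draws subject-level reward and effort sensitivities from bivariate normal
#' distributions across sessions (means, SDs and cross-session correlation
#' from the cohort config), adds the configured intervention effect to
#' active-arm subjects at session 2, and generates choices with a
#' Bernoulli-logit rule on the difference in option values
#' `V = rewSens * reward - effSens * effort`. Response times are lognormal
#' and carry no information about choice; they exist so the exclusion rules
#' can be exercised.
#'
#' If the config carries a `joint` block targeting a choice parameter, a
#' standard-normal trait is drawn per subject and shifts the target parameter
#' by `beta_base` at session 1 and, for the active arm, by `beta_int` at
#' session 2; the traits are returned in the `"traits"` attribute for use by
#' [simulate_item_responses()].
#'
#' @param design trial array from [generate_task_design()].
#' @param cohort a [cohort_config()].
#' @return A data frame (one row per subject x session x trial) with columns
#'   `subject_id`, `arm`, `session`, `block`, `trial`, `reward_hi`,
#'   `reward_lo`, `effort_hi`, `effort_lo`, `is_catch`, `choice_hi`, `rt_s`.
#'   Attributes: `"true_params"` (subject x session sensitivities) and
#'   optionally `"traits"`.
#' @export
simulate_reward_effort_cohort <- function(design, cohort) {
  stopifnot(inherits(cohort, "cohort_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cohort$seed)

  P <- cohort$n_subjects
  arm <- assign_arms(P, cohort$allocation)
  re <- cohort$reward_effort

  pars <- array(NA_real_, c(P, 2, 2),
                dimnames = list(NULL, c("rewSens", "effSens"), NULL))
  for (k in 1:2) {
    Sig <- diag(rep(re$sd[k], 2)) %*% matrix(c(1, re$R[k], re$R[k], 1), 2) %*%
      diag(rep(re$sd[k], 2))
    pars[, k, ] <- mvn_draw(P, re$mu[k, ], Sig)
  }

  trait <- NULL
  jt <- cohort$joint
  if (!is.null(jt) && jt$target %in% c("rewSens", "effSens")) {
    trait <- rnorm(P)
    k <- match(jt$target, c("rewSens", "effSens"))
    pars[, k, 1] <- pars[, k, 1] + jt$beta_base * trait
    pars[, k, 2] <- pars[, k, 2] + ifelse(arm == "active", jt$beta_int, 0) * trait
  }
  # intervention effect: session 2, active arm only
  for (k in 1:2)
    pars[arm == "active", k, 2] <- pars[arm == "active", k, 2] + re$phi_int[k]

  n_trials <- nrow(design)
  idx_p <- rep(seq_len(P), each = 2 * n_trials)
  idx_s <- rep(rep(1:2, each = n_trials), times = P)
  idx_t <- rep(seq_len(n_trials), times = 2 * P)

  rs <- pars[cbind(idx_p, 1, idx_s)]
  es <- pars[cbind(idx_p, 2, idx_s)]
  logit <- rs * (design$reward_hi[idx_t] - design$reward_lo[idx_t]) -
    es * (design$effort_hi[idx_t] - design$effort_lo[idx_t])
  choice <- rbinom(length(logit), 1L, plogis(logit))

  out <- data.frame(
    subject_id = idx_p,
    arm = arm[idx_p],
    session = idx_s,
    block = design$block[idx_t],
    trial = design$trial[idx_t],
    reward_hi = design$reward_hi[idx_t],
    reward_lo = design$reward_lo[idx_t],
    effort_hi = design$effort_hi[idx_t],
    effort_lo = design$effort_lo[idx_t],
    is_catch = design$is_catch[idx_t],
    choice_hi = choice,
    rt_s = rlnorm(length(logit), cohort$rt_meanlog, cohort$rt_sdlog)
  )
  attr(out, "true_params") <- pars
  if (!is.null(trait)) attr(out, "traits") <- trait
  attr(out, "arm") <- arm
  out
}

#' Simulate a two-session causal attribution cohort
#'
#' Per subject and valence, the four latent attribution tendencies
#' (internal/global x session 1/2) are drawn from a multivariate normal with
#' the configured means, SDs and correlation structure; active-arm subjects'
#' session-2 tendencies are shifted by the configured intervention effect.
#' Each scenario then yields two independent Bernoulli codes with
#' `P(internal) = plogis(theta_internal)` and
#' `P(global) = plogis(theta_global)`. Option positions are uniform over the
#' four screen positions and response times lognormal, so the attention
#' exclusion rules can be exercised.
#'
#' @param design scenario schedule from [generate_attribution_design()].
#' @param cohort a [cohort_config()].
#' @return A data frame with columns `subject_id`, `arm`, `session`, `trial`,
#'   `valence`, `choice_internal`, `choice_global`, `option_position`,
#'   `rt_s`, plus a `"true_theta"` attribute (subject x valence x cell array,
#'   cells internal-s1, global-s1, internal-s2, global-s2) and optionally
#'   `"traits"`.
#' @export
simulate_attribution_cohort <- function(design, cohort) {
  stopifnot(inherits(cohort, "cohort_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cohort$seed)

  P <- cohort$n_subjects
  arm <- assign_arms(P, cohort$allocation)
  att <- cohort$attribution
  Sig <- diag(att$sd) %*% att$corr %*% diag(att$sd)

  theta <- array(NA_real_, c(P, 2, 4),
                 dimnames = list(NULL, c("neg", "pos"),
                                 c("int_s1", "glob_s1", "int_s2", "glob_s2")))
  for (v in 1:2) theta[, v, ] <- mvn_draw(P, att$mu[, v], Sig)

  trait <- NULL
  jt <- cohort$joint
  if (!is.null(jt) && is.list(jt$target)) {
    trait <- rnorm(P)
    v <- match(jt$target$valence, c("neg", "pos"))
    d <- match(jt$target$dimension, c("internal", "global"))
    theta[, v, d] <- theta[, v, d] + jt$beta_base * trait
    theta[, v, d + 2] <- theta[, v, d + 2] +
      ifelse(arm == "active", jt$beta_int, 0) * trait
  }
  for (v in 1:2)
    for (d in 1:2)
      theta[arm == "active", v, d + 2] <-
        theta[arm == "active", v, d + 2] + att$phi_int[d, v]

  n_trials <- nrow(design)
  idx_p <- rep(seq_len(P), each = 2 * n_trials)
  idx_s <- rep(rep(1:2, each = n_trials), times = P)
  idx_t <- rep(seq_len(n_trials), times = 2 * P)
  v_i <- match(design$valence[idx_t], c("neg", "pos"))

  th_int <- theta[cbind(idx_p, v_i, (idx_s - 1) * 2 + 1)]
  th_glob <- theta[cbind(idx_p, v_i, (idx_s - 1) * 2 + 2)]

  out <- data.frame(
    subject_id = idx_p,
    arm = arm[idx_p],
    session = idx_s,
    trial = design$trial[idx_t],
    valence = design$valence[idx_t],
    choice_internal = rbinom(length(th_int), 1L, plogis(th_int)),
    choice_global = rbinom(length(th_glob), 1L, plogis(th_glob)),
    option_position = sample(0:3, length(th_int), replace = TRUE),
    rt_s = rlnorm(length(th_int), cohort$rt_meanlog, cohort$rt_sdlog)
  )
  attr(out, "true_theta") <- theta
  if (!is.null(trait)) attr(out, "traits") <- trait
  attr(out, "arm") <- arm
  out
}

#' Simulate ordinal item responses from a graded response model
#'
#' Categories `0..K-1` are drawn with probabilities given by differences of
#' logistic CDFs at `a * theta - kappa_k` (see
#' [grm_category_probabilities()]).
#'
#' @param traits a data frame with `subject_id` and one column per trait
#'   (`theta_A`, `theta_N`), or a named numeric vector for a single trait.
#' @param bank an item bank as from [default_item_bank()].
#' @param seed integer seed.
#' @return Data frame with `subject_id`, `instrument`, `item_id`, `trait`,
#'   `response`.
#' @export
simulate_item_responses <- function(traits, bank, seed = 1L) {
  validate_item_bank(bank)
  if (is.numeric(traits))
    traits <- data.frame(subject_id = seq_along(traits), theta_A = traits)
  tr_cols <- c(A = "theta_A", N = "theta_N")
  need <- unique(bank$trait)
  miss <- need[!tr_cols[need] %in% names(traits)]
  if (length(miss))
    stop("traits table lacks columns for trait(s): ",
         paste(miss, collapse = ", "), call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  rows <- vector("list", nrow(bank))
  for (i in seq_len(nrow(bank))) {
    K <- bank$n_categories[i]
    kap <- as.numeric(bank[i, paste0("kappa_", seq_len(K - 1))])
    th <- traits[[tr_cols[bank$trait[i]]]]
    pr <- t(vapply(th, function(x)
      grm_category_probabilities(x, bank$discrimination[i], kap), numeric(K)))
    resp <- vapply(seq_len(nrow(pr)), function(r)
      sample.int(K, 1L, prob = pr[r, ]) - 1L, integer(1))
    rows[[i]] <- data.frame(subject_id = traits$subject_id,
                            instrument = bank$instrument[i],
                            item_id = bank$item_id[i],
                            trait = bank$trait[i],
                            response = resp)
  }
  out <- do.call(rbind, rows)
  out[order(out$subject_id, out$item_id), , drop = FALSE]
}

#' Apply the preregistered exclusion rules
#'
#' Reward-effort data: a subject is retained if they chose the dominant
#' option on at least one catch trial (per session data are pooled).
#' Attribution data: a subject is excluded if their median response time is
#' not strictly greater than 2 s, or if any single option position was chosen
#' on 75% or more of trials (the published rule requires strictly less
#' than 75%).
#'
#' @param data a choice or attribution dataset.
#' @param kind `"reward_effort"` or `"attribution"`.
#' @return A list with `data` (retained rows), `excluded` (subject ids) and
#'   `report` (data frame of subject_id, reason).
#' @export
apply_exclusion_rules <- function(data, kind = c("reward_effort", "attribution")) {
  kind <- match.arg(kind)
  if (kind == "reward_effort") {
    need <- c("subject_id", "is_catch", "choice_hi")
    if (!all(need %in% names(data)))
      stop("missing columns: ", paste(setdiff(need, names(data)), collapse = ", "),
           call. = FALSE)
    catch <- data[data$is_catch == 1, ]
    ok <- tapply(catch$choice_hi, catch$subject_id, function(x) any(x == 1))
    bad <- as.numeric(names(ok))[!ok]
    report <- if (length(bad))
      data.frame(subject_id = bad, reason = "catch") else
      data.frame(subject_id = numeric(0), reason = character(0))
  } else {
    need <- c("subject_id", "rt_s", "option_position")
    if (!all(need %in% names(data)))
      stop("missing columns: ", paste(setdiff(need, names(data)), collapse = ", "),
           call. = FALSE)
    ids <- unique(data$subject_id)
    reasons <- lapply(ids, function(id) {
      d <- data[data$subject_id == id, ]
      r <- character(0)
      if (!(median(d$rt_s) > 2)) r <- c(r, "rt")
      prop <- table(factor(d$option_position, levels = 0:3)) / nrow(d)
      if (any(prop >= 0.75)) r <- c(r, "position")
      r
    })
    keep <- lengths(reasons) == 0
    bad <- ids[!keep]
    report <- if (length(bad))
      data.frame(subject_id = rep(bad, lengths(reasons[!keep])),
                 reason = unlist(reasons[!keep])) else
      data.frame(subject_id = numeric(0), reason = character(0))
  }
  list(data = data[!data$subject_id %in% report$subject_id, , drop = FALSE],
       excluded = unique(report$subject_id),
       report = report)
}

# deterministic interleaved allocation: arms stay balanced to the target
# ratio under any truncation of the subject sequence
assign_arms <- function(P, allocation = c(1, 1)) {
  w <- allocation[1] / sum(allocation)
  i <- seq_len(P)
  ifelse(floor(i * w) > floor((i - 1) * w), "active", "control")
}

# MVN draws via Cholesky (base R only)
mvn_draw <- function(n, mu, Sigma) {
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("covariance is not positive semidefinite", call. = FALSE)
  L <- chol(Sigma + diag(1e-10, nrow(Sigma)))
  matrix(rnorm(n * length(mu)), n) %*% L + matrix(mu, n, length(mu), byrow = TRUE)
}
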