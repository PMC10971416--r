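#' Summarise group-level intervention effects
#'
#' For each intervention-effect parameter: posterior mean, central credible
#' interval, whether the interval excludes zero (the package's evidence
#' rule), and a standardised version of the effect obtained by dividing the
#' posterior mean by the square root of the mean posterior variance of the
#' session-2 subject-level parameter values, which makes it roughly
#' comparable to a standardised mean difference (SMD).
#'
#' @param fit a `reward_effort_fit` or `attribution_fit` (or joint variant)
#'   fitted with an intervention term.
#' @param level credible level, default 0.90.
#' @return data frame with one row per parameter: `parameter`, `mean`,
#'   `lower`, `upper`, `excludes_zero`, `smd`.
#' @export
intervention_effect_summary <- function(fit, level = 0.90) {
  stopifnot(inherits(fit, "hb_fit"))
  if (!isTRUE(fit$data_info$intervention))
    stop("fit has no intervention-effect draws", call. = FALSE)
  a <- (1 - level) / 2
  P <- length(fit$data_info$subject_ids)
  if (inherits(fit, "reward_effort_fit") || fit$model == "reward_effort_joint") {
    specs <- list(
      list(phi = "phi_rewSens", subj = sprintf("rewSens[%d,2]", seq_len(P))),
      list(phi = "phi_effSens", subj = sprintf("effSens[%d,2]", seq_len(P))))
  } else {
    specs <- list()
    for (v in c("neg", "pos"))
      for (d in c("int", "glob"))
        specs[[length(specs) + 1]] <- list(
          phi = sprintf("phi_%s_%s", d, v),
          subj = sprintf("theta_%s_%s[%d,2]", d, v, seq_len(P)))
  }
  rows <- lapply(specs, function(sp) {
    d <- posterior_draws(fit, sp$phi)
    q <- quantile(d, c(a, 1 - a), names = FALSE)
    # mean posterior variance of session-2 subject parameters
    v2 <- mean(apply(fit$draws[, sp$subj, drop = FALSE], 2, var))
    data.frame(parameter = sp$phi, mean = mean(d), lower = q[1], upper = q[2],
               excludes_zero = q[1] > 0 || q[2] < 0,
               smd = mean(d) / sqrt(v2))
  })
  do.call(rbind, rows)
}

#' Per-subject attribution endorsement probabilities
#'
#' Transforms the latent-trait draws of an attribution fit through the
#' logistic link and summarises the resulting endorsement probabilities.
#'
#' @param fit an `attribution_fit`.
#' @return data frame: `subject_id`, `session`, `valence`, `dimension`,
#'   `probability` (posterior mean of `plogis(theta)`), `sd`.
#' @export
endorsement_summary <- function(fit) {
  stopifnot(inherits(fit, "attribution_fit") || fit$model == "attribution_joint")
  ids <- fit$data_info$subject_ids
  grid <- expand.grid(dimension = c("internal", "global"), session = 1:2,
                      valence = c("neg", "pos"), subject_id = ids,
                      stringsAsFactors = FALSE)
  d_short <- c(internal = "int", global = "glob")
  nm <- sprintf("theta_%s_%s[%d,%d]", d_short[grid$dimension], grid$valence,
                match(grid$subject_id, ids), grid$session)
  pr <- plogis(fit$draws[, nm, drop = FALSE])
  grid$probability <- colMeans(pr)
  grid$sd <- apply(pr, 2, sd)
  grid[, c("subject_id", "session", "valence", "dimension", "probability", "sd")]
}

#' Standardise a coefficient by a predictor/outcome SD ratio
#'
#' Multiplies coefficient draws by `predictor_sd / outcome_sd`, the scaling
#' used to display moderation weights as approximately standardised
#' regression coefficients.
#'
#' @param draws numeric vector of coefficient draws, or an `hb_fit` plus
#'   `parameter`.
#' @param predictor_sd,outcome_sd positive scalars.
#' @param parameter parameter name when `draws` is a fit.
#' @param level credible level for the summary interval.
#' @return list with `draws` (scaled), `mean`, `lower`, `upper`.
#' @export
standardized_beta <- function(draws, predictor_sd, outcome_sd,
                              parameter = NULL, level = 0.90) {
  if (inherits(draws, "hb_fit")) {
    if (is.null(parameter)) stop("supply a parameter name", call. = FALSE)
    draws <- posterior_draws(draws, parameter)
  }
  if (predictor_sd <= 0 || outcome_sd <= 0)
    stop("SDs must be positive", call. = FALSE)
  sc <- draws * predictor_sd / outcome_sd
  a <- (1 - level) / 2
  q <- quantile(sc, c(a, 1 - a), names = FALSE)
  list(draws = sc, mean = mean(sc), lower = q[1], upper = q[2])
}
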