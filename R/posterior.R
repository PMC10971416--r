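#' MCMC sampler settings
#'
#' The `"paper"` profile reproduces the published sampler configuration
#' (four chains of 2000 iterations, 1000 discarded as warm-up). The
#' `"test"` profile (two chains of 500 iterations, 250 warm-up) is meant for
#' continuous-integration runs and quick checks.
#'
#' @param chains number of chains (sampled sequentially).
#' @param iter iterations per chain, including warm-up.
#' @param warmup warm-up (adaptation) iterations discarded per chain.
#' @param thin keep every `thin`-th post-warmup draw.
#' @param seed optional integer; when given, the fit seeds R's RNG so results
#'   are reproducible without an external `set.seed()`.
#' @param profile optional shortcut overriding `chains`/`iter`/`warmup`.
#' @return list of class `"mcmc_control"`.
#' @export
mcmc_control <- function(chains = 4, iter = 2000, warmup = 1000, thin = 1,
                         seed = NULL, profile = NULL) {
  if (!is.null(profile)) {
    profile <- match.arg(profile, c("paper", "test"))
    if (profile == "paper") { chains <- 4; iter <- 2000; warmup <- 1000 }
    else { chains <- 2; iter <- 500; warmup <- 250 }
  }
  stopifnot(warmup < iter, chains >= 1, thin >= 1)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), thin = as.integer(thin),
                 seed = seed),
            class = "mcmc_control")
}

#' Split potential scale reduction factor (R-hat)
#'
#' Computes the Gelman-Rubin convergence statistic on split chains. The
#' default `"rank"` method rank-normalizes the draws and folds them around
#' the median before computing split-R-hat, which is sensitive to both
#' location and scale disagreement between chains; `"classic"` is the
#' textbook split-R-hat on the raw draws.
#'
#' @param chains a list of equal-length numeric vectors (one per chain) or a
#'   matrix with one column per chain.
#' @param method `"rank"` or `"classic"`.
#' @return scalar R-hat (>= 1 up to numerical noise).
#' @export
rhat <- function(chains, method = c("rank", "classic")) {
  method <- match.arg(method)
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  if (length(chains) < 2) stop("need at least 2 chains", call. = FALSE)
  n <- unique(lengths(chains))
  if (length(n) != 1) stop("chains must have equal length", call. = FALSE)
  if (method == "classic") return(.split_rhat(chains))
  z <- .rank_normalize(chains)
  bulk <- .split_rhat(z)
  folded <- lapply(chains, function(x) abs(x - median(unlist(chains))))
  tail_ <- .split_rhat(.rank_normalize(folded))
  max(bulk, tail_)
}

.rank_normalize <- function(chains) {
  all <- unlist(chains)
  S <- length(all)
  r <- rank(all, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (S + 1 / 4))
  split(z, rep(seq_along(chains), lengths(chains)))
}

.split_rhat <- function(chains) {
  halves <- list()
  for (x in chains) {
    n2 <- floor(length(x) / 2)
    halves[[length(halves) + 1]] <- x[seq_len(n2)]
    halves[[length(halves) + 1]] <- x[(length(x) - n2 + 1):length(x)]
  }
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W < .Machine$double.eps) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# assemble an hb_fit object from per-chain draw matrices
new_hb_fit <- function(chains, param_names, model, data_info, mcmc,
                       group_params) {
  chains <- lapply(chains, function(m) { colnames(m) <- param_names; m })
  all_draws <- do.call(rbind, chains)
  rh <- if (length(chains) >= 2) {
    vapply(seq_along(param_names), function(j)
      rhat(lapply(chains, function(m) m[, j])), numeric(1))
  } else rep(NA_real_, length(param_names))
  summaries <- data.frame(
    parameter = param_names,
    mean = colMeans(all_draws),
    sd = apply(all_draws, 2, sd),
    q05 = apply(all_draws, 2, quantile, 0.05, names = FALSE),
    q50 = apply(all_draws, 2, quantile, 0.50, names = FALSE),
    q95 = apply(all_draws, 2, quantile, 0.95, names = FALSE),
    rhat = rh,
    row.names = NULL
  )
  conv <- if (all(is.na(rh))) NA else all(rh[param_names %in% group_params] <= 1.05,
                                          na.rm = TRUE)
  structure(list(chains = chains, draws = all_draws, summaries = summaries,
                 model = model, data_info = data_info, mcmc = mcmc,
                 group_params = group_params, converged = conv),
            class = c(paste0(model, "_fit"), "hb_fit"))
}

#' @export
print.hb_fit <- function(x, ...) {
  cat("Hierarchical Bayesian fit:", x$model, "\n")
  cat(sprintf("  %d chains x %d kept draws; %d parameters\n",
              length(x$chains), nrow(x$chains[[1]]), ncol(x$draws)))
  if (!is.na(x$converged) && !x$converged)
    cat("  WARNING: R-hat > 1.05 on at least one group-level parameter\n")
  gp <- x$summaries[x$summaries$parameter %in% x$group_params, ]
  print(format(gp, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
summary.hb_fit <- function(object, ...) object$summaries

#' Extract posterior draws for one parameter
#'
#' @param fit an `hb_fit`.
#' @param parameter parameter name as in `summary(fit)$parameter`.
#' @return numeric vector of draws, all chains concatenated.
#' @export
posterior_draws <- function(fit, parameter) {
  if (!parameter %in% colnames(fit$draws))
    stop("no such parameter: ", parameter, call. = FALSE)
  fit$draws[, parameter]
}

# posterior-mean subject parameters of a reward-effort fit, long format
re_subject_means <- function(fit) {
  info <- fit$data_info
  out <- expand.grid(session = 1:2, param = c("rewSens", "effSens"),
                     subject_id = info$subject_ids)
  nm <- sprintf("%s[%d,%d]", out$param,
                match(out$subject_id, info$subject_ids), out$session)
  out$estimate <- fit$summaries$mean[match(nm, fit$summaries$parameter)]
  out$arm <- info$arm[match(out$subject_id, info$subject_ids)]
  out
}
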