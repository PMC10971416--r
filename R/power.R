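#' Power of the repeated-measures group-by-time interaction
#'
#' Noncentral-F power for the between-within interaction in a two-group
#' repeated-measures ANOVA with `m` measurements per subject. Follows the
#' convention of the G*Power "ANOVA: repeated measures, within-between
#' interaction" procedure: effect size `f = d / 2` for a two-group contrast
#' on change, noncentrality `lambda = f^2 * N * m / (1 - rho)`,
#' `df1 = (groups - 1) * (m - 1)`, `df2 = (N - groups) * (m - 1)`.
#'
#' @param d standardised effect size (Cohen's d for the group difference in
#'   change between time points).
#' @param n total sample size across both groups.
#' @param m measurements per subject (>= 2).
#' @param rho correlation across repeated measures (-1 < rho < 1).
#' @param alpha significance level.
#' @return power (probability of rejecting at level `alpha`).
#' @export
rm_interaction_power <- function(d, n, m = 2, rho = 0.5, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1, m >= 2, rho > -1, rho < 1, n > 2)
  f <- d / 2
  lambda <- f^2 * n * m / (1 - rho)
  df1 <- (2 - 1) * (m - 1)
  df2 <- (n - 2) * (m - 1)
  crit <- qf(1 - alpha, df1, df2)
  pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Smallest sample size reaching a target interaction power
#'
#' Scans total N upward (in steps of the group count, keeping arms balanced)
#' until [rm_interaction_power()] reaches the target.
#'
#' @param d standardised effect size (must be nonzero).
#' @param target_power required power in (0, 1).
#' @param m measurements per subject.
#' @param rho repeated-measures correlation.
#' @param alpha significance level.
#' @param n_max scan ceiling (error if exceeded).
#' @return smallest total N (multiple of 2).
#' @export
required_sample_size <- function(d, target_power = 0.95, m = 2, rho = 0.5,
                                 alpha = 0.05, n_max = 1e5) {
  stopifnot(target_power > 0, target_power < 1)
  if (d == 0) stop("effect size of zero cannot reach the target power",
                   call. = FALSE)
  n <- 4
  while (n <= n_max) {
    if (rm_interaction_power(d, n, m, rho, alpha) >= target_power) return(n)
    n <- n + 2
  }
  stop("no sample size up to n_max reaches the target power", call. = FALSE)
}

#' Power table over a grid of designs
#'
#' @param d,n,rho vectors; the table is the full grid.
#' @param m,alpha scalars.
#' @return data frame with columns `d`, `n`, `rho`, `power`.
#' @export
power_table <- function(d, n, rho, m = 2, alpha = 0.05) {
  g <- expand.grid(d = d, n = n, rho = rho)
  g$power <- mapply(rm_interaction_power, d = g$d, n = g$n, rho = g$rho,
                    MoreArgs = list(m = m, alpha = alpha))
  g
}
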