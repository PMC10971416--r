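#' Generate a reward-effort task design
#'
#' Builds the trial array for a two-option reward-effort decision task: a set
#' of offer pairs where the higher-reward option always requires strictly more
#' effort (nondominated offers), plus a small number of catch trials on which
#' the highest reward is offered for the lowest effort (attention checks).
#' The default configuration reproduces the published task: 44 trials in four
#' blocks, two of them catch trials, rewards between 3 and 7 coins and efforts
#' between 0.25 and 0.95 of each participant's calibrated maximum.
#'
#' @param n_blocks number of blocks.
#' @param trials_per_block trials per block.
#' @param n_catch total number of catch trials; placed in distinct blocks at
#'   seeded random positions.
#' @param reward_levels integer reward levels (coins) offers are drawn from.
#' @param effort_levels effort levels (fraction of calibrated maximum).
#' @param seed integer seed; the same seed always yields the same array.
#' @return A data frame of class `"re_task_design"` with one row per trial:
#'   `block`, `trial`, `reward_hi`, `reward_lo`, `effort_hi`, `effort_lo`,
#'   `is_catch`. `reward_hi`/`effort_hi` describe the higher-reward option;
#'   on non-catch trials `effort_hi > effort_lo`.
#' @export
generate_task_design <- function(n_blocks = 4, trials_per_block = 11,
                                 n_catch = 2,
                                 reward_levels = 3:7,
                                 effort_levels = seq(0.25, 0.95, length.out = 8),
                                 seed = 1L) {
  if (length(unique(reward_levels)) < 2 || length(unique(effort_levels)) < 2)
    stop("degenerate design: need at least two reward and two effort levels",
         call. = FALSE)
  n_trials <- n_blocks * trials_per_block
  if (n_catch > n_trials) stop("more catch trials than trials", call. = FALSE)
  if (n_catch > n_blocks)
    stop("catch trials are placed in distinct blocks; n_catch must not exceed n_blocks",
         call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  # Nondominated offers: the higher reward always carries the higher effort.
  # Two probe types keep the two sensitivities jointly identifiable from few
  # trials (offer gaps that always co-vary would confound them): three
  # quarters of trials are effort probes (1-coin reward gap, near-maximal
  # effort contrast) and one quarter are reward probes (3-4 coin gap,
  # adjacent effort levels). This is the design-optimization regime a short
  # tradeoff task needs for reliable individual parameter estimates.
  n_eff <- length(effort_levels)
  lo_band <- effort_levels[1]
  hi_band <- effort_levels[seq(max(n_eff - 1L, 2L), n_eff)]
  r_max <- max(reward_levels)
  r_min <- min(reward_levels)
  pick <- function(x) if (length(x) == 1L) x else sample(x, 1L)
  draw_offer <- function() {
    if (runif(1) < 0.75) {  # effort probe
      r_lo <- pick(reward_levels[reward_levels < r_max])
      c(r_lo + 1L, r_lo, pick(hi_band), pick(lo_band))
    } else {                # reward probe
      gap <- min(sample(3:4, 1L), r_max - r_min)
      r_lo <- pick(reward_levels[reward_levels <= r_max - gap])
      i <- pick(seq_len(n_eff - 1L))
      c(r_lo + gap, r_lo, effort_levels[i + 1L], effort_levels[i])
    }
  }
  offers <- t(replicate(n_trials, draw_offer()))

  catch_blocks <- sample(n_blocks, n_catch)
  catch_pos <- vapply(catch_blocks, function(b) {
    as.integer((b - 1) * trials_per_block + sample(trials_per_block, 1L))
  }, integer(1))
  is_catch <- seq_len(n_trials) %in% catch_pos
  # catch: highest reward at lowest effort (dominant option)
  offers[is_catch, 1] <- max(reward_levels)
  offers[is_catch, 2] <- min(reward_levels)
  offers[is_catch, 3] <- min(effort_levels)
  offers[is_catch, 4] <- max(effort_levels)

  out <- data.frame(
    block = rep(seq_len(n_blocks), each = trials_per_block),
    trial = seq_len(n_trials),
    reward_hi = offers[, 1], reward_lo = offers[, 2],
    effort_hi = offers[, 3], effort_lo = offers[, 4],
    is_catch = as.integer(is_catch)
  )
  class(out) <- c("re_task_design", "data.frame")
  attr(out, "reward_levels") <- reward_levels
  attr(out, "effort_levels") <- effort_levels
  out
}

#' Generate a causal attribution task design
#'
#' The published task presents 32 hypothetical event scenarios (16 positive,
#' 16 negative, randomly interleaved) in two blocks; each scenario offers four
#' explanations covering the internal/external x global/specific grid exactly
#' once.
#'
#' @param n_scenarios total number of scenarios.
#' @param n_positive number of positively valenced scenarios; the rest are
#'   negative.
#' @param n_blocks number of blocks.
#' @param seed integer seed for the interleaving order.
#' @return A data frame of class `"attribution_design"` with columns `block`,
#'   `trial`, `valence` (`"pos"`/`"neg"`).
#' @export
generate_attribution_design <- function(n_scenarios = 32, n_positive = 16,
                                        n_blocks = 2, seed = 1L) {
  if (n_positive > n_scenarios) stop("n_positive exceeds n_scenarios", call. = FALSE)
  if (n_scenarios %% n_blocks != 0)
    stop("n_scenarios must divide evenly into blocks", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  valence <- sample(rep(c("pos", "neg"), c(n_positive, n_scenarios - n_positive)))
  out <- data.frame(
    block = rep(seq_len(n_blocks), each = n_scenarios / n_blocks),
    trial = seq_len(n_scenarios),
    valence = valence
  )
  class(out) <- c("attribution_design", "data.frame")
  out
}

# save/restore the global RNG state so seeded generators do not disturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
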