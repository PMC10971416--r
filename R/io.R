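#' Read a choice dataset CSV
#'
#' Validates the trial-level schema used throughout the package:
#' `subject_id, arm, session, block, trial, reward_hi, reward_lo, effort_hi,
#' effort_lo, is_catch, choice_hi, rt_s`.
#'
#' @param path CSV file path.
#' @return data frame.
#' @export
read_choice_csv <- function(path) {
  d <- read.csv(path)
  need <- c("subject_id", "arm", "session", "reward_hi", "reward_lo",
            "effort_hi", "effort_lo", "is_catch", "choice_hi")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("choice CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(d$choice_hi %in% 0:1)) stop("choice_hi must be 0/1", call. = FALSE)
  d
}

#' Read an attribution dataset CSV
#'
#' Schema: `subject_id, arm, session, trial, valence, choice_internal,
#' choice_global, option_position, rt_s`.
#'
#' @param path CSV file path.
#' @return data frame.
#' @export
read_attribution_csv <- function(path) {
  d <- read.csv(path)
  need <- c("subject_id", "arm", "session", "valence", "choice_internal",
            "choice_global")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("attribution CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(d$valence %in% c("pos", "neg")))
    stop("valence must be 'pos' or 'neg'", call. = FALSE)
  d
}

#' Read an item-response dataset CSV
#'
#' Schema: `subject_id, instrument, item_id, trait, response` with ordinal
#' 0-based responses.
#'
#' @param path CSV file path.
#' @return data frame.
#' @export
read_item_csv <- function(path) {
  d <- read.csv(path)
  need <- c("subject_id", "item_id", "trait", "response")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("item CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  d
}

#' Write the posterior summary of a fit to CSV
#'
#' @param fit an `hb_fit`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_posterior_summary <- function(fit, path) {
  write.csv(fit$summaries, path, row.names = FALSE)
  invisible(path)
}
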