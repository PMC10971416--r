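# build the item-data list consumed by the C++ samplers
grm_prepare <- function(item_data, traits, subject_ids = NULL) {
  need <- c("subject_id", "item_id", "trait", "response")
  if (!all(need %in% names(item_data)))
    stop("item data is missing columns: ",
         paste(setdiff(need, names(item_data)), collapse = ", "), call. = FALSE)
  item_data <- item_data[item_data$trait %in% traits, , drop = FALSE]
  if (!nrow(item_data)) stop("no items for trait(s) ", paste(traits, collapse = ", "),
                             call. = FALSE)
  if (is.null(subject_ids)) subject_ids <- sort(unique(item_data$subject_id))
  item_data <- item_data[item_data$subject_id %in% subject_ids, , drop = FALSE]
  if (!nrow(item_data))
    stop("no overlapping subjects between task and item data", call. = FALSE)
  items <- unique(item_data[, c("item_id", "trait")])
  items <- items[order(items$item_id), , drop = FALSE]
  j <- match(item_data$item_id, items$item_id)
  K <- vapply(seq_len(nrow(items)), function(i) {
    obs <- item_data$response[j == i]
    max(obs) + 1L
  }, integer(1))
  n_cat_obs <- vapply(seq_len(nrow(items)), function(i)
    length(unique(item_data$response[j == i])), integer(1))
  if (any(n_cat_obs < 2))
    stop("degenerate item(s) with a single observed category: ",
         paste(items$item_id[n_cat_obs < 2], collapse = ", "), call. = FALSE)
  list(subj = match(item_data$subject_id, subject_ids) - 1L,
       item = j - 1L,
       y = as.integer(item_data$response),
       K = as.integer(pmax(K, 2L)),
       trait = match(items$trait, traits) - 1L,
       item_ids = items$item_id,
       subject_ids = subject_ids)
}

grm_param_names <- function(item_ids, item_K, subject_ids) {
  nm <- character(0)
  for (j in seq_along(item_ids))
    nm <- c(nm, sprintf("disc[%s]", item_ids[j]),
            sprintf("kappa[%s,%d]", item_ids[j], seq_len(item_K[j] - 1)))
  c(nm, sprintf("theta[%d]", seq_along(subject_ids)))
}

#' Fit a unidimensional graded response model
#'
#' Ordered-logistic IRT model for ordinal item responses: the probability of
#' responding at or above category k is `plogis(a_j * theta_p - kappa_jk)`.
#' Identification fixes the latent trait at standard normal and constrains
#' discriminations positive (sampled on the log scale with a standard-normal
#' prior); thresholds have normal(0, 2) priors under an ordering transform.
#'
#' @param item_data data frame with `subject_id`, `item_id`, `trait`,
#'   `response` (ordinal, 0-based).
#' @param trait which trait label to fit (items of other traits are dropped).
#' @param mcmc an [mcmc_control()].
#' @return An object of class `c("grm_fit", "hb_fit")` with item parameters
#'   (`disc[...]`, `kappa[...]`) and subject traits (`theta[p]`).
#' @export
fit_grm <- function(item_data, trait = "A", mcmc = mcmc_control()) {
  prep <- grm_prepare(item_data, trait)
  if (length(prep$item_ids) < 2)
    stop("need at least 2 items for a trait", call. = FALSE)
  if (!is.null(mcmc$seed)) set.seed(mcmc$seed)
  n_keep <- (mcmc$iter - mcmc$warmup) %/% mcmc$thin
  grm <- list(subj = prep$subj, item = prep$item, y = prep$y, K = prep$K,
              trait = prep$trait)
  chains <- lapply(seq_len(mcmc$chains), function(ch)
    sample_grm_cpp(grm, length(prep$subject_ids), mcmc$warmup, n_keep, mcmc$thin))
  nm <- grm_param_names(prep$item_ids, prep$K, prep$subject_ids)
  group <- nm[!grepl("^theta", nm)]
  fit <- new_hb_fit(chains, nm, "grm",
                    list(subject_ids = prep$subject_ids, trait = trait,
                         item_ids = prep$item_ids),
                    mcmc, group)
  if (!is.na(fit$converged) && !fit$converged)
    warning("GRM fit: R-hat > 1.05 on at least one item parameter", call. = FALSE)
  fit
}

#' Posterior-mean trait estimates from a GRM fit
#'
#' @param fit a `grm_fit`.
#' @return data frame `subject_id`, `estimate`, `sd`.
#' @export
trait_estimates <- function(fit) {
  stopifnot(inherits(fit, "grm_fit"))
  nm <- sprintf("theta[%d]", seq_along(fit$data_info$subject_ids))
  s <- fit$summaries[match(nm, fit$summaries$parameter), ]
  data.frame(subject_id = fit$data_info$subject_ids,
             estimate = s$mean, sd = s$sd)
}
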