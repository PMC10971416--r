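#' Standardised per-subject change scores from a two-session fit
#'
#' Change scores are the differences in posterior-mean subject parameter
#' estimates between sessions, standardised by the SD across subjects of the
#' session-1 (baseline) posterior means. The baseline SD pools both arms by
#' default.
#'
#' @param fit a `reward_effort_fit` or `attribution_fit` with arm labels.
#' @param baseline `"pooled"` (default) standardises by the all-subject
#'   baseline SD; `"per_arm"` standardises each arm by its own baseline SD.
#' @return data frame: `parameter`, `subject_id`, `arm`, `change` (raw) and
#'   `change_std`.
#' @export
change_scores <- function(fit, baseline = c("pooled", "per_arm")) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(fit, "hb_fit"))
  ids <- fit$data_info$subject_ids
  arm <- fit$data_info$arm
  if (inherits(fit, "reward_effort_fit") || fit$model == "reward_effort_joint") {
    params <- c("rewSens", "effSens")
    get_mean <- function(par, s)
      fit$summaries$mean[match(sprintf("%s[%d,%d]", par, seq_along(ids), s),
                               fit$summaries$parameter)]
  } else {
    params <- as.vector(outer(c("int", "glob"), c("neg", "pos"),
                              function(d, v) paste0("theta_", d, "_", v)))
    get_mean <- function(par, s)
      fit$summaries$mean[match(sprintf("%s[%d,%d]", par, seq_along(ids), s),
                               fit$summaries$parameter)]
  }
  rows <- lapply(params, function(par) {
    m1 <- get_mean(par, 1)
    m2 <- get_mean(par, 2)
    ch <- m2 - m1
    if (baseline == "pooled") {
      s0 <- sd(m1)
      std <- ch / s0
    } else {
      std <- ch
      for (a in unique(arm)) std[arm == a] <- ch[arm == a] / sd(m1[arm == a])
    }
    data.frame(parameter = par, subject_id = ids, arm = arm,
               change = ch, change_std = std)
  })
  do.call(rbind, rows)
}

#' SD of individual treatment responses
#'
#' Decomposes change-score variability into a component shared with the
#' control arm (within-person fluctuation plus measurement error) and the SD
#' of individual responses to the active treatment,
#' `SD_IR = sqrt(SD_Act^2 - SD_Con^2)`. Its standard error is
#' `sqrt(2 * (SD_Act^4 / DF_Act + SD_Con^4 / DF_Con))` and the 95% CI is
#' `SD_IR +/- 1.96 * SD_IRse`. On standardised change scores, 0.1 / 0.3 /
#' 0.6 mark small, moderate and large individual response heterogeneity.
#'
#' @param sd_act,sd_con standardised change-score SDs in the active and
#'   control arm.
#' @param df_act,df_con degrees of freedom (subjects per arm minus 1).
#' @param clamp_negative if the control variance exceeds the active variance,
#'   clamp `SD_IR` to 0 and flag it (default); `FALSE` returns the signed
#'   root `-sqrt(SD_Con^2 - SD_Act^2)`.
#' @return list of class `"hte_result"`: `sd_act`, `sd_con`, `sd_ir`,
#'   `sd_ir_se`, `ci95`, `effect_class`, `no_heterogeneity`.
#' @export
sd_individual_response <- function(sd_act, sd_con, df_act, df_con,
                                   clamp_negative = TRUE) {
  if (sd_act < 0 || sd_con < 0) stop("SDs must be nonnegative", call. = FALSE)
  if (df_act < 1 || df_con < 1) stop("DFs must be >= 1", call. = FALSE)
  diff2 <- sd_act^2 - sd_con^2
  no_het <- diff2 < 0
  sd_ir <- if (diff2 >= 0) sqrt(diff2) else if (clamp_negative) 0 else -sqrt(-diff2)
  se <- sqrt(2 * (sd_act^4 / df_act + sd_con^4 / df_con))
  ci <- sd_ir + c(-1.96, 1.96) * se
  cls <- if (sd_ir >= 0.6) "large" else if (sd_ir >= 0.3) "moderate"
    else if (sd_ir >= 0.1) "small" else "none"
  structure(list(sd_act = sd_act, sd_con = sd_con,
                 df_act = df_act, df_con = df_con,
                 sd_ir = sd_ir, sd_ir_se = se, ci95 = ci,
                 effect_class = cls, no_heterogeneity = no_het),
            class = "hte_result")
}

#' @export
print.hte_result <- function(x, ...) {
  cat(sprintf("SD of individual responses: %.3f (SE %.3f), 95%% CI [%.3f, %.3f]\n",
              x$sd_ir, x$sd_ir_se, x$ci95[1], x$ci95[2]))
  cat("  effect class:", x$effect_class,
      if (x$no_heterogeneity) "(active variance below control; clamped)" else "",
      "\n")
  invisible(x)
}

#' Heterogeneity of treatment effects for one fitted parameter
#'
#' Convenience wrapper: computes standardised change scores from a fit and
#' runs [sd_individual_response()] on the per-arm SDs.
#'
#' @param fit a two-arm, two-session `hb_fit`.
#' @param parameter which parameter's change scores to analyse (e.g.
#'   `"effSens"` or `"theta_int_pos"`).
#' @param baseline passed to [change_scores()].
#' @return an `"hte_result"` (with the change scores in attribute
#'   `"change_scores"`).
#' @export
hte_from_fit <- function(fit, parameter, baseline = "pooled") {
  cs <- change_scores(fit, baseline)
  cs <- cs[cs$parameter == parameter, ]
  if (!nrow(cs)) stop("no such parameter in change scores: ", parameter,
                      call. = FALSE)
  act <- cs$change_std[cs$arm == "active"]
  con <- cs$change_std[cs$arm == "control"]
  out <- sd_individual_response(sd(act), sd(con),
                                length(act) - 1, length(con) - 1)
  attr(out, "change_scores") <- cs
  out
}
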