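#' Indirect effect by the product of coefficients
#'
#' The mediated (indirect) effect of an exposure on an outcome through a
#' mediator is the product of the exposure-to-mediator effect `a` and the
#' mediator-to-outcome effect `b`. Its standard error is the first-order
#' delta method under independence of the two steps (non-overlapping
#' samples): \eqn{se = \sqrt{a^2 se_b^2 + b^2 se_a^2}}. P-value and
#' confidence interval from the normal reference.
#'
#' @param a,seA exposure-to-mediator effect and its standard error (> 0).
#' @param b,seB mediator-to-outcome effect and its standard error (> 0).
#' @param level confidence level.
#' @return list `(beta, se, pval, ciLow, ciHigh)`.
#' @export
indirectEffect <- function(a, seA, b, seB, level = 0.95) {
  stopifnot(seA > 0, seB > 0, level > 0, level < 1)
  beta <- a * b
  se <- sqrt(a^2 * seB^2 + b^2 * seA^2)
  z <- stats::qnorm((1 + level) / 2)
  pv <- if (se > 0) .normP(beta / se) else as.numeric(beta == 0)
  list(beta = beta, se = se, pval = pv,
       ciLow = beta - z * se, ciHigh = beta + z * se)
}

#' Mediated proportion
#'
#' Ratio of the indirect to the total effect on the log-effect scale, with
#' a delta-method confidence interval for the ratio of two (treated as
#' independent) normal estimates:
#' \eqn{Var \approx se_I^2/T^2 + I^2 se_T^2 / T^4}. The ratio is flagged
#' unreliable when the total effect is imprecise (|total/se| < 2), since a
#' near-zero denominator makes the proportion unstable.
#'
#' @param indirect,seIndirect indirect effect and its standard error.
#' @param total,seTotal total effect (non-zero) and its standard error.
#' @param level confidence level.
#' @return list `(proportion, se, ciLow, ciHigh, pval, reliable)`.
#' @export
mediatedProportion <- function(indirect, seIndirect, total, seTotal,
                               level = 0.95) {
  if (total == 0) stop("domain error: total effect must be non-zero")
  stopifnot(seIndirect >= 0, seTotal >= 0, level > 0, level < 1)
  prop <- indirect / total
  v <- seIndirect^2 / total^2 + indirect^2 * seTotal^2 / total^4
  se <- sqrt(v)
  z <- stats::qnorm((1 + level) / 2)
  pv <- if (se > 0) .normP(prop / se) else as.numeric(prop == 0)
  list(proportion = prop, se = se,
       ciLow = prop - z * se, ciHigh = prop + z * se, pval = pv,
       reliable = abs(total) / seTotal >= 2)
}

# assemble the full mediation result from the three MR fits
.buildMediation <- function(total, step1, step2, level = 0.95,
                            assessed = TRUE, note = "") {
  if (!assessed) {
    return(new("MrMediation", totalBeta = NA_real_, totalSE = NA_real_,
               step1Beta = NA_real_, step1SE = NA_real_,
               step2Beta = NA_real_, step2SE = NA_real_,
               indirectBeta = NA_real_, indirectSE = NA_real_,
               indirectPval = NA_real_, indirectCiLow = NA_real_,
               indirectCiHigh = NA_real_, directBeta = NA_real_,
               proportion = NA_real_, proportionSE = NA_real_,
               proportionCiLow = NA_real_, proportionCiHigh = NA_real_,
               reliable = FALSE, assessed = FALSE, note = note))
  }
  ind <- indirectEffect(step1$beta, step1$se, step2$beta, step2$se, level)
  prop <- mediatedProportion(ind$beta, ind$se, total$beta, total$se, level)
  new("MrMediation",
      totalBeta = total$beta, totalSE = total$se,
      step1Beta = step1$beta, step1SE = step1$se,
      step2Beta = step2$beta, step2SE = step2$se,
      indirectBeta = ind$beta, indirectSE = ind$se, indirectPval = ind$pval,
      indirectCiLow = ind$ciLow, indirectCiHigh = ind$ciHigh,
      directBeta = total$beta - ind$beta,
      proportion = prop$proportion, proportionSE = prop$se,
      proportionCiLow = prop$ciLow, proportionCiHigh = prop$ciHigh,
      reliable = prop$reliable, assessed = TRUE, note = note)
}
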