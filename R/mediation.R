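#' Product-of-coefficients mediated effect
#'
#' The two-step MR mediated effect: the exposure-to-mediator estimate
#' times the mediator-to-outcome estimate.
#'
#' @param beta_x Exposure-to-mediator causal estimate.
#' @param beta_y Mediator-to-outcome causal estimate.
#' @return `beta_x * beta_y`.
#' @export
mediated_effect <- function(beta_x, beta_y) {
  beta_x * beta_y
}

#' Delta-method interval for a product of estimates
#'
#' First-order delta method for the product `beta_x * beta_y`:
#' `var = beta_x^2 se_y^2 + beta_y^2 se_x^2` (the second-order
#' `se_x^2 se_y^2` term is omitted), with a symmetric normal interval
#' around the product.
#'
#' @param beta_x,se_x First-stage estimate and standard error.
#' @param beta_y,se_y Second-stage estimate and standard error.
#' @param level Confidence level, default 0.95 (z = 1.96).
#' @return Named list `se_xy`, `ci_low`, `ci_high`.
#' @export
mediation_ci <- function(beta_x, se_x, beta_y, se_y, level = 0.95) {
  if (se_x < 0 || se_y < 0) stop("standard errors must be non-negative")
  z <- if (level == 0.95) Z95 else qnorm(1 - (1 - level) / 2)
  se_xy <- sqrt(beta_x^2 * se_y^2 + beta_y^2 * se_x^2)
  bxy <- mediated_effect(beta_x, beta_y)
  list(se_xy = se_xy, ci_low = bxy - z * se_xy, ci_high = bxy + z * se_xy)
}

#' Mediated proportion with interval
#'
#' The mediated effect divided by the total effect. The proportion may be
#' negative (the mediator works against the total effect — attenuation,
#' "negative mediation") or exceed 1. The interval divides the product-CI
#' bounds by the total-effect point estimate and reports them in division
#' order (so a negative total effect yields a descending pair), ignoring
#' uncertainty in the total effect.
#'
#' @param beta_xy Mediated effect.
#' @param beta_total Total effect (non-zero).
#' @param ci Optional product CI as `c(low, high)` on the `beta_xy` scale.
#' @return List with `proportion` and (when `ci` is supplied)
#'   `proportion_ci` (length-2, division order preserved).
#' @export
mediated_proportion <- function(beta_xy, beta_total, ci = NULL) {
  if (beta_total == 0) stop("total effect is zero: proportion undefined")
  out <- list(proportion = beta_xy / beta_total)
  if (!is.null(ci)) out$proportion_ci <- ci / beta_total
  out
}

#' Assemble a mediation result from stage estimates
#'
#' Combines precomputed IVW stage estimates (exposure to mediator,
#' mediator to outcome, exposure to outcome) into a full mediation
#' decomposition: mediated effect by product of coefficients, direct
#' effect by subtraction, delta-method CI, and mediated proportion. The
#' decomposition closes exactly: `direct_effect + beta_xy = beta_total`.
#'
#' @param beta_x,se_x Exposure-to-mediator estimate and SE.
#' @param beta_y,se_y Mediator-to-outcome estimate and SE.
#' @param beta_total,se_total Exposure-to-outcome (total) estimate and SE.
#' @param exposure,mediator,outcome Trait labels.
#' @return A `mediation_result` list.
#' @export
mediation_result <- function(beta_x, se_x, beta_y, se_y,
                             beta_total, se_total = NA_real_,
                             exposure = "exposure", mediator = "mediator",
                             outcome = "outcome") {
  bxy <- mediated_effect(beta_x, beta_y)
  ci <- mediation_ci(beta_x, se_x, beta_y, se_y)
  prop <- mediated_proportion(bxy, beta_total,
                              ci = c(ci$ci_low, ci$ci_high))
  structure(list(exposure = exposure, mediator = mediator,
                 outcome = outcome,
                 beta_x = beta_x, se_x = se_x,
                 beta_y = beta_y, se_y = se_y,
                 beta_total = beta_total, se_total = se_total,
                 beta_xy = bxy, beta_xy_se = ci$se_xy,
                 beta_xy_ci = c(ci$ci_low, ci$ci_high),
                 direct_effect = beta_total - bxy,
                 mediated_proportion = prop$proportion,
                 proportion_ci = prop$proportion_ci),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Two-step MR mediation: %s -> %s -> %s\n",
              x$exposure, x$mediator, x$outcome))
  cat(sprintf("  step 1 (exposure->mediator): %.4g (se %.4g)\n",
              x$beta_x, x$se_x))
  cat(sprintf("  step 2 (mediator->outcome):  %.4g (se %.4g)\n",
              x$beta_y, x$se_y))
  cat(sprintf("  total effect:    %.4g\n", x$beta_total))
  cat(sprintf("  mediated effect: %.4g (95%% CI %.4g, %.4g)\n",
              x$beta_xy, x$beta_xy_ci[1], x$beta_xy_ci[2]))
  cat(sprintf("  direct effect:   %.4g\n", x$direct_effect))
  cat(sprintf("  mediated proportion: %.3g%% (%.3g%%, %.3g%%)\n",
              100 * x$mediated_proportion, 100 * x$proportion_ci[1],
              100 * x$proportion_ci[2]))
  cat(" ", mediation_label(x), "\n")
  invisible(x)
}

#' Classify the direction of a mediation effect
#'
#' A mediated effect sharing the sign of the total effect contributes to
#' it (partial mediation, positive proportion); an opposing sign means the
#' mediator attenuates the total effect (negative mediation, negative
#' proportion). With a negative total effect and a negative mediated
#' effect the mediator works along the total effect yet against the
#' protective direction — reported as partial negative mediation.
#'
#' @param x A `mediation_result`.
#' @return One of `"partial mediation (negative direction)"`,
#'   `"partial mediation (positive direction)"`, `"attenuation"`.
#' @export
mediation_label <- function(x) {
  if (sign(x$beta_xy) == sign(x$beta_total)) {
    if (x$beta_total < 0) "partial mediation (negative direction)"
    else "partial mediation (positive direction)"
  } else {
    "attenuation"
  }
}

#' Screening criteria for MR result cascades
#'
#' @param ivw_p_max Maximum IVW p-value to pass (0.05 for the
#'   lipid-to-outcome and lipid-to-mediator screens; 0.01 for the
#'   mediator-to-outcome screen).
#' @param require_direction_concordance Require all available MR methods
#'   to agree in sign, default `TRUE`.
#' @param egger_intercept_p_min Pass requires the Egger intercept p-value
#'   strictly greater than this, default 0.05.
#' @param bonferroni_n Number of tests in the family; IVW p-values below
#'   `0.05 / bonferroni_n` are `significant`, those below `ivw_p_max` but
#'   not the corrected level are `suggestive`.
#' @return A `screen_criteria` list.
#' @export
screen_criteria <- function(ivw_p_max = 0.05,
                            require_direction_concordance = TRUE,
                            egger_intercept_p_min = 0.05,
                            bonferroni_n = 1) {
  stopifnot(ivw_p_max > 0, ivw_p_max < 1,
            egger_intercept_p_min > 0, egger_intercept_p_min < 1,
            bonferroni_n >= 1)
  structure(list(ivw_p_max = ivw_p_max,
                 require_direction_concordance =
                   require_direction_concordance,
                 egger_intercept_p_min = egger_intercept_p_min,
                 bonferroni_n = bonferroni_n),
            class = "screen_criteria")
}

#' Screen one exposure-outcome pair
#'
#' Applies the three retention criteria to a five-method bundle: IVW
#' p-value below the stage threshold, concordant effect directions across
#' all available methods, and no directional pleiotropy (Egger intercept
#' p strictly above the floor). Pairs passing all three are `significant`
#' when the IVW p-value clears the Bonferroni-corrected level
#' `0.05 / bonferroni_n` and `suggestive` otherwise.
#'
#' @param bundle An `mr_method_bundle` (must contain IVW).
#' @param egger_p MR-Egger intercept p-value (taken from the bundle's
#'   Egger fit when omitted).
#' @param criteria A [screen_criteria()].
#' @param pair_id Label for the pair.
#' @return A `screen_outcome`: list with `pair_id`, `p_pass`,
#'   `direction_pass`, `pleiotropy_pass`, `verdict`
#'   (`fail`/`suggestive`/`significant`) and `ivw_p`.
#' @export
screen_pair <- function(bundle, egger_p = NULL,
                        criteria = screen_criteria(), pair_id = "pair") {
  stopifnot(!is.null(bundle$ivw))
  ivw_p <- bundle$ivw$pval
  p_pass <- ivw_p < criteria$ivw_p_max
  betas <- vapply(Filter(Negate(is.null), unclass(bundle)),
                  function(e) e$beta, numeric(1))
  direction_pass <- if (criteria$require_direction_concordance) {
    all(sign(betas) == sign(betas[1]))
  } else {
    TRUE
  }
  if (is.null(egger_p)) {
    egger_p <- if (!is.null(bundle$egger)) bundle$egger$intercept_pval
               else NA_real_
  }
  pleiotropy_pass <- !is.na(egger_p) &&
    egger_p > criteria$egger_intercept_p_min
  verdict <- if (!(p_pass && direction_pass && pleiotropy_pass)) {
    "fail"
  } else if (ivw_p < 0.05 / criteria$bonferroni_n) {
    "significant"
  } else {
    "suggestive"
  }
  structure(list(pair_id = pair_id, p_pass = p_pass,
                 direction_pass = direction_pass,
                 pleiotropy_pass = pleiotropy_pass,
                 verdict = verdict, ivw_p = ivw_p),
            class = "screen_outcome")
}

# one MR stage of the two-step design: instrument selection on the
# exposure-side study, harmonization against the downstream study,
# optional PRESSO outlier removal, then IVW
mr_stage <- function(from_stats, to_stats, criteria, ld = NULL,
                     presso = FALSE, stage = "stage",
                     effects_model = "multiplicative_random",
                     n_sim = 1000, seed = 42) {
  iv <- select_instruments(from_stats, ld, criteria)
  if (nrow(iv) == 0) {
    stop("no instruments survive selection at stage: ", stage)
  }
  h <- tryCatch(harmonize(iv, to_stats),
                error = function(e) {
                  stop("no instruments at stage ", stage, ": ",
                       conditionMessage(e))
                })
  if (presso && nrow(h) >= 4) {
    pr <- mr_presso(h, n_sim = n_sim, seed = seed)
    if (length(pr$outlier_indices) > 0 &&
        length(pr$outlier_indices) < nrow(h) - 1) {
      h <- h[-pr$outlier_indices, , drop = FALSE]
    }
  }
  mr_ivw(h, effects_model)
}

#' Two-step MR mediation from three summary-statistic studies
#'
#' Runs the full product-of-coefficients mediation analysis: step 1
#' estimates the exposure-to-mediator effect (IVW on the exposure's
#' instruments), step 2 the mediator-to-outcome effect (IVW on the
#' mediator's instruments), and the total effect comes from
#' exposure-to-outcome IVW; the mediated effect is the product of the two
#' step estimates, with delta-method CI and mediated proportion.
#'
#' @param exposure_stats,mediator_stats,outcome_stats Summary-statistics
#'   `data.frame`s for the three studies (each covering its own
#'   instruments and, for downstream studies, the upstream instruments).
#' @param criteria An [instrument_criteria()].
#' @param ld_exposure,ld_mediator Optional [ld_matrix()] objects for
#'   clumping the exposure and mediator instruments.
#' @param presso Apply MR-PRESSO outlier removal per stage, default
#'   `FALSE` (the synthetic generator plants no outliers by default).
#' @param effects_model IVW effects model.
#' @param n_sim,seed MR-PRESSO settings.
#' @param exposure,mediator,outcome Trait labels.
#' @return A `mediation_result` (see [mediation_result()]).
#' @export
two_step_mediation <- function(exposure_stats, mediator_stats,
                               outcome_stats,
                               criteria = instrument_criteria(),
                               ld_exposure = NULL, ld_mediator = NULL,
                               presso = FALSE,
                               effects_model = "multiplicative_random",
                               n_sim = 1000, seed = 42,
                               exposure = "exposure",
                               mediator = "mediator",
                               outcome = "outcome") {
  step1 <- mr_stage(exposure_stats, mediator_stats, criteria, ld_exposure,
                    presso, "exposure->mediator", effects_model,
                    n_sim, seed)
  step2 <- mr_stage(mediator_stats, outcome_stats, criteria, ld_mediator,
                    presso, "mediator->outcome", effects_model,
                    n_sim, seed)
  total <- mr_stage(exposure_stats, outcome_stats, criteria, ld_exposure,
                    presso, "exposure->outcome", effects_model,
                    n_sim, seed)
  mediation_result(step1$beta, step1$se, step2$beta, step2$se,
                   total$beta, total$se,
                   exposure = exposure, mediator = mediator,
                   outcome = outcome)
}

#' Reverse-direction MR
#'
#' Runs the five-method suite with the roles of the two studies swapped:
#' instruments are selected from the original outcome study and tested
#' against the original exposure study. Supports reverse-causation checks.
#'
#' @param outcome_stats Summary statistics of the study now used as the
#'   exposure (instrument source).
#' @param exposure_stats Summary statistics of the study now used as the
#'   outcome.
#' @param criteria An [instrument_criteria()].
#' @param ld Optional [ld_matrix()] for the instrument source.
#' @param ... Passed to [mr_all_methods()].
#' @return An `mr_method_bundle`.
#' @export
reverse_mr <- function(outcome_stats, exposure_stats,
                       criteria = instrument_criteria(), ld = NULL, ...) {
  iv <- select_instruments(outcome_stats, ld, criteria)
  if (nrow(iv) == 0) {
    stop("no instruments: the outcome study has no variants at threshold")
  }
  h <- harmonize(iv, exposure_stats)
  mr_all_methods(h, ...)
}
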