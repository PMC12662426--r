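#' Total effect of an exposure on an outcome
#'
#' Runs the full chain for one exposure-outcome pair: instrument selection on
#' the exposure ([selectInstruments()]), harmonization against the outcome,
#' and the IVW estimate.  This is the total effect \eqn{\alpha} of the
#' mediation decomposition.
#'
#' @param exposure,outcome [AssociationSet] objects.
#' @param ld an [LDSource] or NULL.
#' @param config an [mrConfig()] list of thresholds and estimator settings.
#' @return an [MREstimate]; the selected instrument ids are attached as
#'   attribute \code{"instruments"}.
#' @export
totalEffect <- function(exposure, outcome, ld = NULL, config = mrConfig()) {
  iv <- selectInstruments(exposure, ld,
                          p_threshold = config$p_instrument,
                          r2_max = config$r2_max,
                          window_kb = config$window_kb,
                          f_min = config$f_min)
  if (!length(variantIds(iv)))
    .stopf("no instruments survive selection for %s", traitId(exposure))
  h <- harmonize(exposure[variantIds(iv)], outcome)
  if (!nVariants(h))
    .stopf("no instruments survive harmonization for %s on %s",
           traitId(exposure), traitId(outcome))
  fit <- mrIVW(h, config$ivw_mode)
  attr(fit, "instruments") <- harmonizedData(h)$variant_id
  fit
}

#' The two mediation legs: exposure-to-mediator and mediator-to-outcome
#'
#' Estimates \eqn{\beta_1} (exposure on mediator) using instruments selected
#' from the exposure's own associations, and \eqn{\beta_2} (mediator on
#' outcome) using instruments re-selected from the mediator's own
#' associations; the two instrument sets are recorded for auditing.
#'
#' @param exposure,mediator,outcome [AssociationSet] objects.
#' @param ld an [LDSource] or NULL.
#' @param config an [mrConfig()] list.
#' @return list with [MREstimate] elements \code{beta1}, \code{beta2} and an
#'   \code{instruments} list of the two id vectors.
#' @export
twoStepEffects <- function(exposure, mediator, outcome, ld = NULL,
                           config = mrConfig()) {
  beta1 <- totalEffect(exposure, mediator, ld, config)
  beta2 <- totalEffect(mediator, outcome, ld, config)
  list(beta1 = beta1, beta2 = beta2,
       instruments = list(exposure = attr(beta1, "instruments"),
                          mediator = attr(beta2, "instruments")))
}

#' Combine the three legs into a mediation result
#'
#' Product-of-coefficients mediation: the indirect effect is
#' \eqn{\beta_1 \beta_2} with first-order delta-method standard error
#' \eqn{\sqrt{\beta_1^2 se_2^2 + \beta_2^2 se_1^2}} (the three legs come from
#' non-overlapping GWAS and are treated as independent); the proportion
#' mediated is \eqn{(\beta_1 \beta_2 / \alpha) \times 100\%} with a
#' delta-method CI over \eqn{(\beta_1, \beta_2, \alpha)}.  CI bounds are
#' always reported ascending.  The p-value is the two-sided normal test of
#' indirect = 0.
#'
#' @param alpha [MREstimate] of the total effect (exposure on outcome).
#' @param beta1 [MREstimate] of the exposure-on-mediator effect.
#' @param beta2 [MREstimate] of the mediator-on-outcome effect.
#' @param exposure_id,mediator_id,outcome_id optional trait labels.
#' @return a [MediationResult].
#' @examples
#' a  <- MRmediate:::.mrEstimate("IVW", 5L, 0.12, 0.03)
#' b1 <- MRmediate:::.mrEstimate("IVW", 5L, 0.30, 0.05)
#' b2 <- MRmediate:::.mrEstimate("IVW", 5L, 0.20, 0.04)
#' mediationCombine(a, b1, b2)  # indirect 0.06, proportion 50%
#' @export
mediationCombine <- function(alpha, beta1, beta2,
                             exposure_id = "exposure",
                             mediator_id = "mediator",
                             outcome_id = "outcome") {
  stopifnot(is(alpha, "MREstimate"), is(beta1, "MREstimate"),
            is(beta2, "MREstimate"))
  a <- alpha@beta
  if (a == 0) .stopf("total effect is zero: proportion mediated undefined")
  b1 <- beta1@beta
  b2 <- beta2@beta
  s1 <- beta1@se
  s2 <- beta2@se
  sa <- alpha@se

  ind <- b1 * b2
  se_ind <- sqrt(b1^2 * s2^2 + b2^2 * s1^2)
  z <- .z975()
  ind_ci <- sort(c(ind - z * se_ind, ind + z * se_ind))

  prop <- 100 * ind / a
  var_prop <- (b2 / a)^2 * s1^2 + (b1 / a)^2 * s2^2 + (ind / a^2)^2 * sa^2
  se_prop <- 100 * sqrt(var_prop)
  prop_ci <- sort(c(prop - z * se_prop, prop + z * se_prop))

  pval <- if (se_ind > 0) 2 * stats::pnorm(-abs(ind / se_ind)) else
    as.numeric(ind != 0)

  new("MediationResult",
      exposureId = exposure_id, mediatorId = mediator_id,
      outcomeId = outcome_id,
      alpha = a, alphaSe = sa, beta1 = b1, beta1Se = s1,
      beta2 = b2, beta2Se = s2,
      indirect = ind, indirectSe = se_ind,
      indirectCiLow = ind_ci[1], indirectCiHigh = ind_ci[2],
      proportion = prop, proportionSe = se_prop,
      proportionCiLow = prop_ci[1], proportionCiHigh = prop_ci[2],
      pval = pval)
}

#' Two-step MR mediation for one exposure/mediator/outcome triple
#'
#' Runs the three MR legs (total effect \eqn{\alpha}, exposure-on-mediator
#' \eqn{\beta_1}, mediator-on-outcome \eqn{\beta_2}), each with its own
#' instrument selection, and combines them with [mediationCombine()].
#'
#' @param exposure,mediator,outcome [AssociationSet] objects.
#' @param ld an [LDSource] or NULL.
#' @param config an [mrConfig()] list.
#' @return a [MediationResult]; the per-leg instrument ids are attached as
#'   attribute \code{"instruments"}.
#' @export
runMediation <- function(exposure, mediator, outcome, ld = NULL,
                         config = mrConfig()) {
  alpha <- totalEffect(exposure, outcome, ld, config)
  legs <- twoStepEffects(exposure, mediator, outcome, ld, config)
  res <- mediationCombine(alpha, legs$beta1, legs$beta2,
                          exposure_id = traitId(exposure),
                          mediator_id = traitId(mediator),
                          outcome_id = traitId(outcome))
  attr(res, "instruments") <- c(list(total = attr(alpha, "instruments")),
                                legs$instruments)
  res
}

#' Coerce a MediationResult to a one-row data.frame
#'
#' Columns mirror the mediated-effect summary-table convention: exposure,
#' mediator, outcome, mediated effect with 95\% CI, mediated proportion (\%)
#' with 95\% CI, p-value.
#'
#' @param x a [MediationResult].
#' @param row.names,optional,... passed over from the generic, unused.
#' @return one-row data.frame.
#' @export
as.data.frame.MediationResult <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(exposure = x@exposureId, mediator = x@mediatorId,
             outcome = x@outcomeId,
             alpha = x@alpha, alpha_se = x@alphaSe,
             beta1 = x@beta1, beta1_se = x@beta1Se,
             beta2 = x@beta2, beta2_se = x@beta2Se,
             mediated_effect = x@indirect,
             mediated_ci_low = x@indirectCiLow,
             mediated_ci_high = x@indirectCiHigh,
             proportion_pct = x@proportion,
             proportion_ci_low = x@proportionCiLow,
             proportion_ci_high = x@proportionCiHigh,
             pval = x@pval, stringsAsFactors = FALSE)
}
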