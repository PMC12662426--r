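#' Cochran's Q heterogeneity test
#'
#' For an IVW fit: \eqn{Q = \sum_j w_j (\beta_j - \hat\beta)^2} over the Wald
#' ratios, referred to a chi-square distribution on \eqn{J - 1} degrees of
#' freedom.  For an MR-Egger fit: Rucker's \eqn{Q'}, the weighted residual
#' sum of squares of the intercept-plus-slope regression, on \eqn{J - 2}
#' degrees of freedom.  A p-value below .05 suggests instrument
#' heterogeneity.
#'
#' @param h the [HarmonizedSet] the fit was computed from.
#' @param fit an [MREstimate] (IVW-type or MR-Egger); if NULL a fixed-effect
#'   IVW fit is computed internally.
#' @return list with elements \code{q}, \code{df}, \code{pval}.
#' @export
cochranQ <- function(h, fit = NULL) {
  stopifnot(is(h, "HarmonizedSet"))
  if (is.null(fit)) fit <- mrIVW(h, "fixed")
  d <- harmonizedData(h)
  if (identical(fit@method, "MR-Egger")) {
    flip <- d$gamma < 0
    g <- ifelse(flip, -d$gamma, d$gamma)
    G <- ifelse(flip, -d$Gamma, d$Gamma)
    w <- 1 / d$se_Gamma^2
    resid <- G - fit@intercept - fit@beta * g
    q <- sum(w * resid^2)
    df <- nrow(d) - 2
  } else {
    wr <- waldRatios(h)
    if (nrow(wr) < 2L) .stopf("Cochran's Q needs at least 2 instruments")
    q <- sum(wr$weight * (wr$ratio - fit@beta)^2)
    df <- nrow(wr) - 1
  }
  if (df < 1) .stopf("not enough instruments for a heterogeneity test")
  list(q = q, df = df, pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' MR-Egger intercept test of directional pleiotropy
#'
#' Two-sided t test (on \eqn{J - 2} degrees of freedom) that the MR-Egger
#' intercept is zero; a significant intercept indicates directional
#' horizontal pleiotropy.
#'
#' @param fit an [MREstimate] produced by [mrEgger()].
#' @return list with elements \code{intercept}, \code{se}, \code{pval}.
#' @export
eggerInterceptTest <- function(fit) {
  stopifnot(is(fit, "MREstimate"))
  if (!identical(fit@method, "MR-Egger"))
    .stopf("intercept test requires an MR-Egger fit (got '%s')", fit@method)
  list(intercept = fit@intercept, se = fit@interceptSe,
       pval = fit@interceptPval)
}

#' Leave-one-out IVW estimates
#'
#' Sequentially removes each SNP and recomputes the IVW estimate from the
#' remainder, exposing instruments whose exclusion materially moves the
#' pooled effect.
#'
#' @param h a [HarmonizedSet] with at least 3 SNPs.
#' @param mode IVW flavor, see [mrIVW()].
#' @return data.frame with one row per excluded SNP: \code{excluded, beta,
#'   se, ciLow, ciHigh, pval}.
#' @export
leaveOneOut <- function(h, mode = "random") {
  stopifnot(is(h, "HarmonizedSet"))
  d <- harmonizedData(h)
  j <- nrow(d)
  if (j < 3L) .stopf("leave-one-out needs at least 3 instruments (got %d)", j)
  rows <- lapply(seq_len(j), function(i) {
    fit <- mrIVW(h[-i], mode)
    data.frame(excluded = d$variant_id[i], beta = fit@beta, se = fit@se,
               ciLow = fit@ciLow, ciHigh = fit@ciHigh, pval = fit@pval,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full sensitivity report: heterogeneity, pleiotropy, leave-one-out
#'
#' Computes Cochran's Q against the IVW fit, Rucker's Q' and the intercept
#' test from the MR-Egger fit, and the leave-one-out IVW series.  Flags use
#' p < .05 for heterogeneity and pleiotropy; \code{loo_instability} is set
#' when some leave-one-out confidence interval lies entirely on the opposite
#' side of zero from the full-set point estimate.  The largest relative
#' change of the estimate under single-SNP removal is also reported (a
#' configurable threshold, default 30\%, contributes to the instability
#' flag).
#'
#' @param h a [HarmonizedSet] with at least 3 SNPs.
#' @param ivw_mode IVW flavor.
#' @param rel_change_max relative-change threshold for the instability flag.
#' @return a [SensitivityReport].
#' @export
sensitivityReport <- function(h, ivw_mode = "random", rel_change_max = 0.3) {
  ivw <- mrIVW(h, ivw_mode)
  egger <- mrEgger(h)
  q_ivw <- cochranQ(h, mrIVW(h, "fixed"))
  q_egger <- cochranQ(h, egger)
  loo <- leaveOneOut(h, ivw_mode)

  full_pos <- ivw@beta > 0
  sign_flip <- if (full_pos) any(loo$ciHigh < 0) else any(loo$ciLow > 0)
  rel_change <- if (abs(ivw@beta) > 0)
    max(abs(loo$beta - ivw@beta)) / abs(ivw@beta) else Inf
  flags <- c(heterogeneity = q_ivw$pval < 0.05,
             pleiotropy = egger@interceptPval < 0.05,
             loo_instability = sign_flip || rel_change > rel_change_max)
  new("SensitivityReport",
      exposureId = exposureId(h), outcomeId = outcomeId(h),
      qIvw = q_ivw$q, qIvwDf = q_ivw$df, qIvwPval = q_ivw$pval,
      qEgger = q_egger$q, qEggerDf = q_egger$df, qEggerPval = q_egger$pval,
      eggerIntercept = egger@intercept, eggerInterceptSe = egger@interceptSe,
      eggerInterceptPval = egger@interceptPval,
      loo = loo, flags = flags, looMaxRelChange = rel_change)
}

#' Write a SensitivityReport as tab-separated text
#'
#' One-row TSV with columns mirroring supplementary-table conventions
#' (Q, Q_df, Q_pval, Q_egger, Q_egger_df, Q_egger_pval, egger_intercept,
#' intercept_se, intercept_pval, loo_unstable), plus a companion
#' \code{<path>.loo.tsv} with the leave-one-out series.
#'
#' @param object a [SensitivityReport].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSensitivity <- function(object, path) {
  stopifnot(is(object, "SensitivityReport"))
  row <- data.frame(
    exposure = object@exposureId, outcome = object@outcomeId,
    Q = object@qIvw, Q_df = object@qIvwDf, Q_pval = object@qIvwPval,
    Q_egger = object@qEgger, Q_egger_df = object@qEggerDf,
    Q_egger_pval = object@qEggerPval,
    egger_intercept = object@eggerIntercept,
    intercept_se = object@eggerInterceptSe,
    intercept_pval = object@eggerInterceptPval,
    loo_unstable = object@flags[["loo_instability"]],
    stringsAsFactors = FALSE)
  utils::write.table(row, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(object@loo, paste0(path, ".loo.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
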