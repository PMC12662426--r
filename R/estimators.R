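# Shared constructor for estimator results.
.mrEstimate <- function(method, nsnp, beta, se, pval = NULL, df = NA_real_,
                        intercept = NA_real_, intercept_se = NA_real_,
                        intercept_pval = NA_real_) {
  z <- .z975()
  ci_low <- beta - z * se
  ci_high <- beta + z * se
  if (is.null(pval))
    pval <- if (is.finite(se) && se > 0) 2 * stats::pnorm(-abs(beta / se))
            else NA_real_
  new("MREstimate", method = method, nsnp = as.integer(nsnp),
      beta = beta, se = se, ciLow = ci_low, ciHigh = ci_high, pval = pval,
      orValue = exp(beta), orCiLow = exp(ci_low), orCiHigh = exp(ci_high),
      intercept = intercept, interceptSe = intercept_se,
      interceptPval = intercept_pval, df = df)
}

#' Per-SNP Wald ratios
#'
#' For each harmonized SNP, the ratio estimate \eqn{\beta_j = \Gamma_j /
#' \gamma_j} of the causal effect, its first-order delta-method standard
#' error \eqn{SE_j = se_{\Gamma_j} / |\gamma_j|} (exposure-side error
#' ignored, so the inverse-variance weights reduce to the standard
#' \eqn{w_j = \gamma_j^2 / se_{\Gamma_j}^2}), and the weight \eqn{w_j =
#' 1/SE_j^2}.  SNPs with a zero exposure effect are excluded with a warning.
#'
#' @param h a [HarmonizedSet].
#' @return data.frame with columns \code{variant_id, ratio, ratio_se, weight}.
#' @export
waldRatios <- function(h) {
  stopifnot(is(h, "HarmonizedSet"))
  d <- harmonizedData(h)
  zero <- d$gamma == 0
  if (any(zero)) {
    warning(sprintf("%d SNP(s) with zero exposure effect excluded", sum(zero)))
    d <- d[!zero, , drop = FALSE]
  }
  ratio_se <- d$se_Gamma / abs(d$gamma)
  data.frame(variant_id = d$variant_id,
             ratio = d$Gamma / d$gamma,
             ratio_se = ratio_se,
             weight = 1 / ratio_se^2,
             stringsAsFactors = FALSE)
}

#' Inverse-variance weighted estimate
#'
#' The principal estimator: the precision-weighted mean of the Wald ratios,
#' \eqn{\hat\beta = \sum w_j \beta_j / \sum w_j} with \eqn{w_j = \gamma_j^2 /
#' se_{\Gamma_j}^2}, algebraically identical to weighted least squares of
#' \eqn{\Gamma_j} on \eqn{\gamma_j} through the origin.  The fixed-effect
#' standard error is \eqn{(\sum w_j)^{-1/2}}; under the default
#' multiplicative random-effects model it is inflated by
#' \eqn{\max(1, \sqrt{Q/(J-1)})}, so the two coincide when the instruments
#' are homogeneous.  A single SNP degenerates to its Wald ratio.
#'
#' @param h a [HarmonizedSet].
#' @param mode \code{"random"} (multiplicative random effects, default) or
#'   \code{"fixed"}.
#' @return an [MREstimate] with method \code{"IVW"}.
#' @export
mrIVW <- function(h, mode = c("random", "fixed")) {
  mode <- match.arg(mode)
  wr <- waldRatios(h)
  j <- nrow(wr)
  if (j == 0L) .stopf("no instruments available for IVW")
  w <- wr$weight
  beta <- sum(w * wr$ratio) / sum(w)
  se <- sqrt(1 / sum(w))
  if (mode == "random" && j >= 2L) {
    q <- sum(w * (wr$ratio - beta)^2)
    se <- se * max(1, sqrt(q / (j - 1)))
  }
  .mrEstimate("IVW", j, beta, se)
}

#' MR-Egger regression
#'
#' Weighted least squares of \eqn{\Gamma_j} on \eqn{\gamma_j} with an
#' unconstrained intercept and weights \eqn{1/se_{\Gamma_j}^2}, after
#' re-orienting every SNP so \eqn{\gamma_j \ge 0} (required for the intercept
#' to be interpretable as average directional pleiotropy).  The slope is the
#' pleiotropy-robust causal estimate under the InSIDE assumption; a nonzero
#' intercept indicates directional horizontal pleiotropy.  Standard errors
#' use the multiplicative random-effects scaling \eqn{\max(1,
#' \sqrt{Q'/(J-2)})} and p-values the t distribution on \eqn{J-2} degrees of
#' freedom.
#'
#' @param h a [HarmonizedSet] with at least 3 SNPs.
#' @return an [MREstimate] with method \code{"MR-Egger"}; the intercept, its
#'   SE and p-value are carried in the corresponding slots.
#' @export
mrEgger <- function(h) {
  stopifnot(is(h, "HarmonizedSet"))
  d <- harmonizedData(h)
  j <- nrow(d)
  if (j < 3L) .stopf("MR-Egger needs at least 3 instruments (got %d)", j)
  flip <- d$gamma < 0
  g <- ifelse(flip, -d$gamma, d$gamma)
  G <- ifelse(flip, -d$Gamma, d$Gamma)
  w <- 1 / d$se_Gamma^2
  fit <- stats::lm(G ~ g, weights = w)
  sm <- summary(fit)
  coefs <- sm$coefficients
  sigma <- sm$sigma  # sqrt(Q' / (J - 2)) in the weighted model
  se_unscaled <- coefs[, "Std. Error"] / sigma
  se <- se_unscaled * max(1, sigma)
  slope <- coefs["g", "Estimate"]
  intercept <- coefs["(Intercept)", "Estimate"]
  pt2 <- function(est, s) 2 * stats::pt(-abs(est / s), df = j - 2)
  .mrEstimate("MR-Egger", j, slope, se[["g"]],
              pval = pt2(slope, se[["g"]]), df = j - 2,
              intercept = intercept, intercept_se = se[["(Intercept)"]],
              intercept_pval = pt2(intercept, se[["(Intercept)"]]))
}

# Weighted median of ratios at standardized cumulative weight 0.5.
.weightedMedian <- function(ratio, w) {
  o <- order(ratio)
  r <- ratio[o]
  ww <- w[o]
  p <- (cumsum(ww) - ww / 2) / sum(ww)
  if (0.5 <= p[1L]) return(r[1L])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

# Parametric bootstrap over the harmonized effects: resample gamma and Gamma
# from their reported sampling distributions and recompute the estimator.
.bootSe <- function(d, statistic, n_boot, seed) {
  if (n_boot <= 0L) return(NA_real_)
  if (is.null(seed))
    .stopf("a seed is required for bootstrap standard errors")
  j <- nrow(d)
  .withSeed(seed, {
    reps <- vapply(seq_len(n_boot), function(b) {
      g <- stats::rnorm(j, d$gamma, d$se_gamma)
      G <- stats::rnorm(j, d$Gamma, d$se_Gamma)
      ok <- g != 0
      statistic(G[ok] / g[ok], g[ok]^2 / d$se_Gamma[ok]^2)
    }, numeric(1))
    stats::sd(reps)
  })
}

#' Weighted-median estimate
#'
#' Orders the Wald ratios and interpolates them at standardized cumulative
#' weight 0.5 (\eqn{p_j = (\sum_{k \le j} w_k - w_j/2) / \sum_k w_k}).
#' Consistent when at least half the total weight comes from valid
#' instruments.  The standard error comes from a seeded parametric bootstrap
#' (resampling \eqn{\gamma_j} and \eqn{\Gamma_j} from normal distributions
#' with their reported SEs); \code{n_boot = 0} skips it and returns an
#' estimate with NA standard error.
#'
#' @param h a [HarmonizedSet] with at least 3 SNPs.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap (required when
#'   \code{n_boot > 0}).
#' @return an [MREstimate] with method \code{"weighted-median"}.
#' @export
mrWeightedMedian <- function(h, n_boot = 1000L, seed = NULL) {
  wr <- waldRatios(h)
  if (nrow(wr) < 3L)
    .stopf("weighted median needs at least 3 instruments (got %d)", nrow(wr))
  beta <- .weightedMedian(wr$ratio, wr$weight)
  d <- harmonizedData(h)
  d <- d[d$gamma != 0, , drop = FALSE]
  se <- .bootSe(d, function(r, w) .weightedMedian(r, w), n_boot, seed)
  .mrEstimate("weighted-median", nrow(wr), beta, se)
}

# Mode of a Gaussian kernel density over the ratios.  Bandwidth
# phi * 1.06 * s * J^(-1/5) with s the (weighted) SD of the ratios.
.modeOfRatios <- function(ratio, w, phi) {
  s <- .wsd(ratio, w)
  j <- length(ratio)
  bw <- phi * 1.06 * s * j^(-1 / 5)
  if (!is.finite(bw) || bw <= 0) return(ratio[which.max(w)])
  dens <- stats::density(ratio, weights = w / sum(w), bw = bw, n = 2048,
                         kernel = "gaussian")
  dens$x[which.max(dens$y)]
}

#' Mode-based estimates (simple and weighted mode)
#'
#' The causal estimate is the mode of a Gaussian kernel density over the
#' Wald ratios: unweighted for the simple mode, inverse-variance weighted
#' for the weighted mode.  The bandwidth is \eqn{\varphi \times 1.06\, s\,
#' J^{-1/5}} with \eqn{s} the (weighted) standard deviation of the ratios
#' and \eqn{\varphi} a tuning factor (default 1).  Consistent when the
#' largest group of instruments sharing one ratio value is valid (the ZEMPA
#' assumption).  Standard errors come from the same seeded parametric
#' bootstrap as [mrWeightedMedian()].
#'
#' @param h a [HarmonizedSet] with at least 3 SNPs.
#' @param weighted use inverse-variance weights (weighted mode) or equal
#'   weights (simple mode).
#' @param bandwidth_factor the tuning factor \eqn{\varphi}.
#' @param n_boot,seed bootstrap settings, see [mrWeightedMedian()].
#' @return an [MREstimate] with method \code{"weighted-mode"} or
#'   \code{"simple-mode"}.
#' @export
mrMode <- function(h, weighted = TRUE, bandwidth_factor = 1, n_boot = 1000L,
                   seed = NULL) {
  wr <- waldRatios(h)
  if (nrow(wr) < 3L)
    .stopf("mode estimator needs at least 3 instruments (got %d)", nrow(wr))
  wts <- if (weighted) wr$weight else rep(1, nrow(wr))
  beta <- .modeOfRatios(wr$ratio, wts, bandwidth_factor)
  d <- harmonizedData(h)
  d <- d[d$gamma != 0, , drop = FALSE]
  stat <- if (weighted) {
    function(r, w) .modeOfRatios(r, w, bandwidth_factor)
  } else {
    function(r, w) .modeOfRatios(r, rep(1, length(r)), bandwidth_factor)
  }
  se <- .bootSe(d, stat, n_boot, seed)
  .mrEstimate(if (weighted) "weighted-mode" else "simple-mode",
              nrow(wr), beta, se)
}

#' @rdname mrMode
#' @export
mrWeightedMode <- function(h, bandwidth_factor = 1, n_boot = 1000L,
                           seed = NULL)
  mrMode(h, weighted = TRUE, bandwidth_factor = bandwidth_factor,
         n_boot = n_boot, seed = seed)

#' @rdname mrMode
#' @export
mrSimpleMode <- function(h, bandwidth_factor = 1, n_boot = 1000L,
                         seed = NULL)
  mrMode(h, weighted = FALSE, bandwidth_factor = bandwidth_factor,
         n_boot = n_boot, seed = seed)

#' All five MR estimators on one harmonized set
#'
#' Runs IVW (principal) plus the four validation estimators (MR-Egger,
#' weighted median, weighted mode, simple mode) when at least 3 instruments
#' are available, and returns them as a named list.
#'
#' @param h a [HarmonizedSet].
#' @param ivw_mode IVW flavor, see [mrIVW()].
#' @param n_boot,seed,bandwidth_factor settings for the bootstrap-based
#'   estimators.
#' @return named list of [MREstimate] objects (\code{ivw}, and when
#'   \eqn{J \ge 3}: \code{egger, weighted_median, weighted_mode,
#'   simple_mode}).
#' @export
mrAllMethods <- function(h, ivw_mode = "random", n_boot = 1000L, seed = NULL,
                         bandwidth_factor = 1) {
  if (n_boot > 0 && is.null(seed))
    .stopf("a seed is required when n_boot > 0")
  out <- list(ivw = mrIVW(h, ivw_mode))
  if (nVariants(h) >= 3L) {
    out$egger <- mrEgger(h)
    out$weighted_median <- mrWeightedMedian(
      h, n_boot, seed = if (n_boot > 0) deriveSeed(seed, "wmedian") else NULL)
    out$weighted_mode <- mrWeightedMode(
      h, bandwidth_factor, n_boot,
      seed = if (n_boot > 0) deriveSeed(seed, "wmode") else NULL)
    out$simple_mode <- mrSimpleMode(
      h, bandwidth_factor, n_boot,
      seed = if (n_boot > 0) deriveSeed(seed, "smode") else NULL)
  }
  out
}
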