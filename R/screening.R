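#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: for p-values sorted ascending,
#' \eqn{q_{(i)} = \min_{j \ge i} m\, p_{(j)} / j}, returned in the original
#' order and capped at 1.  Hand-rolled (a cumulative minimum over the sorted
#' vector) so the package's multiple-testing step is independently testable
#' against enumeration oracles.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return numeric vector of q-values, same order as the input.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhFdr <- function(pvals) {
  m <- length(pvals)
  if (!m) return(numeric(0))
  if (any(!is.finite(pvals) | pvals < 0 | pvals > 1))
    .stopf("p-values must lie in [0, 1]")
  o <- order(pvals)
  adj <- pvals[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(adj)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' Evidence tier for one tested pair
#'
#' \code{"strong"} when the nominal p-value clears the screening threshold
#' (default .01) and the FDR q-value is below \code{fdr_max} (default .05);
#' \code{"suggestive"} when p < .05 without meeting the strong rule;
#' \code{"null"} otherwise.
#'
#' @param p nominal p-values.
#' @param q FDR q-values (same length).
#' @param p_screen nominal p threshold of the strong tier.
#' @param fdr_max FDR threshold of the strong tier.
#' @return character vector of tiers.
#' @export
tierEvidence <- function(p, q, p_screen = 0.01, fdr_max = 0.05) {
  stopifnot(length(p) == length(q))
  strong <- p < p_screen & q < fdr_max
  suggestive <- p < 0.05 & !strong
  out <- rep("null", length(p))
  out[suggestive] <- "suggestive"
  out[strong] <- "strong"
  out
}

#' Screen many exposures against outcomes
#'
#' Runs the full per-pair pipeline (instrument selection, harmonization, IVW
#' plus the four validation estimators, sensitivity diagnostics) for every
#' exposure-outcome combination, applies Benjamini-Hochberg FDR within each
#' family, and assigns evidence tiers.  An FDR family is all exposures of one
#' trait class tested against one outcome, the most conservative reading
#' consistent with per-outcome reporting.  Pair-level failures (e.g. no
#' surviving instruments) are recorded in the \code{status} column, not
#' fatal.  Deterministic given \code{config$seed}: bootstrap substreams are
#' derived per pair.
#'
#' @param exposures list of [AssociationSet] exposures (one trait class per
#'   family; mixed classes form separate families).
#' @param outcomes list of [AssociationSet] outcomes.
#' @param ld an [LDSource] or NULL.
#' @param config an [mrConfig()] list; \code{seed} is required when
#'   \code{n_boot > 0}.
#' @return data.frame with one row per pair: identifiers, instrument count,
#'   the IVW estimate (beta, se, OR with CI, p), the four validation betas
#'   and p-values, heterogeneity/pleiotropy diagnostics, FDR q-value and
#'   tier.
#' @export
runScreen <- function(exposures, outcomes, ld = NULL, config = mrConfig()) {
  if (!length(exposures)) .stopf("at least one exposure is required")
  if (!length(outcomes)) .stopf("at least one outcome is required")
  stopifnot(all(vapply(exposures, is, logical(1), "AssociationSet")),
            all(vapply(outcomes, is, logical(1), "AssociationSet")))
  if (config$n_boot > 0 && is.null(config$seed))
    .stopf("config$seed is required when n_boot > 0")

  rows <- list()
  k <- 0L
  for (oi in seq_along(outcomes)) {
    for (ei in seq_along(exposures)) {
      k <- k + 1L
      ex <- exposures[[ei]]
      ou <- outcomes[[oi]]
      row <- data.frame(
        exposure = traitId(ex), outcome = traitId(ou),
        exposure_class = traitType(ex), nsnp = NA_integer_,
        beta = NA_real_, se = NA_real_, or = NA_real_,
        or_ci_low = NA_real_, or_ci_high = NA_real_, pval = NA_real_,
        beta_egger = NA_real_, pval_egger = NA_real_,
        beta_wmedian = NA_real_, pval_wmedian = NA_real_,
        beta_wmode = NA_real_, pval_wmode = NA_real_,
        beta_smode = NA_real_, pval_smode = NA_real_,
        q_pval = NA_real_, egger_intercept = NA_real_,
        egger_intercept_pval = NA_real_, loo_unstable = NA,
        fdr = NA_real_, tier = NA_character_, status = "ok",
        stringsAsFactors = FALSE)
      res <- tryCatch({
        iv <- selectInstruments(ex, ld,
                                p_threshold = config$p_instrument,
                                r2_max = config$r2_max,
                                window_kb = config$window_kb,
                                f_min = config$f_min)
        if (!length(variantIds(iv))) .stopf("no instruments after filtering")
        h <- harmonize(ex[variantIds(iv)], ou)
        if (!nVariants(h)) .stopf("no instruments after harmonization")
        pair_seed <- if (is.null(config$seed)) NULL
                     else deriveSeed(config$seed, "screen", k)
        fits <- mrAllMethods(h, config$ivw_mode, config$n_boot, pair_seed,
                             config$bandwidth_factor)
        row$nsnp <- fits$ivw@nsnp
        row$beta <- fits$ivw@beta
        row$se <- fits$ivw@se
        row$or <- fits$ivw@orValue
        row$or_ci_low <- fits$ivw@orCiLow
        row$or_ci_high <- fits$ivw@orCiHigh
        row$pval <- fits$ivw@pval
        if (!is.null(fits$egger)) {
          row$beta_egger <- fits$egger@beta
          row$pval_egger <- fits$egger@pval
          row$beta_wmedian <- fits$weighted_median@beta
          row$pval_wmedian <- fits$weighted_median@pval
          row$beta_wmode <- fits$weighted_mode@beta
          row$pval_wmode <- fits$weighted_mode@pval
          row$beta_smode <- fits$simple_mode@beta
          row$pval_smode <- fits$simple_mode@pval
          sens <- sensitivityReport(h, config$ivw_mode)
          row$q_pval <- sens@qIvwPval
          row$egger_intercept <- sens@eggerIntercept
          row$egger_intercept_pval <- sens@eggerInterceptPval
          row$loo_unstable <- sens@flags[["loo_instability"]]
        }
        row
      }, error = function(e) {
        row$status <- conditionMessage(e)
        row
      })
      rows[[k]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL

  # FDR families: one outcome x one exposure class; every tested pair
  # belongs to exactly one family.
  fam <- interaction(out$outcome, out$exposure_class, drop = TRUE)
  for (f in levels(fam)) {
    idx <- which(fam == f & out$status == "ok" & !is.na(out$pval))
    if (!length(idx)) next
    out$fdr[idx] <- bhFdr(out$pval[idx])
    out$tier[idx] <- tierEvidence(out$pval[idx], out$fdr[idx],
                                  config$p_screen, config$fdr_max)
  }
  out
}
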