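#' @import methods
NULL

.TRAIT_TYPES <- c("exposure-immune", "mediator-metabolite", "outcome-disease")

.ASSOC_COLS <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                 "beta", "se", "pval", "eaf", "n")

#' AssociationSet: per-variant GWAS summary associations for one trait
#'
#' Container for the summary-association table of a single trait (one GWAS).
#' Each record carries the per-allele effect estimate \code{beta} (log odds
#' ratio for binary traits, SD units for continuous traits), its standard
#' error, the association p-value, the allele pair defining the orientation of
#' \code{beta}, and optionally chromosome/position (used only for clumping
#' windows), effect-allele frequency and sample size.
#'
#' Invariants enforced by the validity method: positive standard errors,
#' p-values in \eqn{[0,1]}, distinct uppercase alleles, and unique
#' \code{variant_id}.
#'
#' @slot traitId accession or label of the trait.
#' @slot traitType one of \code{"exposure-immune"}, \code{"mediator-metabolite"},
#'   \code{"outcome-disease"}.
#' @slot assoc data.frame of per-variant records (canonical columns
#'   \code{variant_id, chrom, pos, effect_allele, other_allele, beta, se,
#'   pval, eaf, n}).
#'
#' @seealso [readSummary()], [harmonize()], [selectInstruments()]
#' @export
setClass("AssociationSet",
         representation(traitId = "character",
                        traitType = "character",
                        assoc = "data.frame"))

setValidity("AssociationSet", function(object) {
  msg <- character(0)
  if (length(object@traitId) != 1L || !nzchar(object@traitId))
    msg <- c(msg, "traitId must be a single non-empty string")
  if (length(object@traitType) != 1L || !object@traitType %in% .TRAIT_TYPES)
    msg <- c(msg, sprintf("traitType must be one of: %s",
                          paste(.TRAIT_TYPES, collapse = ", ")))
  a <- object@assoc
  missing_cols <- setdiff(.ASSOC_COLS, names(a))
  if (length(missing_cols))
    return(sprintf("assoc is missing columns: %s",
                   paste(missing_cols, collapse = ", ")))
  if (nrow(a)) {
    if (anyDuplicated(a$variant_id))
      msg <- c(msg, "variant_id must be unique within an AssociationSet")
    if (!all(is.finite(a$se)) || any(a$se <= 0))
      msg <- c(msg, "all standard errors must be finite and > 0")
    if (any(!is.finite(a$pval) | a$pval < 0 | a$pval > 1))
      msg <- c(msg, "all p-values must lie in [0, 1]")
    if (any(a$effect_allele == a$other_allele))
      msg <- c(msg, "effect_allele must differ from other_allele")
    if (any(a$effect_allele != toupper(a$effect_allele)) ||
        any(a$other_allele != toupper(a$other_allele)))
      msg <- c(msg, "alleles must be uppercase")
    eaf_ok <- is.na(a$eaf) | (a$eaf >= 0 & a$eaf <= 1)
    if (!all(eaf_ok))
      msg <- c(msg, "eaf must be in [0, 1] or NA")
  }
  if (length(msg)) msg else TRUE
})

#' HarmonizedSet: exposure-outcome paired per-SNP effects
#'
#' The result of allele harmonization between an exposure and an outcome
#' AssociationSet.  For each shared SNP it stores the exposure effect
#' \eqn{\gamma_j} with its SE, the outcome effect \eqn{\Gamma_j} with its SE
#' re-expressed for the exposure's effect allele, and the exposure p-value
#' used for instrument bookkeeping.  Palindromic (A/T, C/G) SNPs and SNPs with
#' irreconcilable allele pairs are absent by construction; their counts are
#' retained for auditing.
#'
#' @slot exposureId,outcomeId trait identifiers of the two parents.
#' @slot data data.frame with columns \code{variant_id, gamma, se_gamma,
#'   Gamma, se_Gamma, pval_exposure}.
#' @slot nDroppedPalindromic,nDroppedIncompatible integer drop counts.
#'
#' @seealso [harmonize()], [waldRatios()], [mrIVW()]
#' @export
setClass("HarmonizedSet",
         representation(exposureId = "character",
                        outcomeId = "character",
                        data = "data.frame",
                        nDroppedPalindromic = "integer",
                        nDroppedIncompatible = "integer"))

.HARM_COLS <- c("variant_id", "gamma", "se_gamma", "Gamma", "se_Gamma",
                "pval_exposure")

setValidity("HarmonizedSet", function(object) {
  d <- object@data
  missing_cols <- setdiff(.HARM_COLS, names(d))
  if (length(missing_cols))
    return(sprintf("data is missing columns: %s",
                   paste(missing_cols, collapse = ", ")))
  msg <- character(0)
  if (nrow(d)) {
    if (anyDuplicated(d$variant_id)) msg <- c(msg, "duplicate variant_id")
    if (any(d$se_gamma <= 0) || any(d$se_Gamma <= 0))
      msg <- c(msg, "standard errors must be > 0")
  }
  if (object@nDroppedPalindromic < 0L || object@nDroppedIncompatible < 0L)
    msg <- c(msg, "drop counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' InstrumentSet: variants surviving the instrument-selection filters
#'
#' Ordered set of variant ids retained after the p-value screen, greedy LD
#' clumping and the F-statistic weak-instrument filter, together with the
#' per-SNP F statistic (\eqn{F = \beta^2 / SE^2} on the exposure) and audit
#' counts recording how many SNPs each filter stage passed.
#'
#' @slot variantIds character vector of retained variant ids (selection order).
#' @slot fStat named numeric vector of per-SNP F statistics.
#' @slot audit named integer vector of per-stage SNP counts
#'   (\code{n_input, n_after_pvalue, n_after_clump, n_after_f}).
#' @seealso [selectInstruments()]
#' @export
setClass("InstrumentSet",
         representation(variantIds = "character",
                        fStat = "numeric",
                        audit = "integer"))

setValidity("InstrumentSet", function(object) {
  if (length(object@fStat) != length(object@variantIds))
    return("fStat must have one entry per retained variant")
  if (length(object@variantIds) &&
      !identical(names(object@fStat), object@variantIds))
    return("fStat must be named by variantIds, in order")
  TRUE
})

#' MREstimate: one MR method's causal estimate
#'
#' A single causal-effect estimate on the log odds-ratio scale, with its
#' standard error, normal 95\% confidence interval, two-sided p-value and the
#' exponentiated (odds ratio) scale.  MR-Egger estimates additionally carry
#' the regression intercept, its SE and p-value (the horizontal-pleiotropy
#' test) and the residual degrees of freedom used for t-based inference.
#'
#' @slot method estimator label (\code{"IVW"}, \code{"MR-Egger"},
#'   \code{"weighted-median"}, \code{"weighted-mode"}, \code{"simple-mode"}).
#' @slot nsnp number of instruments used.
#' @slot beta,se point estimate (log OR) and standard error.
#' @slot ciLow,ciHigh normal 95\% confidence bounds.
#' @slot pval two-sided p-value (normal, or t for MR-Egger).
#' @slot orValue,orCiLow,orCiHigh the estimate and CI on the odds-ratio scale.
#' @slot intercept,interceptSe,interceptPval MR-Egger intercept terms (NA for
#'   other methods).
#' @slot df residrual degrees of freedom for t-based p-values (NA when normal).
#' @export
setClass("MREstimate",
         representation(method = "character",
                        nsnp = "integer",
                        beta = "numeric",
                        se = "numeric",
                        ciLow = "numeric",
                        ciHigh = "numeric",
                        pval = "numeric",
                        orValue = "numeric",
                        orCiLow = "numeric",
                        orCiHigh = "numeric",
                        intercept = "numeric",
                        interceptSe = "numeric",
                        interceptPval = "numeric",
                        df = "numeric"))

setValidity("MREstimate", function(object) {
  msg <- character(0)
  if (is.finite(object@ciLow) && is.finite(object@ciHigh) &&
      !(object@ciLow <= object@beta && object@beta <= object@ciHigh))
    msg <- c(msg, "confidence interval must bracket the point estimate")
  if (is.finite(object@orValue) && object@orValue <= 0)
    msg <- c(msg, "odds ratio must be positive")
  if (object@nsnp < 1L) msg <- c(msg, "nsnp must be >= 1")
  if (length(msg)) msg else TRUE
})

#' SensitivityReport: heterogeneity, pleiotropy and leave-one-out diagnostics
#'
#' @slot exposureId,outcomeId trait identifiers.
#' @slot qIvw,qIvwDf,qIvwPval Cochran's Q against the IVW fit (df = J - 1).
#' @slot qEgger,qEggerDf,qEggerPval Rucker's Q' against the MR-Egger fit
#'   (df = J - 2).
#' @slot eggerIntercept,eggerInterceptSe,eggerInterceptPval the MR-Egger
#'   intercept test of directional pleiotropy.
#' @slot loo data.frame of leave-one-out IVW estimates (one row per excluded
#'   SNP: \code{excluded, beta, se, ciLow, ciHigh, pval}).
#' @slot flags named logical vector: \code{heterogeneity} (Q p < .05),
#'   \code{pleiotropy} (intercept p < .05), \code{loo_instability} (some
#'   leave-one-out CI lies entirely on the opposite side of zero from the
#'   full-set estimate).
#' @slot looMaxRelChange largest relative change of the estimate under
#'   single-SNP removal.
#' @seealso [sensitivityReport()]
#' @export
setClass("SensitivityReport",
         representation(exposureId = "character",
                        outcomeId = "character",
                        qIvw = "numeric", qIvwDf = "numeric", qIvwPval = "numeric",
                        qEgger = "numeric", qEggerDf = "numeric", qEggerPval = "numeric",
                        eggerIntercept = "numeric",
                        eggerInterceptSe = "numeric",
                        eggerInterceptPval = "numeric",
                        loo = "data.frame",
                        flags = "logical",
                        looMaxRelChange = "numeric"))

#' MediationResult: two-step MR mediation for one exposure/mediator/outcome triple
#'
#' Product-of-coefficients mediation on summary statistics: the total effect
#' \eqn{\alpha} (exposure to outcome), the two legs \eqn{\beta_1} (exposure to
#' mediator) and \eqn{\beta_2} (mediator to outcome), the indirect effect
#' \eqn{\beta_1 \beta_2} with a delta-method SE, and the proportion mediated
#' \eqn{(\beta_1 \beta_2 / \alpha) \times 100\%} with a delta-method CI
#' treating the three legs as independent.
#'
#' @slot exposureId,mediatorId,outcomeId trait identifiers.
#' @slot alpha,alphaSe total effect and SE.
#' @slot beta1,beta1Se exposure-to-mediator effect and SE.
#' @slot beta2,beta2Se mediator-to-outcome effect and SE.
#' @slot indirect,indirectSe,indirectCiLow,indirectCiHigh the product
#'   \eqn{\beta_1\beta_2} with SE and normal 95\% CI.
#' @slot proportion,proportionSe,proportionCiLow,proportionCiHigh proportion
#'   mediated, in percent, with delta-method SE and CI (bounds ascending).
#' @slot pval two-sided normal test of indirect = 0.
#' @seealso [mediationCombine()], [runMediation()]
#' @export
setClass("MediationResult",
         representation(exposureId = "character",
                        mediatorId = "character",
                        outcomeId = "character",
                        alpha = "numeric", alphaSe = "numeric",
                        beta1 = "numeric", beta1Se = "numeric",
                        beta2 = "numeric", beta2Se = "numeric",
                        indirect = "numeric", indirectSe = "numeric",
                        indirectCiLow = "numeric", indirectCiHigh = "numeric",
                        proportion = "numeric", proportionSe = "numeric",
                        proportionCiLow = "numeric", proportionCiHigh = "numeric",
                        pval = "numeric"))

setValidity("MediationResult", function(object) {
  msg <- character(0)
  if (abs(object@indirect - object@beta1 * object@beta2) >
      1e-12 * max(1, abs(object@indirect)))
    msg <- c(msg, "indirect effect must equal beta1 * beta2")
  if (is.finite(object@indirectCiLow) &&
      object@indirectCiLow > object@indirectCiHigh)
    msg <- c(msg, "indirect CI bounds must be ascending")
  if (is.finite(object@proportionCiLow) &&
      object@proportionCiLow > object@proportionCiHigh)
    msg <- c(msg, "proportion CI bounds must be ascending")
  if (length(msg)) msg else TRUE
})

# ---- LD sources -------------------------------------------------------------

#' LDSource: abstract provider of pairwise linkage-disequilibrium r-squared
#'
#' Virtual parent of [LDMatrix] (dense matrix, fixtures and simulations) and
#' [LDPairList] (sparse precomputed pair list, real use).  Implementations
#' answer [ldR2()] queries; variants unknown to the source are treated as in
#' linkage equilibrium (r-squared 0) with everything else.
#' @export
setClass("LDSource", representation("VIRTUAL"))

#' @describeIn LDSource-class dense symmetric r-squared matrix over a fixed
#'   set of variant ids.
#' @slot ids variant ids (row/column order of \code{r2}).
#' @slot r2 symmetric matrix of pairwise r-squared values in [0, 1].
#' @export
setClass("LDMatrix", contains = "LDSource",
         representation(ids = "character", r2 = "matrix"))

setValidity("LDMatrix", function(object) {
  if (nrow(object@r2) != length(object@ids) ||
      ncol(object@r2) != length(object@ids))
    return("r2 must be a square matrix matching ids")
  if (any(object@r2 < 0 | object@r2 > 1)) return("r2 values must be in [0, 1]")
  if (max(abs(object@r2 - t(object@r2))) > 1e-12) return("r2 must be symmetric")
  if (length(object@ids) && max(abs(diag(object@r2) - 1)) > 1e-12)
    return("diagonal r2 must be 1")
  TRUE
})

#' @describeIn LDSource-class sparse pair list; absent pairs have r-squared 0.
#' @slot pairs data.frame with columns \code{id_a, id_b, r2}.
#' @export
setClass("LDPairList", contains = "LDSource",
         representation(pairs = "data.frame"))

setValidity("LDPairList", function(object) {
  p <- object@pairs
  if (!all(c("id_a", "id_b", "r2") %in% names(p)))
    return("pairs needs columns id_a, id_b, r2")
  if (nrow(p) && any(p$r2 < 0 | p$r2 > 1)) return("r2 values must be in [0, 1]")
  TRUE
})

# ---- Synthetic data ---------------------------------------------------------

#' TripleSpec: generating parameters of a synthetic three-trait causal system
#'
#' The stated world of the simulator: an immune-cell-like exposure, a plasma
#' metabolite-like mediator, and a binary disease outcome, linked by
#' \code{alpha_total = direct + b1 * b2}.  See [tripleSpec()] for the
#' constructor and the meaning and defaults of each parameter.
#'
#' @slot nSnpsX,nSnpsM,nSnpsNull counts of exposure-instrument,
#'   mediator-instrument and null background loci.
#' @slot gammaSd,deltaSd instrument effect scales (half-normal magnitudes) for
#'   exposure and mediator loci.
#' @slot alphaTotal,b1,b2 true total, exposure-to-mediator and
#'   mediator-to-outcome effects; the direct effect is
#'   \code{alphaTotal - b1 * b2}.
#' @slot pleiotropyMode,pleiotropyScale,pleiotropyFraction horizontal
#'   pleiotropy model applied to a fraction of exposure instruments:
#'   \code{"none"}, \code{"balanced"} (mean-zero) or \code{"directional"}.
#' @slot nExp,nMed,nOut GWAS sample sizes driving the per-SNP standard errors.
#' @slot palindromicRate fraction of loci assigned palindromic (A/T or C/G)
#'   allele pairs, to exercise harmonization.
#' @slot ldBlocks optional list(n_blocks, block_size, r2) of equicorrelated
#'   LD blocks among exposure instruments.
#' @slot seed integer seed; the generator is deterministic given the spec.
#' @export
setClass("TripleSpec",
         representation(nSnpsX = "integer", nSnpsM = "integer",
                        nSnpsNull = "integer",
                        gammaSd = "numeric", deltaSd = "numeric",
                        alphaTotal = "numeric", b1 = "numeric", b2 = "numeric",
                        pleiotropyMode = "character",
                        pleiotropyScale = "numeric",
                        pleiotropyFraction = "numeric",
                        nExp = "numeric", nMed = "numeric", nOut = "numeric",
                        palindromicRate = "numeric",
                        ldBlocks = "ANY",
                        seed = "integer"))

setValidity("TripleSpec", function(object) {
  msg <- character(0)
  if (object@nSnpsX < 1L) msg <- c(msg, "nSnpsX must be >= 1")
  if (min(object@nExp, object@nMed, object@nOut) <= 0)
    msg <- c(msg, "sample sizes must be > 0")
  if (!object@pleiotropyMode %in% c("none", "balanced", "directional"))
    msg <- c(msg, "pleiotropyMode must be none, balanced or directional")
  if (object@pleiotropyScale < 0) msg <- c(msg, "pleiotropy scale must be >= 0")
  if (object@pleiotropyFraction < 0 || object@pleiotropyFraction > 1)
    msg <- c(msg, "pleiotropyFraction must be in [0, 1]")
  if (object@palindromicRate < 0 || object@palindromicRate > 1)
    msg <- c(msg, "palindromicRate must be in [0, 1]")
  if (object@gammaSd <= 0 || object@deltaSd <= 0)
    msg <- c(msg, "effect scales must be > 0")
  if (!is.null(object@ldBlocks) &&
      !all(c("n_blocks", "block_size", "r2") %in% names(object@ldBlocks)))
    msg <- c(msg, "ldBlocks needs n_blocks, block_size, r2")
  if (length(msg)) msg else TRUE
})

#' TripleSimulation: simulated summary statistics plus generating truth
#'
#' @slot exposure,mediator,outcome [AssociationSet] objects sharing one
#'   variant universe.
#' @slot truth the [TripleSpec] that generated them.
#' @slot ld an [LDPairList] of the injected LD structure, or NULL.
#' @seealso [simulateTriple()]
#' @export
setClass("TripleSimulation",
         representation(exposure = "AssociationSet",
                        mediator = "AssociationSet",
                        outcome = "AssociationSet",
                        truth = "TripleSpec",
                        ld = "ANY"))
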