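#' @rdname AssociationSet-class
#' @export
setMethod("traitId", "AssociationSet", function(object) object@traitId)

#' @rdname AssociationSet-class
#' @export
setMethod("traitType", "AssociationSet", function(object) object@traitType)

#' @rdname AssociationSet-class
#' @export
setMethod("assocData", "AssociationSet", function(object) object@assoc)

#' @rdname AssociationSet-class
#' @export
setMethod("variantIds", "AssociationSet",
          function(object) object@assoc$variant_id)

#' @rdname AssociationSet-class
#' @export
setMethod("nVariants", "AssociationSet", function(object) nrow(object@assoc))

#' @rdname AssociationSet-class
#' @param i variant ids (character) or row indices to keep.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "AssociationSet", function(x, i, j, ..., drop = FALSE) {
  a <- x@assoc
  if (is.character(i)) {
    idx <- match(i, a$variant_id)
    if (anyNA(idx))
      .stopf("unknown variant id(s): %s",
             paste(utils::head(i[is.na(idx)], 5L), collapse = ", "))
  } else idx <- i
  out <- a[idx, , drop = FALSE]
  rownames(out) <- NULL
  new("AssociationSet", traitId = x@traitId, traitType = x@traitType,
      assoc = out)
})

setMethod("show", "AssociationSet", function(object) {
  cat(sprintf("AssociationSet '%s' (%s): %d variant(s)\n",
              object@traitId, object@traitType, nrow(object@assoc)))
  if (nrow(object@assoc))
    print(utils::head(object@assoc, 5L))
})

#' @rdname HarmonizedSet-class
#' @export
setMethod("exposureId", "HarmonizedSet", function(object) object@exposureId)

#' @rdname HarmonizedSet-class
#' @export
setMethod("outcomeId", "HarmonizedSet", function(object) object@outcomeId)

#' @rdname HarmonizedSet-class
#' @export
setMethod("harmonizedData", "HarmonizedSet", function(object) object@data)

#' @rdname HarmonizedSet-class
#' @export
setMethod("droppedCounts", "HarmonizedSet", function(object)
  c(palindromic = object@nDroppedPalindromic,
    incompatible = object@nDroppedIncompatible))

#' @rdname HarmonizedSet-class
#' @export
setMethod("nVariants", "HarmonizedSet", function(object) nrow(object@data))

#' @rdname HarmonizedSet-class
#' @param x a HarmonizedSet.
#' @param i variant ids (character) or row indices to keep.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "HarmonizedSet", function(x, i, j, ..., drop = FALSE) {
  d <- x@data
  if (is.character(i)) i <- match(i, d$variant_id)
  out <- d[i, , drop = FALSE]
  rownames(out) <- NULL
  new("HarmonizedSet", exposureId = x@exposureId, outcomeId = x@outcomeId,
      data = out, nDroppedPalindromic = x@nDroppedPalindromic,
      nDroppedIncompatible = x@nDroppedIncompatible)
})

setMethod("show", "HarmonizedSet", function(object) {
  cat(sprintf("HarmonizedSet %s -> %s: %d SNP(s) (dropped: %d palindromic, %d incompatible)\n",
              object@exposureId, object@outcomeId, nrow(object@data),
              object@nDroppedPalindromic, object@nDroppedIncompatible))
})

#' @rdname InstrumentSet-class
#' @export
setMethod("variantIds", "InstrumentSet", function(object) object@variantIds)

#' @rdname InstrumentSet-class
#' @export
setMethod("fStatistics", "InstrumentSet", function(object) object@fStat)

#' @rdname InstrumentSet-class
#' @export
setMethod("auditCounts", "InstrumentSet", function(object) object@audit)

setMethod("show", "InstrumentSet", function(object) {
  cat(sprintf("InstrumentSet: %d instrument(s)\n", length(object@variantIds)))
  cat("  stages: ", paste(sprintf("%s=%d", names(object@audit), object@audit),
                          collapse = ", "), "\n", sep = "")
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("MREstimate [%s] nsnp=%d\n", object@method, object@nsnp))
  cat(sprintf("  beta = %.4g (se %.4g), 95%% CI [%.4g, %.4g], p = %.3g\n",
              object@beta, object@se, object@ciLow, object@ciHigh,
              object@pval))
  cat(sprintf("  OR = %.4g [%.4g, %.4g]\n",
              object@orValue, object@orCiLow, object@orCiHigh))
  if (identical(object@method, "MR-Egger"))
    cat(sprintf("  intercept = %.4g (se %.4g), p = %.3g\n",
                object@intercept, object@interceptSe, object@interceptPval))
})

setMethod("show", "SensitivityReport", function(object) {
  cat(sprintf("SensitivityReport %s -> %s\n",
              object@exposureId, object@outcomeId))
  cat(sprintf("  Cochran Q (IVW)   = %.4g on %g df, p = %.3g\n",
              object@qIvw, object@qIvwDf, object@qIvwPval))
  cat(sprintf("  Rucker Q' (Egger) = %.4g on %g df, p = %.3g\n",
              object@qEgger, object@qEggerDf, object@qEggerPval))
  cat(sprintf("  Egger intercept   = %.4g (se %.4g), p = %.3g\n",
              object@eggerIntercept, object@eggerInterceptSe,
              object@eggerInterceptPval))
  cat(sprintf("  flags: heterogeneity=%s pleiotropy=%s loo_instability=%s\n",
              object@flags[["heterogeneity"]], object@flags[["pleiotropy"]],
              object@flags[["loo_instability"]]))
})

setMethod("show", "MediationResult", function(object) {
  cat(sprintf("MediationResult: %s -> %s -> %s\n",
              object@exposureId, object@mediatorId, object@outcomeId))
  cat(sprintf("  alpha = %.4g (se %.4g); beta1 = %.4g (se %.4g); beta2 = %.4g (se %.4g)\n",
              object@alpha, object@alphaSe, object@beta1, object@beta1Se,
              object@beta2, object@beta2Se))
  cat(sprintf("  indirect = %.4g [%.4g, %.4g], p = %.3g\n",
              object@indirect, object@indirectCiLow, object@indirectCiHigh,
              object@pval))
  cat(sprintf("  proportion mediated = %.3g%% [%.3g%%, %.3g%%]\n",
              object@proportion, object@proportionCiLow,
              object@proportionCiHigh))
})

setMethod("show", "TripleSimulation", function(object) {
  cat(sprintf("TripleSimulation: %s / %s / %s (%d shared variants)\n",
              traitId(object@exposure), traitId(object@mediator),
              traitId(object@outcome), nVariants(object@exposure)))
  tr <- object@truth
  cat(sprintf("  truth: alpha_total=%.3g b1=%.3g b2=%.3g direct=%.3g pleiotropy=%s\n",
              tr@alphaTotal, tr@b1, tr@b2, tr@alphaTotal - tr@b1 * tr@b2,
              tr@pleiotropyMode))
})

#' Coerce an MREstimate to a one-row data.frame
#'
#' @param x an [MREstimate].
#' @param row.names,optional,... passed over from the generic, unused.
#' @return one-row data.frame with the estimate's fields.
#' @export
as.data.frame.MREstimate <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(method = x@method, nsnp = x@nsnp, beta = x@beta, se = x@se,
             ci_low = x@ciLow, ci_high = x@ciHigh, pval = x@pval,
             or = x@orValue, or_ci_low = x@orCiLow, or_ci_high = x@orCiHigh,
             egger_intercept = x@intercept,
             egger_intercept_se = x@interceptSe,
             egger_intercept_pval = x@interceptPval,
             stringsAsFactors = FALSE)
}
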